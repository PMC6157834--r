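tt <- acq_times()
aif <- test_aif(tt)

test_that("delayed convolution handles trivial inputs and bad grids", {
  zero <- dce_curve(tt, rep(0, length(tt)))
  out <- delayed_convolve(zero, function(u) exp(-u / 30), delay = 3, times = tt)
  expect_equal(out$values, rep(0, length(tt)))
  expect_error(delayed_convolve(aif, identity, 0, c(0, 2, 2)),
               "strictly increasing")
})

test_that("delayed convolution matches fine-grid quadrature", {
  got <- delayed_convolve(aif, function(u) exp(-u / 30), delay = 4, times = tt)
  want <- quad_conv_oracle(aif, function(u) exp(-u / 30), 4, tt)
  expect_lt(max(abs(got$values - want)), 0.005 * max(want))
})

test_that("vascular-only ETM reproduces the (shifted) AIF exactly", {
  out <- etm_concentration(c(Ktrans = 0, ve = 0.4, vp = 1, delay = 0), aif, tt)
  expect_equal(out$values, aif$values)
  out2 <- etm_concentration(c(Ktrans = 0, ve = 0.4, vp = 0.08, delay = 6),
                            aif, tt)
  expect_equal(out2$values, 0.08 * curve_at(aif, tt, delay = 6))
  expect_error(etm_concentration(c(Ktrans = 5, ve = 0, vp = 0.1, delay = 0),
                                 aif, tt), "ve")
})

test_that("ETM matches the quadrature oracle on phantom-like parameters", {
  for (p in list(c(10, 0.4, 0.08, 4), c(2, 0.1, 0.01, 0), c(40, 0.6, 0.2, 2))) {
    got <- etm_concentration(
      c(Ktrans = p[1], ve = p[2], vp = p[3], delay = p[4]), aif, tt)
    want <- quad_etm_oracle(p[1], p[2], p[3], p[4], aif, tt)
    expect_lt(max(abs(got$values - want)), 0.005 * max(want))
  }
})

test_that("ETM with vanishing efflux reduces to the Patlak model", {
  got <- etm_concentration(c(Ktrans = 10, ve = 1e7, vp = 0.08, delay = 0),
                           aif, tt)
  want <- patlak_concentration(c(K1 = 10, vp = 0.08), aif, tt)
  expect_lt(max(abs(got$values - want$values)), 0.001 * max(want$values))
})

test_that("2CXM matches the two-compartment ODE oracle", {
  skip_if_not_installed("deSolve")
  for (p in list(c(60, 0.08, 12, 0.4, 0),    # tumor-rim-like
                 c(12, 0.01, 0.5, 0.2, 4),   # white-matter-like
                 c(200, 0.9, 0, 0.01, 0))) { # vessel-like (no leakage)
    got <- tcxm_concentration(
      c(Fp = p[1], vp = p[2], Fe = p[3], ve = p[4], delay = p[5]), aif, tt)
    want <- ode_tcxm_oracle(p[1], p[2], p[3], p[4], p[5], aif, tt)
    expect_lt(max(abs(got$values - want)), 0.005 * max(want))
  }
})

test_that("2CXM without leakage equals the one-compartment closed form", {
  got <- tcxm_concentration(c(Fp = 60, vp = 0.08, Fe = 0, ve = 0.2,
                              delay = 0), aif, tt)
  a <- (60 / 6000) / 0.08
  want <- (60 / 6000) * quad_conv_oracle(aif, function(u) exp(-a * u), 0, tt)
  expect_lt(max(abs(got$values - want)), 0.005 * max(want))
})

test_that("2CXM converges to ETM in the high-flow limit", {
  got <- tcxm_concentration(c(Fp = 1e5, vp = 0.08, Fe = 12, ve = 0.4,
                              delay = 0), aif, tt)
  want <- etm_concentration(c(Ktrans = 12, ve = 0.4, vp = 0.08, delay = 0),
                            aif, tt)
  expect_lt(max(abs(got$values - want$values)), 0.01 * max(want$values))
})

test_that("near-confluent eigenvalues are handled continuously", {
  # Fp/vp == Fe/ve makes a == b; the discriminant stays positive through
  # the cross term, but push parameters so alpha ~ beta numerically
  base <- c(Fp = 60, vp = 0.1, Fe = 0.006, ve = 1e-5, delay = 0)
  ref <- tcxm_concentration(base * c(1, 1, 1.0001, 1.0001, 1), aif, tt)
  got <- tcxm_concentration(base, aif, tt)
  expect_lt(max(abs(got$values - ref$values)), 0.01 * max(abs(ref$values)))
  expect_true(all(is.finite(got$values)))
})

test_that("Patlak model is exact for its closed forms", {
  out <- patlak_concentration(c(K1 = 0, vp = 0.3), aif, tt)
  expect_equal(out$values, 0.3 * aif$values)
  const <- dce_curve(tt, rep(2, length(tt)))
  ramp <- patlak_concentration(c(K1 = 6, vp = 0), const, tt)
  expect_equal(ramp$values, (6 / 6000) * 2 * tt, tolerance = 1e-12)
})

test_that("all forward models are homogeneous of degree 1 in the AIF", {
  s <- 3.7
  aif_s <- dce_curve(aif$times, s * aif$values)
  pe <- c(Ktrans = 10, ve = 0.4, vp = 0.08, delay = 2)
  p2 <- c(Fp = 60, vp = 0.08, Fe = 12, ve = 0.4, delay = 2)
  pp <- c(K1 = 6, vp = 0.05)
  expect_equal(etm_concentration(pe, aif_s, tt)$values,
               s * etm_concentration(pe, aif, tt)$values, tolerance = 1e-12)
  expect_equal(tcxm_concentration(p2, aif_s, tt)$values,
               s * tcxm_concentration(p2, aif, tt)$values, tolerance = 1e-12)
  expect_equal(patlak_concentration(pp, aif_s, tt)$values,
               s * patlak_concentration(pp, aif, tt)$values, tolerance = 1e-12)
})

test_that("model outputs are non-negative for valid parameters", {
  set.seed(7)
  for (i in 1:20) {
    pe <- c(Ktrans = runif(1, 0, 50), ve = runif(1, 0.05, 0.8),
            vp = runif(1, 0, 0.5), delay = runif(1, -4, 8))
    p2 <- c(Fp = runif(1, 5, 300), vp = runif(1, 0.02, 0.8),
            Fe = runif(1, 0, 30), ve = runif(1, 0.05, 0.8),
            delay = runif(1, -4, 8))
    eps <- 1e-12 * max(aif$values)
    expect_gte(min(etm_concentration(pe, aif, tt)$values), -eps)
    expect_gte(min(tcxm_concentration(p2, aif, tt)$values), -eps)
  }
})

test_that("equivalent Ktrans never exceeds either flow", {
  set.seed(8)
  Fp <- runif(50, 0, 500); Fe <- runif(50, 0, 100)
  expect_true(all(ktrans_equiv(Fp, Fe) <= pmin(Fp, Fe) + 1e-12))
  expect_equal(ktrans_equiv(60, 12), 10)
})

test_that("parameter constructors enforce their invariants", {
  expect_error(etm_params(Ktrans = 5, ve = 0, vp = 0.1), "ve")
  expect_error(tcxm_params(Fp = 60, vp = 0, Fe = 5, ve = 0.4), "vp")
  expect_error(tcxm_params(Fp = 60, vp = 0.1, Fe = 5, ve = 0), "ve")
  expect_silent(tcxm_params(Fp = 0, vp = 0, Fe = 0, ve = 0))
  expect_equal(unname(kep(10, 0.4)), 25)
})
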