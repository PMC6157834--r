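# Shared fixtures and independent oracles for the forward-model and
# statistics tests. The oracles integrate the same mathematical objects as
# the implementation (the piecewise-linear interpolant of the sampled AIF)
# by completely different numerical routes: brute-force fine-grid
# quadrature, direct ODE integration, exhaustive enumeration.

acq_times <- function(dur = 298, dt = 2) seq(0, dur, by = dt)

test_aif <- function(times = acq_times()) population_aif(times)

# Fine-grid trapezoidal quadrature of (aif(. - delay) * kernel)(t), where
# aif(.) is the piecewise-linear interpolant of the sampled curve (zero
# before its first sample, last value after the end) -- the same integrand
# the package discretizes, integrated ~refine x finer.
quad_conv_oracle <- function(aif, kernel, delay, times, refine = 40) {
  af <- stats::approxfun(aif$times + delay, aif$values, yleft = 0,
                         yright = aif$values[length(aif$values)])
  vapply(times, function(t) {
    if (t <= times[1]) return(0)
    tau <- seq(times[1], t, length.out = refine * 100 + 1)
    f <- af(tau) * kernel(t - tau)
    sum(diff(tau) * (f[-1] + f[-length(f)]) / 2)
  }, numeric(1))
}

# ETM curve by quadrature: vascular term interpolated, leakage term by
# fine-grid quadrature of the exponential kernel.
quad_etm_oracle <- function(Ktrans, ve, vp, delay, aif, times) {
  kep_s <- (Ktrans / 6000) / ve
  af <- stats::approxfun(aif$times + delay, aif$values, yleft = 0,
                         yright = aif$values[length(aif$values)])
  (Ktrans / 6000) * quad_conv_oracle(aif, function(u) exp(-kep_s * u),
                                     delay, times) + vp * af(times)
}

# 2CXM curve by direct integration of the two-compartment mass-balance
# ODEs (plasma and interstitial concentration), driven by the
# piecewise-linear AIF; stiff solver at tight tolerance.
ode_tcxm_oracle <- function(Fp, vp, Fe, ve, delay, aif, times) {
  fp <- Fp / 6000; fe <- Fe / 6000
  ca <- stats::approxfun(aif$times + delay, aif$values, yleft = 0,
                         yright = aif$values[length(aif$values)])
  deriv <- function(t, y, parms) {
    list(c((fp * (ca(t) - y[1]) + fe * (y[2] - y[1])) / vp,
           fe * (y[1] - y[2]) / ve))
  }
  fine <- seq(times[1], times[length(times)], by = diff(times)[1] / 10)
  sol <- deSolve::ode(c(0, 0), fine, deriv, NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-13)
  ct <- vp * sol[, 2] + ve * sol[, 3]
  stats::approx(fine, ct, xout = times)$y
}

# Exhaustive pairwise AUC: mean over all (positive, negative) pairs of
# 1[score_pos > score_neg] + 0.5 * 1[tie].
pairwise_auc_oracle <- function(labels, scores) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Exact two-sided signed-rank p-value via the generating-polynomial
# distribution of W = sum of ranks with positive sign (a different
# algorithm from the implementation's sign-pattern enumeration).
genpoly_wilcoxon_oracle <- function(d) {
  d <- d[d != 0]
  rk <- rank(abs(d))
  W <- sum(rk[d > 0])
  # distribution over 2^n sign patterns: counts[w*2 + 1] since midranks can
  # be half-integers; work on doubled ranks to stay integer
  rk2 <- as.integer(round(2 * rk))
  counts <- c(1, rep(0, sum(rk2)))
  for (r in rk2) {
    shifted <- c(rep(0, r), counts[1:(length(counts) - r)])
    counts <- counts + shifted
  }
  probs <- counts / 2^length(d)
  w2 <- round(2 * W)
  support <- seq_along(counts) - 1
  min(1, 2 * min(sum(probs[support <= w2]), sum(probs[support >= w2])))
}

# A modest noisy 2CXM voxel fixture used across fitting tests.
rim_curve <- function(times = acq_times(), aif = test_aif(times)) {
  tcxm_concentration(c(Fp = 60, vp = 0.08, Fe = 12, ve = 0.4, delay = 0),
                     aif, times)
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual / expected - 1)), tol)
}
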