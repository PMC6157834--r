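#' Physiological parameter ranges
#'
#' Closed intervals defining the physiologically admissible box used by the
#' penalized least-squares fitter: `Fp` 0-500 ml/100g/min, `ve` 0-1 ml/g,
#' `vp` 0-1 ml/g, `K1` 0-100 ml/100g/min. `Ktrans` and `Fe` inherit the `K1`
#' range; the delay is unconstrained. The Bayesian fitter imposes no upper
#' bounds.
#'
#' @param Fp,K1,ve,vp Length-2 numeric intervals `c(lo, hi)`.
#' @return A named list of intervals of class `"dce_ranges"`.
#' @export
dce_ranges <- function(Fp = c(0, 500), K1 = c(0, 100),
                       ve = c(0, 1), vp = c(0, 1)) {
  r <- list(Fp = Fp, K1 = K1, ve = ve, vp = vp)
  for (nm in names(r))
    if (length(r[[nm]]) != 2L || r[[nm]][1] > r[[nm]][2])
      stop("each range must be c(lo, hi) with lo <= hi", call. = FALSE)
  structure(r, class = "dce_ranges")
}

range_for <- function(ranges, name) {
  switch(name,
         Fp = ranges$Fp,
         K1 = , Ktrans = , Fe = ranges$K1,
         ve = ranges$ve, vp = ranges$vp,
         c(-Inf, Inf))
}

# TRUE if every named parameter lies inside its physiological interval.
params_in_range <- function(par, ranges) {
  for (nm in names(par)) {
    rg <- range_for(ranges, nm)
    if (par[[nm]] < rg[1] || par[[nm]] > rg[2]) return(FALSE)
  }
  TRUE
}

#' Fitter control settings
#'
#' @param penalty Constant added once to the sum of squares when any
#'   parameter leaves its physiological range (LM only); default 100000.
#' @param max_iter Maximum EM iterations for the Bayesian fitter.
#' @param lm_max_iter Maximum Levenberg-Marquardt iterations.
#' @param tol Relative log-posterior change declaring EM convergence.
#' @param sigma2_floor Lower bound on the noise variance estimate.
#' @param jac_step Relative forward-difference step for numeric Jacobians.
#' @return A list of class `"dce_control"`.
#' @export
dce_control <- function(penalty = 1e5, max_iter = 50L, lm_max_iter = 100L,
                        tol = 1e-6, sigma2_floor = 1e-12, jac_step = 1e-6) {
  structure(list(penalty = penalty, max_iter = as.integer(max_iter),
                 lm_max_iter = as.integer(lm_max_iter), tol = tol,
                 sigma2_floor = sigma2_floor, jac_step = jac_step),
            class = "dce_control")
}

# Forward model dispatch on a natural-unit named parameter vector.
model_curve <- function(model, par, aif, times) {
  switch(model,
         etm = etm_concentration(par, aif, times),
         `2cxm` = tcxm_concentration(par, aif, times),
         patlak = patlak_concentration(par, aif, times),
         stop("unknown model: ", model, call. = FALSE))
}

model_par_names <- function(model) {
  switch(model,
         etm = c("Ktrans", "ve", "vp", "delay"),
         `2cxm` = c("Fp", "vp", "Fe", "ve", "delay"))
}

#' Log-domain reparameterization of the kinetic parameters
#'
#' The Bayesian fitter estimates log-transformed parameters so that the
#' hemodynamic quantities can never go negative; the delay, which may
#' legitimately be near zero or negative, is passed through untransformed.
#' The extended Tofts model is additionally re-parameterized to
#' `(log Ktrans, log kep, log vp, delay)` with `kep = Ktrans/ve`, matching
#' the parameter list of its prior; the 2CXM transform is
#' `(log Fp, log vp, log Fe, log ve, delay)`. The inverse is an exact
#' round-trip.
#'
#' @param params Named numeric vector: natural units for `"forward"`,
#'   transformed domain for `"inverse"`.
#' @param model `"etm"` or `"2cxm"`.
#' @param direction `"forward"` (natural to log) or `"inverse"`.
#' @return Named numeric vector in the other domain.
#' @export
transform_params <- function(params, model = c("etm", "2cxm"),
                             direction = c("forward", "inverse")) {
  model <- match.arg(model); direction <- match.arg(direction)
  p <- unlist(params)
  if (direction == "forward") {
    nm <- model_par_names(model)
    p <- p[nm]
    if (any(p[setdiff(nm, "delay")] <= 0))
      stop("forward transform requires strictly positive parameters",
           call. = FALSE)
    if (model == "etm") {
      c(lKtrans = log(p[["Ktrans"]]), lkep = log(p[["Ktrans"]] / p[["ve"]]),
        lvp = log(p[["vp"]]), delay = p[["delay"]])
    } else {
      c(lFp = log(p[["Fp"]]), lvp = log(p[["vp"]]), lFe = log(p[["Fe"]]),
        lve = log(p[["ve"]]), delay = p[["delay"]])
    }
  } else {
    if (model == "etm") {
      c(Ktrans = exp(p[[1L]]), ve = exp(p[[1L]] - p[[2L]]),
        vp = exp(p[[3L]]), delay = p[[4L]])
    } else {
      c(Fp = exp(p[[1L]]), vp = exp(p[[2L]]), Fe = exp(p[[3L]]),
        ve = exp(p[[4L]]), delay = p[[5L]])
    }
  }
}

#' @rdname transform_params
#' @details `transform_jacobian()` returns the analytic Jacobian
#'   `d(transformed)/d(natural)` of the forward transform at `params`.
#' @export
transform_jacobian <- function(params, model = c("etm", "2cxm")) {
  model <- match.arg(model)
  p <- unlist(params)[model_par_names(model)]
  if (model == "etm") {
    J <- matrix(0, 4, 4, dimnames = list(c("lKtrans", "lkep", "lvp", "delay"),
                                         names(p)))
    J["lKtrans", "Ktrans"] <- 1 / p[["Ktrans"]]
    J["lkep", "Ktrans"] <- 1 / p[["Ktrans"]]
    J["lkep", "ve"] <- -1 / p[["ve"]]
    J["lvp", "vp"] <- 1 / p[["vp"]]
    J["delay", "delay"] <- 1
  } else {
    J <- matrix(0, 5, 5, dimnames = list(c("lFp", "lvp", "lFe", "lve", "delay"),
                                         names(p)))
    J["lFp", "Fp"] <- 1 / p[["Fp"]]
    J["lvp", "vp"] <- 1 / p[["vp"]]
    J["lFe", "Fe"] <- 1 / p[["Fe"]]
    J["lve", "ve"] <- 1 / p[["ve"]]
    J["delay", "delay"] <- 1
  }
  J
}

#' Prior for the Bayesian fitter
#'
#' Gaussian prior in the transformed (log) domain. The mean comes from the
#' initializer ([build_init()]); the delay prior mean is 0 s. The diagonal
#' covariance defaults are, for the extended Tofts model, `(0.1, 10, 0.1,
#' 10)` over `(log Ktrans, log kep, log vp, delay)` — tight on the leakage
#' constant and plasma volume, loose on the efflux rate and delay — and for
#' the 2CXM `(0.1, 1, 10, 1, 10)` over `(log Fp, log vp, log Fe, log ve,
#' delay)`. Entries are log-domain variances (the delay entry acts on the
#' untransformed delay, in s^2).
#'
#' @param model `"etm"` or `"2cxm"`.
#' @param init A [build_init()] result or a named natural-unit vector giving
#'   the prior mean location.
#' @param cov Optional diagonal covariance override (vector of variances).
#' @param delay_mean Prior mean of the delay, seconds.
#' @return A list of class `"dce_prior"` with `model`, `mean`, `cov`.
#' @export
dce_prior <- function(model = c("etm", "2cxm"), init, cov = NULL,
                      delay_mean = 0) {
  model <- match.arg(model)
  par <- if (inherits(init, "dce_init")) init$par else unlist(init)
  par <- par[model_par_names(model)]
  par["delay"] <- delay_mean
  m <- transform_params(pmax_named(par), model, "forward")
  if (is.null(cov))
    cov <- if (model == "etm") c(0.1, 10, 0.1, 10) else c(0.1, 1, 10, 1, 10)
  if (length(cov) != length(m) || any(cov <= 0))
    stop("prior covariance must be positive and match the parameter count",
         call. = FALSE)
  structure(list(model = model, mean = m, cov = as.numeric(cov)),
            class = "dce_prior")
}

# floor the non-delay entries so the log transform is defined
pmax_named <- function(par, floor = 1e-6) {
  nd <- setdiff(names(par), "delay")
  par[nd] <- pmax(par[nd], floor)
  par
}

#' Penalized sum-of-squares cost
#'
#' The least-squares objective of the LM fitter: the sum of squared
#' differences between the model curve and the data, plus a constant penalty
#' (default 100,000) added once whenever any parameter lies outside its
#' physiological range — a deliberate cost cliff that discourages, but does
#' not forbid, non-physiological excursions. Total function: parameter
#' vectors for which the forward model is singular are costed as a zero
#' model curve plus the penalty.
#'
#' @param model `"etm"` or `"2cxm"`.
#' @param params Named natural-unit parameter vector.
#' @param curve Observed tissue [dce_curve].
#' @param aif Arterial input function [dce_curve].
#' @param ranges A [dce_ranges()] list.
#' @param penalty_const The out-of-range penalty; default 100000.
#' @return The scalar cost.
#' @export
penalized_cost <- function(model, params, curve, aif, ranges = dce_ranges(),
                           penalty_const = 1e5) {
  curve <- as_curve(curve)
  p <- unlist(params)
  if (anyNA(p) || any(!is.finite(p))) return(Inf)
  mc <- tryCatch(model_curve(model, p, aif, curve$times)$values,
                 error = function(e) NULL)
  if (is.null(mc)) return(sum(curve$values^2) + penalty_const)
  sse <- sum((curve$values - mc)^2)
  if (!params_in_range(p, ranges)) sse <- sse + penalty_const
  sse
}

#' Penalized Levenberg-Marquardt fit
#'
#' Minimizes [penalized_cost()] from the starting guess by
#' Levenberg-Marquardt least squares with a numerically differentiated
#' Jacobian; the out-of-range penalty enters as an extra residual element of
#' `sqrt(penalty)` so the optimizer's sum of squares equals the penalized
#' cost exactly. The returned parameters are whatever minimum the descent
#' reaches — possibly local, possibly non-physiological; that failure mode
#' is intrinsic to the method and is what the Bayesian alternative is
#' measured against.
#'
#' @param model `"etm"` or `"2cxm"`.
#' @param curve Observed tissue [dce_curve].
#' @param aif Arterial input function [dce_curve].
#' @param init A [build_init()] result or named natural-unit vector.
#' @param ranges A [dce_ranges()] list.
#' @param control A [dce_control()] list.
#' @return A `"dce_fit"` object; see [dce_fit()].
#' @export
fit_lm <- function(model, curve, aif, init, ranges = dce_ranges(),
                   control = dce_control()) {
  curve <- as_curve(curve); aif <- as_curve(aif)
  par0 <- if (inherits(init, "dce_init")) init$par else unlist(init)
  par0 <- par0[model_par_names(model)]
  y <- curve$values
  sq_pen <- sqrt(control$penalty)
  resid_fn <- function(p) {
    names(p) <- names(par0)
    mc <- tryCatch(model_curve(model, p, aif, curve$times)$values,
                   error = function(e) rep(0, length(y)))
    pen <- if (params_in_range(p, ranges)) 0 else sq_pen
    c(y - mc, pen)
  }
  ctl <- minpack.lm::nls.lm.control(maxiter = control$lm_max_iter,
                                    ftol = 1e-13, ptol = 1e-13)
  # warm restarts re-open the trust region at the current iterate, which
  # reliably finishes descents the first pass abandons on a flat stretch
  run_from <- function(p) tryCatch(
    minpack.lm::nls.lm(par = p, fn = resid_fn, control = ctl),
    error = function(e) NULL)
  res <- run_from(par0)
  iters <- if (is.null(res)) 0L else res$niter
  if (!is.null(res)) {
    for (r in 1:2) {
      again <- run_from(res$par)
      if (is.null(again)) break
      iters <- iters + again$niter
      improved <- again$deviance < res$deviance * (1 - 1e-12)
      res <- again
      if (!improved) break
    }
  }
  if (is.null(res)) {
    est <- par0; converged <- FALSE
  } else {
    est <- res$par; names(est) <- names(par0)
    converged <- res$info %in% 1:4
  }
  fit_vals <- tryCatch(model_curve(model, est, aif, curve$times)$values,
                       error = function(e) rep(NA_real_, length(y)))
  sse <- sum((y - fit_vals)^2)
  cost <- sse + if (params_in_range(est, ranges)) 0 else control$penalty
  new_dce_fit(model = model, method = "lm", estimate = est,
              curve = curve, aif = aif, fitted = fit_vals,
              sigma2 = max(sse / length(y), control$sigma2_floor),
              vcov_log = NULL, iterations = iters, converged = converged,
              cost = cost, init = par0, prior = NULL, ranges = ranges)
}

#' Bayesian expectation-maximization fit
#'
#' Maximum-a-posteriori estimation of the log-transformed kinetic parameters
#' under the Gaussian observation model `y ~ N(f(theta), sigma^2 I)` and the
#' Gaussian prior of [dce_prior()]. Each iteration takes a
#' Levenberg-damped Gauss-Newton step on the log posterior (E-step, with a
#' Laplace — local Gaussian — approximation of the posterior) and then
#' re-estimates the noise variance from the mean squared residual at the
#' current mode plus a curvature correction `tr(J Sigma J')/T` that accounts
#' for posterior parameter uncertainty (M-step). Iteration stops when the
#' relative change of the log posterior falls below `control$tol` or after
#' `control$max_iter` iterations. No upper bounds are imposed on the
#' parameters.
#'
#' @param model `"etm"` or `"2cxm"`.
#' @param curve Observed tissue [dce_curve].
#' @param aif Arterial input function [dce_curve].
#' @param prior A [dce_prior()].
#' @param control A [dce_control()] list.
#' @return A `"dce_fit"` object whose `estimate` is the exponentiated
#'   posterior mode (delay untransformed) and whose `vcov_log` is the
#'   log-domain Laplace posterior covariance.
#' @export
fit_bayes <- function(model, curve, aif, prior, control = dce_control()) {
  curve <- as_curve(curve); aif <- as_curve(aif)
  stopifnot(inherits(prior, "dce_prior"), identical(prior$model, model))
  y <- curve$values
  n <- length(y)
  m0 <- prior$mean
  C0inv <- diag(1 / prior$cov, length(m0))
  p <- length(m0)
  fwd <- function(th) {
    nat <- transform_params(th, model, "inverse")
    tryCatch(model_curve(model, nat, aif, curve$times)$values,
             error = function(e) rep(Inf, n))
  }
  jac <- function(th, f0) {
    J <- matrix(0, n, p)
    for (k in seq_len(p)) {
      h <- control$jac_step * (1 + abs(th[k]))
      thk <- th; thk[k] <- thk[k] + h
      J[, k] <- (fwd(thk) - f0) / h
    }
    J
  }
  log_post <- function(resid, th, s2) {
    -n / 2 * log(s2) - sum(resid^2) / (2 * s2) -
      0.5 * sum((th - m0)^2 / prior$cov)
  }
  th <- m0
  f0 <- fwd(th)
  r <- y - f0
  if (any(!is.finite(r))) r <- y
  s2 <- max(stats::var(r) * (n - 1) / n, control$sigma2_floor)
  lp <- log_post(r, th, s2)
  lam <- 1e-3
  converged <- FALSE
  iters <- 0L
  J <- jac(th, f0)
  for (it in seq_len(control$max_iter)) {
    iters <- it
    H0 <- crossprod(J) / s2 + C0inv
    g <- crossprod(J, r) / s2 - C0inv %*% (th - m0)
    accepted <- FALSE
    for (try in 1:40) {
      step <- tryCatch(solve(H0 + lam * diag(p), g), error = function(e) NULL)
      if (is.null(step)) { lam <- lam * 10; next }
      thn <- th + as.vector(step)
      fn <- fwd(thn)
      rn <- y - fn
      if (all(is.finite(rn))) {
        lpn <- log_post(rn, thn, s2)
        if (lpn >= lp) {
          th <- thn; f0 <- fn; r <- rn; lp <- lpn
          lam <- max(lam / 10, 1e-12)
          accepted <- TRUE
          break
        }
      }
      lam <- lam * 10
      if (lam > 1e12) break
    }
    J <- jac(th, f0)
    # M-step: residual variance at the mode plus the Laplace curvature term
    H0 <- crossprod(J) / s2 + C0inv
    Sig <- tryCatch(chol2inv(chol(H0)), error = function(e) NULL)
    curv <- if (is.null(Sig)) 0 else sum(J * (J %*% Sig))
    s2_new <- max((sum(r^2) + curv) / n, control$sigma2_floor)
    lp_new <- log_post(r, th, s2_new)
    if (abs(lp_new - lp) <= control$tol * (abs(lp) + 1e-10) && accepted) {
      s2 <- s2_new; lp <- lp_new
      converged <- TRUE
      break
    }
    s2 <- s2_new; lp <- lp_new
    if (!accepted && lam > 1e12) break
  }
  H0 <- crossprod(J) / s2 + C0inv
  Sig <- tryCatch(chol2inv(chol(H0)), error = function(e) {
    chol2inv(chol(H0 + 1e-8 * diag(p)))
  })
  dimnames(Sig) <- list(names(m0), names(m0))
  est <- transform_params(th, model, "inverse")
  fit_vals <- f0
  new_dce_fit(model = model, method = "bayes", estimate = est,
              curve = curve, aif = aif, fitted = fit_vals,
              sigma2 = s2, vcov_log = Sig, iterations = iters,
              converged = converged, cost = -lp, init = NULL, prior = prior,
              ranges = NULL)
}
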