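#' Fit a kinetic model to a single concentration-time curve
#'
#' The front-end estimator: given a tissue curve and an arterial input
#' function, fits the extended Tofts or two-compartment-exchange model by
#' either penalized Levenberg-Marquardt least squares (`method = "lm"`) or
#' the Bayesian expectation-maximization estimator on log-transformed
#' parameters (`method = "bayes"`). The starting guess (LM) and prior mean
#' (BM) default to the Patlak/SVD/AUC composition of [build_init()].
#'
#' @param curve Tissue concentration [dce_curve] (or a two-column
#'   data.frame).
#' @param aif Arterial input function [dce_curve] (plasma concentration).
#' @param model `"2cxm"` or `"etm"`.
#' @param method `"bayes"` or `"lm"`.
#' @param init Optional starting guess: a [build_init()] result or a named
#'   natural-unit vector. Computed from the data when `NULL`.
#' @param prior Optional [dce_prior()] (Bayesian method only); derived from
#'   `init` when `NULL`.
#' @param ranges [dce_ranges()] penalty box for the LM method.
#' @param config List passed to [build_init()] when `init` is `NULL`.
#' @param control [dce_control()] settings.
#' @return An object of class `"dce_fit"` with components `estimate` (named
#'   vector, natural units: flows ml/100g/min, volumes fractions, delay s),
#'   `sigma2`, `iterations`, `converged`, `cost` (penalized SSE for LM,
#'   negative log posterior for BM), `vcov_log` (BM only), and the data.
#'   Methods: `print`, `summary`, `coef`, `predict`, `fitted`, `residuals`,
#'   `plot`, `simulate`, `vcov`, `logLik`.
#' @examples
#' tt <- seq(0, 298, by = 2)
#' aif <- population_aif(tt)
#' truth <- tcxm_params(Fp = 60, vp = 0.08, Fe = 12, ve = 0.4)
#' y <- tcxm_concentration(truth, aif, tt)
#' fit <- dce_fit(y, aif, model = "2cxm", method = "bayes")
#' coef(fit)
#' @export
dce_fit <- function(curve, aif, model = c("2cxm", "etm"),
                    method = c("bayes", "lm"), init = NULL, prior = NULL,
                    ranges = dce_ranges(), config = list(),
                    control = dce_control()) {
  model <- match.arg(model); method <- match.arg(method)
  curve <- as_curve(curve); aif <- as_curve(aif)
  if (is.null(init) && (method == "lm" || is.null(prior)))
    init <- build_init(model, curve, aif, config = config)
  if (method == "lm") {
    fit_lm(model, curve, aif, init, ranges = ranges, control = control)
  } else {
    if (is.null(prior)) prior <- dce_prior(model, init)
    fit_bayes(model, curve, aif, prior, control = control)
  }
}

new_dce_fit <- function(model, method, estimate, curve, aif, fitted, sigma2,
                        vcov_log, iterations, converged, cost, init, prior,
                        ranges) {
  structure(list(model = model, method = method, estimate = estimate,
                 curve = curve, aif = aif, fitted = fitted, sigma2 = sigma2,
                 vcov_log = vcov_log, iterations = iterations,
                 converged = converged, cost = cost, init = init,
                 prior = prior, ranges = ranges),
            class = "dce_fit")
}

#' @export
print.dce_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Kinetic model fit (%s, %s)\n",
              toupper(x$model), if (x$method == "bayes") "Bayesian EM" else
                "penalized Levenberg-Marquardt"))
  print(round(x$estimate, digits))
  cat(sprintf("sigma^2 = %.4g; %d iterations; %sconverged\n",
              x$sigma2, x$iterations, if (x$converged) "" else "NOT "))
  invisible(x)
}

#' @export
coef.dce_fit <- function(object, ...) object$estimate

#' @export
fitted.dce_fit <- function(object, ...) dce_curve(object$curve$times, object$fitted)

#' @export
residuals.dce_fit <- function(object, ...) object$curve$values - object$fitted

#' @export
vcov.dce_fit <- function(object, ...) object$vcov_log

#' @export
logLik.dce_fit <- function(object, ...) {
  n <- length(object$curve$times)
  r <- residuals(object)
  ll <- -n / 2 * (log(2 * pi * object$sigma2)) - sum(r^2) / (2 * object$sigma2)
  structure(ll, df = length(object$estimate) + 1L, nobs = n, class = "logLik")
}

#' @export
predict.dce_fit <- function(object, times = NULL, aif = NULL, ...) {
  if (is.null(times)) times <- object$curve$times
  if (is.null(aif)) aif <- object$aif
  model_curve(object$model, object$estimate, aif, times)
}

#' @export
summary.dce_fit <- function(object, level = 0.95, ...) {
  est <- object$estimate
  tab <- data.frame(estimate = est,
                    units = vapply(names(est), param_units, ""),
                    row.names = names(est))
  if (!is.null(object$vcov_log)) {
    sd_log <- sqrt(diag(object$vcov_log))
    z <- stats::qnorm(1 - (1 - level) / 2)
    # transformed-domain CI mapped back; delay is untransformed
    th <- transform_params(pmax_named(est), object$model, "forward")
    lo <- th - z * sd_log; hi <- th + z * sd_log
    nat_lo <- transform_params(lo, object$model, "inverse")
    nat_hi <- transform_params(hi, object$model, "inverse")
    tab$ci_lo <- pmin(nat_lo, nat_hi)[names(est)]
    tab$ci_hi <- pmax(nat_lo, nat_hi)[names(est)]
  }
  derived <- if (object$model == "etm")
    c(kep = unname(est[["Ktrans"]] / est[["ve"]])) else
    c(Ktrans_equiv = unname(ktrans_equiv(est[["Fp"]], est[["Fe"]])))
  out <- list(model = object$model, method = object$method, table = tab,
              derived = derived, sigma2 = object$sigma2,
              iterations = object$iterations, converged = object$converged,
              cost = object$cost)
  class(out) <- "summary.dce_fit"
  out
}

#' @export
print.summary.dce_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Kinetic model fit: %s via %s\n\n", toupper(x$model),
              if (x$method == "bayes") "Bayesian EM (MAP, Laplace posterior)"
              else "penalized Levenberg-Marquardt"))
  print(format(x$table, digits = digits))
  cat("\nDerived: ", paste(sprintf("%s = %.*g", names(x$derived), digits,
                                   x$derived), collapse = ", "), "\n", sep = "")
  cat(sprintf("Noise variance %.4g; cost %.6g; %d iterations; %sconverged\n",
              x$sigma2, x$cost, x$iterations, if (x$converged) "" else "NOT "))
  invisible(x)
}

#' @export
plot.dce_fit <- function(x, ...) {
  graphics::plot(x$curve$times, x$curve$values, pch = 16, cex = 0.6,
                 col = "grey40", xlab = "time (s)",
                 ylab = "concentration", ...)
  graphics::lines(x$curve$times, x$fitted, col = "firebrick", lwd = 2)
  graphics::legend("topright", c("data", "fit"), pch = c(16, NA),
                   lty = c(NA, 1), col = c("grey40", "firebrick"), bty = "n")
  invisible(x)
}

#' @export
simulate.dce_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(object$fitted)
  sd <- sqrt(object$sigma2)
  out <- lapply(seq_len(nsim), function(i)
    dce_curve(object$curve$times, object$fitted + stats::rnorm(n, 0, sd)))
  if (nsim == 1L) out[[1L]] else out
}
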