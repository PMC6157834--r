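#' Patlak plot fit
#'
#' Ordinary least squares on the Patlak linearization
#' `C(t)/Cp(t) = vp + K1 * (int_0^t Cp)/Cp(t)`: the slope estimates the
#' uptake constant `K1` and the intercept the plasma volume `vp`. Exact (a
#' linear identity) on data generated by the Patlak forward model; on data
#' with back-flux (kep > 0) it underestimates the true leakage constant,
#' which is the expected behavior of an irreversible-uptake approximation.
#'
#' Frames are used from `window[1]` to `window[2]` (default: bolus arrival
#' + 30 s to the end of the scan) and only where `Cp` exceeds
#' `cp_floor_frac` of the AIF peak, which keeps the linearization away from
#' division by near-zero plasma concentration.
#'
#' @param curve Tissue concentration [dce_curve].
#' @param aif Arterial input function [dce_curve].
#' @param window Length-2 numeric, seconds; `NULL` for the default window.
#' @param cp_floor_frac Minimum `Cp` as a fraction of the AIF peak.
#' @return A [patlak_params] vector (K1 in ml/100g/min, vp fraction).
#' @export
patlak_fit <- function(curve, aif, window = NULL, cp_floor_frac = 0.05) {
  curve <- as_curve(curve); aif <- as_curve(aif)
  tt <- curve$times
  cp <- curve_at(aif, tt)
  if (all(cp == 0)) stop("AIF is identically zero", call. = FALSE)
  if (is.null(window)) {
    nb <- n_baseline_frames(aif)
    window <- c(aif$times[min(nb + 1L, length(tt))] + 30, tt[length(tt)])
  }
  sel <- tt >= window[1] & tt <= window[2] & cp > cp_floor_frac * max(cp)
  if (sum(sel) < 3L)
    stop("insufficient data: fewer than 3 usable frames in the Patlak window",
         call. = FALSE)
  x <- cumtrapz(tt, cp)[sel] / cp[sel]
  y <- curve$values[sel] / cp[sel]
  fit <- stats::lm.fit(cbind(1, x), y)
  patlak_params(K1 = flow_from_si(unname(fit$coefficients[2L])),
                vp = unname(fit$coefficients[1L]))
}

#' Model-free deconvolution by truncated SVD
#'
#' Solves the discrete convolution `C = A r` for the flow-scaled residue
#' `r(t) = Fp R(t)`, where `A` is the lower-triangular, trapezoid-corrected
#' convolution matrix built from the AIF, with singular values below
#' `threshold_frac * sigma_max` zeroed before inversion. The plasma-flow
#' estimate is the maximum of the deconvolved residue; the leakage
#' (`Ktrans`) estimate reads the residue after the vascular spike has
#' passed, as its maximum from 10 s after bolus arrival onward. (For slow
#' efflux this equals the residue's late plateau; for fast efflux the
#' plateau has already decayed and the post-spike value is the only reading
#' that still reflects the leakage rate.)
#'
#' @param curve Tissue concentration [dce_curve]; resampled to a uniform grid
#'   internally if sampling is non-uniform.
#' @param aif Arterial input function [dce_curve].
#' @param threshold_frac Singular-value cutoff as a fraction of the largest
#'   singular value, in `[0, 1)`; default 0.2.
#' @return A list: `residue` (the deconvolved [dce_curve] `Fp R(t)`, in
#'   1/s... scaled to ml/100g/min), `Fp_est`, `Ktrans_est` (both
#'   ml/100g/min).
#' @export
svd_deconvolve <- function(curve, aif, threshold_frac = 0.2) {
  curve <- as_curve(curve); aif <- as_curve(aif)
  if (threshold_frac < 0 || threshold_frac >= 1)
    stop("threshold_frac must be in [0, 1)", call. = FALSE)
  tt <- curve$times
  dt <- diff(tt)
  if (max(dt) - min(dt) > 1e-8 * mean(dt)) {
    tt <- seq(tt[1L], tt[length(tt)], length.out = length(tt))
    y <- curve_at(curve, tt)
  } else y <- curve$values
  cp <- curve_at(aif, tt)
  if (all(cp == 0)) stop("AIF is identically zero", call. = FALSE)
  n <- length(tt)
  # trapezoid-corrected lower-triangular Toeplitz convolution matrix
  A <- conv_weights(tt) * stats::toeplitz(cp)
  A[upper.tri(A)] <- 0
  sv <- svd(A)
  # even at threshold 0, singular values at rounding level are null space
  tol <- max(threshold_frac, .Machine$double.eps * n)
  dinv <- ifelse(sv$d >= tol * sv$d[1L], 1 / sv$d, 0)
  r <- sv$v %*% (dinv * crossprod(sv$u, y))
  r <- as.vector(r)
  arrival <- aif$times[n_baseline_frames(aif)]
  post <- tt >= arrival + 10
  if (!any(post)) post <- tt >= tt[1L] + 2 / 3 * (tt[n] - tt[1L])
  list(residue = dce_curve(tt, flow_from_si(r)),
       Fp_est = flow_from_si(max(r, 0)),
       Ktrans_est = flow_from_si(max(r[post], 0)))
}

#' Interstitial-volume starting value from the late tissue AUC
#'
#' Integrates the tissue curve from 60 s after the baseline end to 300 s and
#' normalizes by the AIF area over the same window, yielding a dimensionless,
#' dose-invariant fraction that rank-orders with the true `ve`. The result is
#' clipped to `(floor, 1)` so it can serve as a log-transform-safe starting
#' value.
#'
#' @param curve Tissue concentration [dce_curve].
#' @param aif Arterial input function [dce_curve].
#' @param baseline_end End of the pre-bolus baseline, seconds.
#' @param floor Lower clip, default 1e-3.
#' @return A single numeric `ve` starting value in `(floor, 1]`.
#' @export
auc_ve <- function(curve, aif, baseline_end = 0, floor = 1e-3) {
  curve <- as_curve(curve); aif <- as_curve(aif)
  a <- baseline_end + 60
  b <- min(300, curve$times[length(curve$times)])
  if (b <= a) stop("insufficient data: empty AUC window", call. = FALSE)
  num <- trapz_window(curve, a, b)
  den <- trapz_window(aif, a, b)
  if (den <= 0) stop("AIF has no area in the AUC window", call. = FALSE)
  min(max(num / den, floor), 1)
}

#' Compose the fitting starting guess / prior mean
#'
#' Combines the three initializer sub-methods the way the voxelwise pipeline
#' expects: `K1` and `vp` from the Patlak fit, `Fp` and `Ktrans` from SVD
#' deconvolution, `ve` from the late AUC ratio. For the extended Tofts model
#' the guess is (Ktrans, ve, vp, delay = 0); for the 2CXM it is (Fp, vp,
#' Fe = Patlak K1, ve, delay = 0). Every hemodynamic entry is floored at a
#' strictly positive minimum so the log transform of the Bayesian fitter is
#' always defined; if a sub-method fails the configured fallback (the floor
#' vector by default) is used and recorded in the provenance.
#'
#' @param model `"2cxm"` or `"etm"`.
#' @param curve Tissue concentration [dce_curve].
#' @param aif Arterial input function [dce_curve].
#' @param config Optional list: `svd_threshold` (default 0.2),
#'   `patlak_window` (default `NULL` = automatic), `baseline_end` (seconds,
#'   default from bolus detection on the AIF), `init_floor` (default 1e-3, in
#'   each parameter's natural unit), `fallback` (named vector overriding the
#'   floor vector on failure).
#' @return An object of class `"dce_init"`: list with `model`, `par` (named
#'   vector, natural units), `provenance` (named character vector).
#' @export
build_init <- function(model = c("2cxm", "etm"), curve, aif, config = list()) {
  model <- match.arg(model)
  curve <- as_curve(curve); aif <- as_curve(aif)
  thr <- config$svd_threshold %||% 0.2
  floorv <- config$init_floor %||% 1e-3
  base_end <- config$baseline_end %||% aif$times[n_baseline_frames(aif)]
  prov <- c()
  grab <- function(expr, what) {
    tryCatch(expr, error = function(e) { NULL })
  }
  pk <- grab(patlak_fit(curve, aif, window = config$patlak_window))
  sv <- grab(svd_deconvolve(curve, aif, threshold_frac = thr))
  ve0 <- grab(auc_ve(curve, aif, baseline_end = base_end, floor = floorv))
  pick <- function(val, name, src) {
    if (is.null(val) || !is.finite(val)) {
      prov[name] <<- "fallback"
      fb <- config$fallback
      if (!is.null(fb) && name %in% names(fb)) return(fb[[name]])
      return(floorv)
    }
    prov[name] <<- src
    max(val, floorv)
  }
  par <- if (model == "etm") {
    c(Ktrans = pick(sv$Ktrans_est, "Ktrans", "svd"),
      ve = pick(ve0, "ve", "auc"),
      vp = pick(pk[["vp"]], "vp", "patlak"),
      delay = 0)
  } else {
    c(Fp = pick(sv$Fp_est, "Fp", "svd"),
      vp = pick(pk[["vp"]], "vp", "patlak"),
      Fe = pick(pk[["K1"]], "Fe", "patlak"),
      ve = pick(ve0, "ve", "auc"),
      delay = 0)
  }
  prov["delay"] <- "fixed"
  structure(list(model = model, par = par, provenance = prov),
            class = "dce_init")
}

#' @export
print.dce_init <- function(x, ...) {
  cat(sprintf("<dce_init> %s: %s\n", x$model,
              paste(sprintf("%s=%.4g", names(x$par), x$par), collapse = ", ")))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
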