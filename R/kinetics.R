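#' Kinetic parameter vectors
#'
#' Constructors for the parameter sets of the three forward models. Units
#' follow the DCE-MRI convention: flows (`Ktrans`, `Fp`, `Fe`, `K1`) in
#' ml/100g/min, volume fractions (`ve`, `vp`) dimensionless (ml/g at unit
#' tissue density), `delay` in seconds. Internally all rate constants are
#' converted to fraction per second.
#'
#' For the two-compartment-exchange model the reported permeability-rate map
#' `K1` is the extravasation flow `Fe`; the composite leakage constant
#' `Ktrans_equiv = Fp * Fe / (Fp + Fe)` is exposed separately via
#' [ktrans_equiv()].
#'
#' @param Ktrans,K1,Fp,Fe Flow-like parameters, ml/100g/min.
#' @param ve,vp Volume fractions in `[0, 1]` (physically).
#' @param delay AIF-to-tissue bolus delay, seconds.
#' @return A named numeric vector of class `"etm_params"`, `"tcxm_params"` or
#'   `"patlak_params"`.
#' @examples
#' etm_params(Ktrans = 10, ve = 0.4, vp = 0.08)
#' ktrans_equiv(Fp = 60, Fe = 12)  # 10 ml/100g/min
#' @export
etm_params <- function(Ktrans, ve, vp, delay = 0) {
  p <- c(Ktrans = Ktrans, ve = ve, vp = vp, delay = delay)
  if (anyNA(p) || any(!is.finite(p))) stop("parameters must be finite", call. = FALSE)
  if (Ktrans > 0 && ve == 0)
    stop("ve must be positive when Ktrans > 0 (kep undefined)", call. = FALSE)
  structure(p, class = "etm_params")
}

#' @rdname etm_params
#' @export
tcxm_params <- function(Fp, vp, Fe, ve, delay = 0) {
  p <- c(Fp = Fp, vp = vp, Fe = Fe, ve = ve, delay = delay)
  if (anyNA(p) || any(!is.finite(p))) stop("parameters must be finite", call. = FALSE)
  if (Fp > 0 && vp == 0)
    stop("vp must be positive when Fp > 0", call. = FALSE)
  if (Fe > 0 && ve == 0)
    stop("ve must be positive when Fe > 0", call. = FALSE)
  structure(p, class = "tcxm_params")
}

#' @rdname etm_params
#' @export
patlak_params <- function(K1, vp) {
  p <- c(K1 = K1, vp = vp)
  if (anyNA(p) || any(!is.finite(p))) stop("parameters must be finite", call. = FALSE)
  structure(p, class = "patlak_params")
}

#' @rdname etm_params
#' @export
ktrans_equiv <- function(Fp, Fe) {
  ifelse(Fp + Fe > 0, Fp * Fe / (Fp + Fe), 0)
}

#' @rdname etm_params
#' @export
kep <- function(Ktrans, ve) Ktrans / ve

# Lower-triangular trapezoid weight matrix for integrating over the sample
# grid: row i holds the weights that turn integrand samples at times[1..i]
# into the integral from times[1] to times[i]. Cached on the last grid seen,
# since voxelwise fitting reuses one grid thousands of times.
.conv_cache <- new.env(parent = emptyenv())

conv_weights <- function(times) {
  if (!is.null(.conv_cache$times) && identical(.conv_cache$times, times))
    return(.conv_cache$W)
  n <- length(times)
  W <- matrix(0, n, n)
  for (i in 2:n) {
    w <- numeric(i)
    dt <- diff(times[1:i])
    w[1L] <- dt[1L] / 2
    w[i] <- dt[i - 1L] / 2
    if (i > 2L) w[2:(i - 1L)] <- (times[3:i] - times[1:(i - 2L)]) / 2
    W[i, 1:i] <- w
  }
  .conv_cache$times <- times
  .conv_cache$W <- W
  W
}

# Signed lag matrix t_i - t_j, cached alongside the weights.
conv_lags <- function(times) {
  if (is.null(.conv_cache$lag_times) || !identical(.conv_cache$lag_times, times)) {
    .conv_cache$lag_times <- times
    .conv_cache$L <- outer(times, times, "-")
  }
  .conv_cache$L
}

#' Delayed convolution of an AIF with an analytic impulse response
#'
#' Discretizes `(Cp(. - delay) * kernel)(t)` on the acquisition grid by the
#' trapezoidal rule. The AIF is shifted by linear interpolation with
#' zero-padding before its first sample; the kernel is evaluated analytically
#' at every lag, so the only discretization error is the trapezoidal
#' quadrature of the product. All forward models share this engine.
#'
#' @param aif A [dce_curve]: the arterial (plasma) input function.
#' @param kernel A vectorized function of lag (seconds) returning the impulse
#'   response.
#' @param delay Bolus delay in seconds, applied to the AIF; continuous, not
#'   snapped to the grid.
#' @param times Output time grid (seconds, strictly increasing).
#' @return A [dce_curve] on `times`.
#' @examples
#' tt <- seq(0, 100, by = 2)
#' aif <- dce_curve(tt, exp(-(tt - 20)^2 / 50))
#' delayed_convolve(aif, function(u) exp(-u / 30), delay = 4, times = tt)
#' @export
delayed_convolve <- function(aif, kernel, delay = 0, times) {
  aif <- as_curve(aif)
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  cpd <- curve_at(aif, times, delay = delay)
  L <- conv_lags(times)
  K <- matrix(0, length(times), length(times))
  low <- L >= 0
  K[low] <- kernel(L[low])
  vals <- as.vector((conv_weights(times) * K) %*% cpd)
  dce_curve(times, vals)
}

# Exact convolution of the piecewise-linear interpolant of cp (sampled on
# `times`) with exp(-alpha * u). Per panel p spanning (t[p-1], t[p]) the
# integral of (linear segment) x exponential has closed-form weights u_p,
# v_p on the segment endpoints; summing panels gives
#   y_i = sum_{p <= i} (cp[p-1] u_p + cp[p] v_p) exp(-alpha (t_i - t_p)),
# assembled as one lower-triangular matrix product. Unlike sampling the
# kernel on the grid, this stays accurate for arbitrarily fast rates
# (alpha * dt >> 1), where the kernel is effectively a delta the grid cannot
# resolve. All exponents are clamped (safe_exp) so non-physical negative
# rates probed by an optimizer give huge finite values, never overflow.
conv_exp <- function(cp, times, alpha) {
  n <- length(times)
  h <- diff(times)
  x <- alpha * h
  E <- safe_exp(-x)
  if (abs(alpha) < 1e-12) {
    u <- h / 2
    v <- h / 2
  } else {
    small <- abs(x) < 1e-5
    phi <- (1 - E) / (alpha^2 * h)    # (1 - e^-x)/(alpha x)
    u <- phi - E / alpha
    v <- 1 / alpha - phi
    u[small] <- h[small] / 2 - alpha * h[small]^2 / 3
    v[small] <- h[small] / 2 - alpha * h[small]^2 / 6
  }
  if (max(h) - min(h) < 1e-9 * mean(h)) {
    # uniform grid: the panel sums obey the linear recurrence
    # y_i = E y_{i-1} + (cp[i-1] u + cp[i] v), solved in O(n)
    b <- c(0, cp[-n] * u + cp[-1L] * v)
    out <- as.vector(stats::filter(b, E[1L], method = "recursive"))
  } else {
    L <- conv_lags(times)
    Elag <- matrix(0, n, n)
    low <- L >= 0
    Elag[low] <- safe_exp(-alpha * L[low])
    A <- Elag * matrix(c(0, v), n, n, byrow = TRUE)
    A[, 1:(n - 1L)] <- A[, 1:(n - 1L)] +
      Elag[, 2:n] * matrix(u, n, n - 1L, byrow = TRUE)
    out <- as.vector(A %*% cp)
  }
  # clamp so that wildly non-physical (negative-rate) excursions probed by
  # an optimizer cost astronomically much but never produce Inf/NaN
  out[!is.finite(out)] <- 1e50
  pmin(pmax(out, -1e50), 1e50)
}

#' Extended Tofts model concentration curve
#'
#' `C(t) = vp * Cp(t - delay) + Ktrans * int Cp(tau - delay)
#' exp(-kep (t - tau)) dtau` with `kep = Ktrans / ve`. The vascular term is
#' added analytically (interpolated, not convolved), and the leakage term
#' integrates the piecewise-linear AIF against the exponential kernel in
#' closed form per sampling panel, which stays accurate however fast the
#' efflux rate is relative to the frame interval. Parameters outside their
#' physical range are tolerated so that unconstrained optimizers can evaluate
#' the model anywhere, except the singular case `ve == 0` with
#' `Ktrans > 0`.
#'
#' @param params An [etm_params] vector (or any named vector with entries
#'   Ktrans, ve, vp, delay).
#' @param aif The arterial input function, a [dce_curve] (plasma
#'   concentration).
#' @param times Output time grid in seconds.
#' @return A [dce_curve].
#' @export
etm_concentration <- function(params, aif, times) {
  p <- as_par(params, c("Ktrans", "ve", "vp"), delay_default = 0)
  aif <- as_curve(aif)
  vasc <- p[["vp"]] * curve_at(aif, times, delay = p[["delay"]])
  if (p[["Ktrans"]] == 0) return(dce_curve(times, vasc))
  if (p[["ve"]] == 0)
    stop("ve must be nonzero when Ktrans > 0", call. = FALSE)
  kt_s <- flow_to_si(p[["Ktrans"]])
  kep_s <- kt_s / p[["ve"]]
  cpd <- curve_at(aif, times, delay = p[["delay"]])
  dce_curve(times, vasc + kt_s * conv_exp(cpd, times, kep_s))
}

#' Two-compartment-exchange model concentration curve
#'
#' The 2CXM impulse response is the biexponential
#' `H(t) = Fp (A exp(-alpha t) + (1 - A) exp(-beta t))` whose rates are the
#' eigenvalues of the plasma/interstitium mass-balance system:
#' with `a = (Fp + Fe)/vp` and `b = Fe/ve` (all rates per second),
#' `alpha, beta = ((a + b) +/- sqrt((a + b)^2 - 4 Fp Fe/(vp ve))) / 2` and
#' `A = (alpha - g)/(alpha - beta)` with `g = Fe/ve + Fe/vp`. The tissue curve
#' is `H` convolved with the delayed AIF, each exponential mode integrated
#' against the piecewise-linear AIF in closed form (accurate even when the
#' fast eigenvalue outruns the frame interval, as it does for vessel-like
#' voxels and in the high-flow limit). Degenerate cases use analytic limits:
#' `Fe = 0` collapses to the one-compartment plasma model
#' `Fp exp(-Fp t / vp)`, and near-confluent eigenvalues are split by a
#' relative 1e-8 before the partial-fraction form.
#'
#' @param params A [tcxm_params] vector (entries Fp, vp, Fe, ve, delay).
#' @inheritParams etm_concentration
#' @return A [dce_curve].
#' @export
tcxm_concentration <- function(params, aif, times) {
  p <- as_par(params, c("Fp", "vp", "Fe", "ve"), delay_default = 0)
  aif <- as_curve(aif)
  if (p[["Fp"]] == 0) return(dce_curve(times, numeric(length(times))))
  if (p[["vp"]] == 0) stop("vp must be nonzero when Fp > 0", call. = FALSE)
  fp <- flow_to_si(p[["Fp"]]); fe <- flow_to_si(p[["Fe"]])
  vp <- p[["vp"]]; ve <- p[["ve"]]
  cpd <- curve_at(aif, times, delay = p[["delay"]])
  if (fe == 0 || ve == 0) {
    if (fe > 0) stop("ve must be nonzero when Fe > 0", call. = FALSE)
    return(dce_curve(times, fp * conv_exp(cpd, times, fp / vp)))
  }
  a <- (fp + fe) / vp
  b <- fe / ve
  disc <- (a + b)^2 - 4 * fp * fe / (vp * ve)
  # disc >= 0 for any real parameters with vp, ve > 0 (it equals
  # (a - b)^2 + 4 fe^2/(vp ve)); clamp roundoff only.
  if (disc < 0) {
    if (disc < -1e-12 * (a + b)^2)
      stop("internal inconsistency: complex eigenvalues", call. = FALSE)
    disc <- 0
  }
  alpha <- ((a + b) + sqrt(disc)) / 2
  beta <- ((a + b) - sqrt(disc)) / 2
  if (min(fp, fe, vp, ve) >= 0 && beta < -1e-12 * alpha)
    stop("internal inconsistency: negative eigenvalue", call. = FALSE)
  g <- b + fe / vp
  if (abs(alpha - beta) < 1e-10 * abs(alpha)) {
    # near-confluent eigenvalues: split them symmetrically by a relative
    # 1e-8 before the partial-fraction form (avoids 0/0; the O(1e-8)
    # perturbation is far below the quadrature tolerance)
    dsp <- 1e-8 * abs(alpha)
    alpha <- alpha + dsp / 2
    beta <- beta - dsp / 2
  }
  A <- (alpha - g) / (alpha - beta)
  vals <- fp * (A * conv_exp(cpd, times, alpha) +
                  (1 - A) * conv_exp(cpd, times, beta))
  dce_curve(times, vals)
}

#' Patlak model concentration curve
#'
#' The linear irreversible-uptake model
#' `C(t) = vp Cp(t) + K1 int_0^t Cp`, with no delay and no back-flux. Exactly
#' linear in its parameters, which makes it the initializer of choice.
#'
#' @param params A [patlak_params] vector (entries K1, vp).
#' @inheritParams etm_concentration
#' @return A [dce_curve].
#' @export
patlak_concentration <- function(params, aif, times) {
  p <- as_par(params, c("K1", "vp"), delay_default = NULL)
  aif <- as_curve(aif)
  cp <- curve_at(aif, times)
  dce_curve(times, p[["vp"]] * cp + flow_to_si(p[["K1"]]) * cumtrapz(times, cp))
}

# exp with the argument capped so that wildly non-physical parameters probed
# by an unconstrained optimizer yield a huge finite cost, never Inf/NaN.
safe_exp <- function(x) exp(pmin(x, 100))

# Coerce a parameter vector/list to named numeric, checking required names.
as_par <- function(params, required, delay_default = 0) {
  p <- unlist(params)
  if (!all(required %in% names(p)))
    stop("parameters must include: ", paste(required, collapse = ", "),
         call. = FALSE)
  if (!is.null(delay_default) && !("delay" %in% names(p)))
    p <- c(p, delay = delay_default)
  if (anyNA(p) || any(!is.finite(p)))
    stop("parameters must be finite", call. = FALSE)
  p
}
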