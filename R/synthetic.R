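#' Population arterial input function (Parker form)
#'
#' Analytic population AIF: a mixture of two Gaussians (first pass and
#' recirculation) plus an exponential washout modulated by a sigmoid, using
#' the published population-average constants (times in minutes internally),
#' shifted by a bolus-arrival offset and zero before arrival. The reference
#' form corresponds to a standard 0.1 mmol/kg dose; `dose_scale` scales the
#' whole curve linearly, so the half-dose protocol simulated here uses
#' `dose_scale = 0.5`. By default the blood curve is converted to plasma
#' concentration with hematocrit 0.45.
#'
#' @param times Time grid, seconds.
#' @param dose_scale Linear amplitude scale relative to the 0.1 mmol/kg
#'   reference bolus; default 0.5 (0.05 mmol/kg).
#' @param t0 Bolus arrival time, seconds; the curve is zero before `t0`.
#' @param hct Hematocrit used to convert blood to plasma concentration;
#'   `NULL` to return the blood-concentration curve.
#' @return A [dce_curve] (plasma concentration, mM, unless `hct = NULL`).
#' @examples
#' aif <- population_aif(seq(0, 298, by = 2))
#' max(aif$values)
#' @export
population_aif <- function(times, dose_scale = 0.5, t0 = 10, hct = 0.45) {
  tm <- (times - t0) / 60                      # minutes since arrival
  A <- c(0.809, 0.330); Tn <- c(0.17046, 0.365); sg <- c(0.0563, 0.132)
  al <- 1.050; be <- 0.1685; s <- 38.078; tau <- 0.483
  g <- A[1] / (sg[1] * sqrt(2 * pi)) * exp(-(tm - Tn[1])^2 / (2 * sg[1]^2)) +
       A[2] / (sg[2] * sqrt(2 * pi)) * exp(-(tm - Tn[2])^2 / (2 * sg[2]^2))
  wash <- al * exp(-be * tm) / (1 + exp(-s * (tm - tau)))
  cb <- dose_scale * (g + wash)
  cb[tm < 0] <- 0
  out <- dce_curve(times, cb)
  if (!is.null(hct)) out <- hct_correct(out, hct)
  out
}

#' Digital reference phantom specification
#'
#' Describes a synthetic brain-like slice with four tissue classes — white
#' matter, tumor rim, tumor core, and vessel — on a rectangular grid, with
#' known ground-truth kinetic parameters per class, the acquisition time
#' axis, and a noise level. Defaults reproduce the simulated acquisition: 2 s
#' frame interval, 5 min duration (150 frames).
#'
#' Default region truths (2CXM parameterization; flows ml/100g/min, volumes
#' fractions): white matter (Fp 12, vp 0.01, Fe 0.5, ve 0.2), tumor rim
#' (Fp 60, vp 0.08, Fe 12, ve 0.4), tumor core (Fp 20, vp 0.03, Fe 6,
#' ve 0.5), vessel (Fp 200, vp 0.9, Fe 0, ve 0.01). The extended-Tofts truth
#' uses the equivalent leakage constant `Ktrans = Fp*Fe/(Fp+Fe)` with the
#' same `ve`, `vp`. These are plausible fixture values chosen inside the
#' physiological fitting ranges, not measured tissue values.
#'
#' @param shape Integer grid shape `c(nx, ny, nz)`; default `c(16, 16, 1)`.
#' @param times Acquisition time axis in seconds; default 150 frames at 2 s.
#' @param snr Signal-to-noise ratio: peak noiseless *tissue* (non-vessel)
#'   concentration divided by the additive Gaussian noise SD. `Inf` for
#'   noiseless.
#' @param jitter Multiplicative log-normal per-voxel parameter jitter SD (on
#'   the log scale); 0 disables.
#' @param truths Named list of per-region 2CXM truth vectors, each with
#'   entries Fp, vp, Fe, ve; regions `wm`, `rim`, `core`, `vessel`.
#' @param low_grade Logical; if `TRUE`, rim leakage and plasma volume are
#'   reduced (Fe and vp halved relative to `truths`) to emulate the weaker
#'   enhancement of low-grade lesions.
#' @param seed Integer seed making generation fully deterministic.
#' @return An object of class `"phantom_spec"`.
#' @export
phantom_spec <- function(shape = c(16, 16, 1),
                         times = seq(0, by = 2, length.out = 150),
                         snr = Inf, jitter = 0,
                         truths = NULL, low_grade = FALSE, seed = 1L) {
  if (length(shape) == 2L) shape <- c(shape, 1L)
  stopifnot(length(shape) == 3L, all(shape >= 1), all(diff(times) > 0))
  default <- list(
    wm     = c(Fp = 12,  vp = 0.01, Fe = 0.5, ve = 0.2),
    rim    = c(Fp = 60,  vp = 0.08, Fe = 12,  ve = 0.4),
    core   = c(Fp = 20,  vp = 0.03, Fe = 6,   ve = 0.5),
    vessel = c(Fp = 200, vp = 0.9,  Fe = 0,   ve = 0.01))
  if (is.null(truths)) truths <- default
  if (low_grade) {
    truths$rim[["Fe"]] <- truths$rim[["Fe"]] / 2
    truths$rim[["vp"]] <- truths$rim[["vp"]] / 2
  }
  structure(list(shape = as.integer(shape), times = times, snr = snr,
                 jitter = jitter, truths = truths, low_grade = low_grade,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> %s grid, %d frames (dt %g s), SNR %s, seed %d\n",
              paste(x$shape, collapse = "x"), length(x$times),
              x$times[2] - x$times[1], format(x$snr), x$seed))
  invisible(x)
}

# Region layout: concentric tumor (core disk inside rim annulus) offset to
# one side, a small vessel patch near a corner, white matter elsewhere.
phantom_regions <- function(shape) {
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  reg <- array("wm", dim = shape)
  cx <- nx * 0.62; cy <- ny * 0.55
  r_core <- min(nx, ny) / 8; r_rim <- min(nx, ny) / 4
  for (i in seq_len(nx)) for (j in seq_len(ny)) {
    r <- sqrt((i - cx)^2 + (j - cy)^2)
    if (r <= r_core) reg[i, j, ] <- "core"
    else if (r <= r_rim) reg[i, j, ] <- "rim"
  }
  vx <- max(1L, round(nx * 0.15)); vy <- max(1L, round(ny * 0.15))
  reg[vx + 0:1, vy, seq_len(nz)] <- "vessel"
  reg
}

#' Generate a digital reference phantom
#'
#' Simulates a dynamic concentration-time series voxel by voxel from the
#' chosen forward model with each region's ground-truth parameters (plus
#' optional per-voxel log-normal jitter), adds Gaussian noise at the SD
#' implied by `spec$snr`, and returns the series together with the
#' ground-truth parameter maps and the AIF used. Deterministic given
#' `(spec, model)` — the seed lives in the spec.
#'
#' @param spec A [phantom_spec].
#' @param model `"2cxm"` or `"etm"`: the forward model generating the voxel
#'   curves (the ETM truth uses the equivalent-leakage parameterization of
#'   the region truths).
#' @param aif Optional [dce_curve] to use as the input function; default
#'   [population_aif] on the spec's time axis.
#' @return A list of class `"dce_phantom"`: `series` (a [dce_series]),
#'   `truth` (named list of 3D truth maps), `aif`, `region` (character
#'   array), `spec`, `model`, `noise_sd`.
#' @export
generate_phantom <- function(spec, model = c("2cxm", "etm"), aif = NULL) {
  model <- match.arg(model)
  stopifnot(inherits(spec, "phantom_spec"))
  for (rg in spec$truths) {
    if (any(rg[c("Fp", "vp", "Fe", "ve")] < 0) ||
        (rg[["Fp"]] > 0 && rg[["vp"]] <= 0) || (rg[["Fe"]] > 0 && rg[["ve"]] <= 0))
      stop("invalid region parameters in phantom spec", call. = FALSE)
  }
  if (is.null(aif)) aif <- population_aif(spec$times)
  reg <- phantom_regions(spec$shape)
  nt <- length(spec$times)
  nvox <- prod(spec$shape)
  pnames <- if (model == "2cxm") c("Fp", "vp", "K1", "ve", "delay")
            else c("Ktrans", "ve", "vp", "delay")
  truth <- lapply(pnames, function(p) array(0, dim = spec$shape))
  names(truth) <- pnames
  dat <- array(0, dim = c(spec$shape, nt))
  set.seed(spec$seed)
  idx <- arrayInd(seq_len(nvox), spec$shape)
  # per-voxel parameters first (jitter), curves second, noise last, so the
  # random stream is reproducible and independent of voxel curve content
  jit <- if (spec$jitter > 0)
    matrix(exp(stats::rnorm(nvox * 4, 0, spec$jitter)), nvox, 4) else
    matrix(1, nvox, 4)
  curves <- matrix(0, nvox, nt)
  for (v in seq_len(nvox)) {
    rg <- spec$truths[[reg[v]]]
    p2 <- rg * c(jit[v, ])  # Fp, vp, Fe, ve
    if (model == "2cxm") {
      curves[v, ] <- tcxm_concentration(
        tcxm_params(p2[["Fp"]], p2[["vp"]], p2[["Fe"]], p2[["ve"]]),
        aif, spec$times)$values
      truth$Fp[v] <- p2[["Fp"]]; truth$vp[v] <- p2[["vp"]]
      truth$K1[v] <- p2[["Fe"]]; truth$ve[v] <- p2[["ve"]]
    } else {
      kt <- ktrans_equiv(p2[["Fp"]], p2[["Fe"]])
      curves[v, ] <- etm_concentration(
        etm_params(kt, p2[["ve"]], p2[["vp"]]), aif, spec$times)$values
      truth$Ktrans[v] <- kt; truth$ve[v] <- p2[["ve"]]; truth$vp[v] <- p2[["vp"]]
    }
  }
  tissue_peak <- max(curves[reg != "vessel", , drop = FALSE])
  noise_sd <- if (is.finite(spec$snr)) tissue_peak / spec$snr else 0
  if (noise_sd > 0)
    curves <- curves + matrix(stats::rnorm(nvox * nt, 0, noise_sd), nvox, nt)
  for (v in seq_len(nvox)) dat[idx[v, 1], idx[v, 2], idx[v, 3], ] <- curves[v, ]
  series <- dce_series(dat, spec$times, mask = array(TRUE, dim = spec$shape))
  structure(list(series = series, truth = truth, aif = aif, region = reg,
                 spec = spec, model = model, noise_sd = noise_sd),
            class = "dce_phantom")
}

#' @export
print.dce_phantom <- function(x, ...) {
  cat(sprintf("<dce_phantom> %s model, %s grid, noise SD %.4g\n",
              x$model, paste(x$spec$shape, collapse = "x"), x$noise_sd))
  invisible(x)
}

#' Simulate a reader-score table
#'
#' Draws ordinal image-quality scores (1-4) from a latent-variable
#' cumulative-threshold model for a full factorial of patients x 2 raters x
#' 2 fitting algorithms x 7 parameter maps x 3 image features (t2b, t2v,
#' oai). The latent quality is a sum of effect shifts plus a per-patient
#' random effect and Gaussian noise, cut at three thresholds.
#'
#' Default effects echo the direction and magnitude of a reader study of
#' LM- versus Bayesian-fitted maps: the Bayesian algorithm shifts latent
#' quality by +1.518, with map, feature, rater and (optional) grade shifts
#' configurable.
#'
#' @param n_patients Number of patients (>= 2); default 42.
#' @param effects Named list of latent shifts: `algorithm` (added for BM),
#'   `map` (named vector over the 7 maps), `feature` (named vector over
#'   t2b/t2v/oai), `rater2`, `grade` (added for high-grade), `intercept`,
#'   and optionally `bm_interaction` — a vector named `"map.feature"`
#'   (e.g. `c(ve_2cxm.t2b = 2)`) added only for BM rows of that map/feature
#'   cell, which plants an algorithm signal in specific predictors. Missing
#'   entries default to the built-ins.
#' @param prop_high Proportion of high-grade patients; default 32/42.
#' @param patient_sd SD of the per-patient random effect (latent units).
#' @param noise_sd SD of the residual latent noise.
#' @param thresholds Three increasing cutpoints mapping latent quality to
#'   scores 1-4.
#' @param seed Integer seed.
#' @return A data.frame with columns patient, grade, rater, algorithm, map,
#'   feature, score (class `"score_table"`).
#' @export
generate_scores <- function(n_patients = 42, effects = list(), prop_high = 32 / 42,
                            patient_sd = 0.5, noise_sd = 1,
                            thresholds = c(1, 2.5, 4), seed = 1L) {
  if (n_patients < 2) stop("need at least two patients", call. = FALSE)
  if (any(diff(thresholds) <= 0) || length(thresholds) != 3L)
    stop("thresholds must be three increasing cutpoints", call. = FALSE)
  maps <- c("K1_2cxm", "vp_2cxm", "Fp_2cxm", "ve_2cxm",
            "Ktrans_etm", "vp_etm", "ve_etm")
  feats <- c("t2b", "t2v", "oai")
  def <- list(
    intercept = 1.25,
    algorithm = 1.518,
    map = c(K1_2cxm = 0, vp_2cxm = 0.745, Fp_2cxm = 1.095, ve_2cxm = 0.213,
            Ktrans_etm = -0.27, vp_etm = 0.475, ve_etm = -0.057),
    feature = c(t2b = 0, t2v = 1.334, oai = 0.830),
    rater2 = 0.194,
    grade = 0,
    bm_interaction = numeric(0))
  for (nm in names(effects)) def[[nm]] <- effects[[nm]]
  set.seed(seed)
  n_high <- round(prop_high * n_patients)
  grade <- c(rep("high", n_high), rep("low", n_patients - n_high))
  pat_re <- stats::rnorm(n_patients, 0, patient_sd)
  tab <- expand.grid(patient = seq_len(n_patients), rater = c(1L, 2L),
                     algorithm = c("LM", "BM"), map = maps, feature = feats,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  latent <- def$intercept +
    def$algorithm * (tab$algorithm == "BM") +
    def$map[tab$map] + def$feature[tab$feature] +
    def$rater2 * (tab$rater == 2L) +
    def$grade * (grade[tab$patient] == "high") +
    pat_re[tab$patient] +
    stats::rnorm(nrow(tab), 0, noise_sd)
  if (length(def$bm_interaction)) {
    cell <- paste(tab$map, tab$feature, sep = ".")
    hit <- match(cell, names(def$bm_interaction))
    add <- ifelse(is.na(hit), 0, def$bm_interaction[hit])
    latent <- latent + add * (tab$algorithm == "BM")
  }
  tab$grade <- grade[tab$patient]
  tab$score <- as.integer(cut(latent, c(-Inf, thresholds, Inf), labels = FALSE))
  tab <- tab[, c("patient", "grade", "rater", "algorithm", "map", "feature",
                 "score")]
  class(tab) <- c("score_table", "data.frame")
  tab
}
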