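#' Dynamic 4D concentration series
#'
#' Container for a 4D (x, y, z, t) concentration-time volume with its time
#' axis, voxel geometry, and an optional tissue mask.
#'
#' @param data 4D numeric array (x, y, z, t). A 3D array is treated as a
#'   single-slice (x, y, 1, t) volume.
#' @param times Time axis in seconds, length equal to the 4th dimension.
#' @param voxdim Voxel size in mm, length 3.
#' @param mask Optional logical 3D array matching the spatial shape.
#' @return An object of class `"dce_series"`.
#' @export
dce_series <- function(data, times, voxdim = c(1, 1, 1), mask = NULL) {
  if (length(dim(data)) == 3L)
    dim(data) <- c(dim(data)[1:2], 1L, dim(data)[3])
  if (length(dim(data)) != 4L)
    stop("'data' must be a 4D (x, y, z, t) array", call. = FALSE)
  if (dim(data)[4] != length(times))
    stop("time axis length must match the 4th dimension", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  if (!is.null(mask)) {
    if (!identical(dim(mask), dim(data)[1:3]))
      stop("mask shape must equal the spatial shape", call. = FALSE)
    mask <- array(as.logical(mask), dim = dim(mask))
  }
  structure(list(data = data, times = as.numeric(times),
                 voxdim = as.numeric(voxdim), mask = mask),
            class = "dce_series")
}

#' @export
print.dce_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<dce_series> %dx%dx%d voxels, %d frames over [%g, %g] s\n",
              d[1], d[2], d[3], d[4], x$times[1], x$times[length(x$times)]))
  invisible(x)
}

#' Read a 4D NIfTI series with a JSON sidecar
#'
#' The sidecar supplies what NIfTI headers carry unreliably: the time axis
#' (`times`, seconds, or `dt` + optional `t0`) and optionally the number of
#' pre-bolus baseline frames (`n_baseline`).
#'
#' @param path Path to a NIfTI file (.nii or .nii.gz).
#' @param sidecar Path to the JSON sidecar; default `path` with the NIfTI
#'   extension replaced by `.json`. May be `NULL` if `times` is given.
#' @param times Optional explicit time axis, overriding the sidecar.
#' @return A [dce_series] (with attribute `"n_baseline"` if the sidecar sets
#'   it).
#' @export
read_series <- function(path, sidecar = NULL, times = NULL) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  arr <- array(as.vector(arr), dim = dim(arr))  # drop NIfTI attributes
  vd <- RNifti::pixdim(img)[1:3]
  n_base <- NULL
  if (is.null(times)) {
    if (is.null(sidecar)) sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
    if (!file.exists(sidecar))
      stop("no time axis: supply 'times' or a JSON sidecar", call. = FALSE)
    sc <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    times <- if (!is.null(sc$times)) sc$times else
      (if (is.null(sc$t0)) 0 else sc$t0) + sc$dt * (seq_len(dim(arr)[4]) - 1)
    n_base <- sc$n_baseline
  }
  out <- dce_series(arr, times, voxdim = vd)
  if (!is.null(n_base)) attr(out, "n_baseline") <- n_base
  out
}

#' Write parameter maps as NIfTI volumes
#'
#' One 3D NIfTI per parameter, named `{model}_{algorithm}_{param}.nii.gz`,
#' with units and the model/algorithm tags recorded in the header description
#' field.
#'
#' @param maps A `"dce_maps"` object from [fit_volume()].
#' @param dir Output directory (created if needed).
#' @param voxdim Voxel size in mm.
#' @return Character vector of the paths written, invisibly.
#' @export
write_maps <- function(maps, dir, voxdim = c(1, 1, 1)) {
  stopifnot(inherits(maps, "dce_maps"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  alg <- if (maps$method == "bayes") "bm" else "lm"
  paths <- character(0)
  for (pn in names(maps$maps)) {
    fn <- file.path(dir, sprintf("%s_%s_%s.nii.gz", maps$model, alg, pn))
    img <- RNifti::asNifti(maps$maps[[pn]])
    RNifti::pixdim(img) <- voxdim
    img$descrip <- sprintf("%s [%s] %s/%s", pn, param_units(pn), maps$model, alg)
    RNifti::writeNifti(img, fn)
    paths <- c(paths, fn)
  }
  invisible(paths)
}

param_units <- function(p) {
  switch(p, Fp = , Fe = , K1 = , Ktrans = "ml/100g/min",
         ve = , vp = "ml/g", delay = "s", "")
}

#' In-plane 3x3 uniform smoothing of a dynamic series
#'
#' Applies a 3x3 boxcar filter to every slice of every frame, the spatial
#' smoothing used on concentration maps before voxelwise fitting. Edge (and,
#' if a mask is present, out-of-mask) neighbors are dropped and the kernel
#' renormalized over the remaining ones; no smoothing across slices.
#'
#' @param series A [dce_series] with in-plane extent at least 3x3.
#' @return A smoothed [dce_series] (mask carried over unchanged).
#' @export
smooth_series <- function(series) {
  stopifnot(inherits(series, "dce_series"))
  d <- dim(series$data)
  if (d[1] < 3L || d[2] < 3L)
    stop("in-plane extent must be at least 3x3", call. = FALSE)
  m <- series$mask
  out <- series$data
  for (z in seq_len(d[3])) {
    mz <- if (is.null(m)) matrix(TRUE, d[1], d[2]) else m[, , z]
    cnt <- box3_sum(mz * 1)
    for (tt in seq_len(d[4])) {
      fr <- series$data[, , z, tt]
      fr[!mz] <- 0
      sm <- box3_sum(fr) / pmax(cnt, 1)
      sm[!mz] <- series$data[, , z, tt][!mz]
      out[, , z, tt] <- sm
    }
  }
  dce_series(out, series$times, series$voxdim, series$mask)
}

# Sum over the 3x3 neighborhood of each entry (zero beyond the edges),
# computed by shifted additions.
box3_sum <- function(mat) {
  nr <- nrow(mat); nc <- ncol(mat)
  p <- matrix(0, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- mat
  out <- matrix(0, nr, nc)
  for (di in 0:2) for (dj in 0:2)
    out <- out + p[di + seq_len(nr), dj + seq_len(nc)]
  out
}

#' Extract an arterial input function from a voxel ROI
#'
#' Averages the time-curves of the given voxels from the *unsmoothed* series
#' (smoothing would dilute the arterial peak), subtracts the pre-bolus
#' baseline mean, and optionally applies a hematocrit correction to convert
#' blood to plasma concentration.
#'
#' @param series A [dce_series].
#' @param roi Matrix of voxel indices, one row per voxel, columns (x, y, z);
#'   a vector of length 3 selects a single voxel.
#' @param n_baseline Number of leading pre-bolus frames whose mean is
#'   subtracted; 0 disables baseline subtraction.
#' @param hct Hematocrit for blood-to-plasma conversion; `NULL` (default)
#'   leaves the curve unscaled.
#' @return A [dce_curve].
#' @export
extract_aif <- function(series, roi, n_baseline = 5L, hct = NULL) {
  stopifnot(inherits(series, "dce_series"))
  if (is.vector(roi)) roi <- matrix(roi, nrow = 1L)
  roi <- as.matrix(roi)
  if (nrow(roi) == 0L) stop("ROI is empty", call. = FALSE)
  d <- dim(series$data)
  if (any(roi < 1) || any(roi[, 1] > d[1]) || any(roi[, 2] > d[2]) ||
      any(roi[, 3] > d[3]))
    stop("ROI indices out of bounds", call. = FALSE)
  curves <- t(apply(roi, 1L, function(v) series$data[v[1], v[2], v[3], ]))
  avg <- colMeans(curves)
  if (n_baseline > 0L) avg <- avg - mean(avg[seq_len(min(n_baseline, length(avg)))])
  out <- dce_curve(series$times, avg)
  if (!is.null(hct)) out <- hct_correct(out, hct)
  out
}

#' Voxelwise fitting of a dynamic series into parameter maps
#'
#' Runs the full per-voxel estimation chain — initialization via
#' [build_init()], then [dce_fit()] with the chosen model and algorithm — for
#' every in-mask voxel and assembles one 3D map per parameter. Voxels where
#' fitting fails are set to `NaN` and counted. Voxels are independent, so the
#' result does not depend on processing order.
#'
#' @param series A [dce_series]. If it has no mask, one is derived as the
#'   voxels whose temporal peak exceeds `mask_k` times the baseline SD.
#' @param aif The arterial input function, a [dce_curve].
#' @param model `"2cxm"` or `"etm"`.
#' @param method `"lm"` or `"bayes"`.
#' @param config Optional list passed to [build_init()] (keys svd_threshold,
#'   patlak_window, baseline_end, init_floor).
#' @param control A [dce_control()] list for the fitters.
#' @param ranges A [dce_ranges()] list (LM penalty bounds).
#' @param mask_k Threshold multiplier for the derived mask.
#' @return An object of class `"dce_maps"`: list with `maps` (named list of
#'   3D arrays, including the 2CXM `K1` map which reports `Fe`), `model`,
#'   `method`, `n_failed`, `n_fit`.
#' @export
fit_volume <- function(series, aif, model = c("2cxm", "etm"),
                       method = c("bayes", "lm"), config = list(),
                       control = dce_control(), ranges = dce_ranges(),
                       mask_k = 3) {
  model <- match.arg(model); method <- match.arg(method)
  stopifnot(inherits(series, "dce_series"))
  aif <- as_curve(aif)
  d <- dim(series$data)
  mask <- series$mask
  if (is.null(mask)) {
    nb <- max(2L, n_baseline_frames(aif))
    mask <- apply(series$data, 1:3, function(y)
      max(y) > mask_k * stats::sd(y[seq_len(nb)]) && any(y != 0))
  }
  vox <- which(mask, arr.ind = TRUE)
  if (nrow(vox) == 0L)
    stop("dce_pipeline_error: no voxels selected for fitting", call. = FALSE)
  pnames <- if (model == "2cxm") c("Fp", "vp", "K1", "ve", "delay")
            else c("Ktrans", "ve", "vp", "delay")
  maps <- lapply(pnames, function(p) array(NaN, dim = d[1:3]))
  names(maps) <- pnames
  n_failed <- 0L
  for (v in seq_len(nrow(vox))) {
    i <- vox[v, 1]; j <- vox[v, 2]; k <- vox[v, 3]
    curve <- dce_curve(series$times, series$data[i, j, k, ])
    est <- tryCatch({
      fit <- dce_fit(curve, aif, model = model, method = method,
                     config = config, control = control, ranges = ranges)
      coef(fit)
    }, error = function(e) NULL)
    if (is.null(est)) { n_failed <- n_failed + 1L; next }
    if (model == "2cxm") {
      maps$Fp[i, j, k] <- est[["Fp"]]; maps$vp[i, j, k] <- est[["vp"]]
      maps$K1[i, j, k] <- est[["Fe"]]; maps$ve[i, j, k] <- est[["ve"]]
      maps$delay[i, j, k] <- est[["delay"]]
    } else {
      maps$Ktrans[i, j, k] <- est[["Ktrans"]]; maps$ve[i, j, k] <- est[["ve"]]
      maps$vp[i, j, k] <- est[["vp"]]; maps$delay[i, j, k] <- est[["delay"]]
    }
  }
  out <- structure(list(maps = maps, model = model, method = method,
                        n_failed = n_failed, n_fit = nrow(vox)),
                   class = "dce_maps")
  if (n_failed > nrow(vox) / 2)
    stop(sprintf("dce_pipeline_error: %d of %d voxel fits failed",
                 n_failed, nrow(vox)), call. = FALSE)
  out
}

#' @export
print.dce_maps <- function(x, ...) {
  cat(sprintf("<dce_maps> %s/%s: %s; %d voxels fit, %d failed\n",
              x$model, x$method, paste(names(x$maps), collapse = ", "),
              x$n_fit, x$n_failed))
  invisible(x)
}

# Number of frames before bolus arrival on a curve (first exceedance of
# baseline mean + 5 SD, baseline = first 5 frames), at least 1.
n_baseline_frames <- function(curve, n0 = 5L, k = 5) {
  v <- curve$values
  n0 <- min(n0, length(v) - 1L)
  thr <- mean(v[seq_len(n0)]) + k * max(stats::sd(v[seq_len(n0)]), 1e-12)
  hit <- which(v > thr)
  if (length(hit) == 0L) return(n0)
  max(1L, hit[1L] - 1L)
}
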