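#' Parameter-map recovery report
#'
#' Compares estimated parameter maps against ground truth: per-parameter
#' bias, RMSE, Pearson correlation, and the out-of-range voxel fraction —
#' the share of estimates outside the physiological ranges, which
#' operationalizes the "spurious voxel" rate that degrades leakage maps.
#' NaN voxels (failed fits) are excluded pairwise.
#'
#' @param truth Named list of numeric arrays/vectors (ground-truth maps), or
#'   the `truth` element of a [generate_phantom()] result.
#' @param estimate A `"dce_maps"` object or a named list of arrays matching
#'   `truth`'s shapes.
#' @param ranges A [dce_ranges()] list defining out-of-range.
#' @param params Which parameters to report; default the intersection of the
#'   two map sets, minus `delay` when truth has none.
#' @return A data.frame of class `"recovery_report"` with columns param,
#'   bias, rmse, r, oor_frac, n.
#' @export
recovery_report <- function(truth, estimate, ranges = dce_ranges(),
                            params = NULL) {
  est_maps <- if (inherits(estimate, "dce_maps")) estimate$maps else estimate
  if (is.null(params)) params <- intersect(names(truth), names(est_maps))
  if (length(params) == 0L) stop("no common parameters to compare", call. = FALSE)
  rows <- lapply(params, function(pn) {
    tv <- as.vector(truth[[pn]]); ev <- as.vector(est_maps[[pn]])
    if (length(tv) != length(ev)) stop("shape mismatch for ", pn, call. = FALSE)
    ok <- is.finite(tv) & is.finite(ev)
    tv <- tv[ok]; ev <- ev[ok]
    if (length(tv) < 2L)
      stop("insufficient data: fewer than 2 valid voxels for ", pn,
           call. = FALSE)
    d <- ev - tv
    r <- if (stats::sd(tv) == 0 || stats::sd(ev) == 0) {
      if (all(d == 0)) 1 else NA_real_
    } else stats::cor(tv, ev)
    rg <- range_for(ranges, pn)
    data.frame(param = pn, bias = mean(d), rmse = sqrt(mean(d^2)), r = r,
               oor_frac = mean(ev < rg[1] | ev > rg[2]), n = length(tv))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("recovery_report", "data.frame")
  out
}

#' Area under the ROC curve
#'
#' Nonparametric AUC by the rank (pairwise-probability) definition: the
#' probability that a randomly chosen positive scores higher than a randomly
#' chosen negative, ties counting one half. Also returns the ROC curve
#' points.
#'
#' @param labels Binary labels (logical, 0/1, or a two-level factor; the
#'   second level / `TRUE` / `1` is the positive class).
#' @param scores Numeric scores, higher = more positive.
#' @return A list with `auc` and `points` (data.frame fpr, tpr, threshold).
#' @export
roc_auc <- function(labels, scores) {
  if (is.factor(labels)) labels <- labels == levels(labels)[2L]
  labels <- as.logical(labels)
  if (anyNA(labels) || anyNA(scores)) stop("missing values", call. = FALSE)
  if (length(labels) != length(scores)) stop("length mismatch", call. = FALSE)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L)
    stop("both classes must be present", call. = FALSE)
  rk <- rank(scores)                       # midranks handle ties
  auc <- (sum(rk[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thr <- sort(unique(scores), decreasing = TRUE)
  pts <- t(vapply(thr, function(th) c(
    fpr = sum(!labels & scores >= th) / n_neg,
    tpr = sum(labels & scores >= th) / n_pos), numeric(2)))
  points <- rbind(data.frame(fpr = 0, tpr = 0, threshold = Inf),
                  data.frame(fpr = pts[, 1], tpr = pts[, 2], threshold = thr))
  list(auc = auc, points = points)
}

#' Wilcoxon signed-rank test
#'
#' Paired signed-rank test with the exact null distribution computed by full
#' enumeration of the 2^n sign patterns for n <= 12 non-zero differences
#' (midranks for tied magnitudes), and a normal approximation with tie
#' correction and continuity correction otherwise. Zero differences are
#' dropped; if all differences are zero the result is degenerate with
#' p = 1.
#'
#' @param x Numeric vector.
#' @param y Optional paired vector; differences are `x - y` (or `x` itself
#'   when `y` is `NULL`).
#' @param exact_max Largest n for which exact enumeration is used.
#' @return A list with `W` (sum of ranks of positive differences), `p`
#'   (two-sided), `n` (non-zero differences), `exact`, `degenerate`.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, exact_max = 12L) {
  d <- if (is.null(y)) x else x - y
  if (!is.null(y) && length(x) != length(y))
    stop("paired vectors must have equal length", call. = FALSE)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    return(list(W = NA_real_, p = 1, n = 0L, exact = TRUE, degenerate = TRUE))
  rk <- rank(abs(d))
  W <- sum(rk[d > 0])
  if (n <= exact_max) {
    # distribution of W over all 2^n equally likely sign assignments
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    Ws <- as.vector(signs %*% rk)
    p <- min(1, 2 * min(mean(Ws <= W), mean(Ws >= W)))
    list(W = W, p = p, n = n, exact = TRUE, degenerate = FALSE)
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(rk)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
    z <- (W - mu - 0.5 * sign(W - mu)) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    list(W = W, p = p, n = n, exact = FALSE, degenerate = FALSE)
  }
}

#' Tumor-grade discrimination from normalized map means
#'
#' For each subject, averages a parameter map over the tumor mask and
#' normalizes by the mean over non-affected white matter; then compares
#' high- versus low-grade subjects by a rank test and by the AUC. Because
#' the two grade groups are independent subjects, the default test is the
#' unpaired rank-sum (Mann-Whitney) form; a paired signed-rank variant is
#' available for matched designs.
#'
#' @param maps List over subjects of 3D parameter arrays (one parameter).
#' @param tumor_masks,wm_masks Lists over subjects of logical arrays.
#' @param grades Character/factor vector, `"high"` or `"low"`, per subject.
#' @param paired Use the paired signed-rank test instead of rank-sum
#'   (requires equal group sizes in matched order).
#' @return A list with `ratios` (named by grade), `p`, `auc`, `excluded`
#'   (subjects with zero white-matter mean).
#' @export
grade_discrimination <- function(maps, tumor_masks, wm_masks, grades,
                                 paired = FALSE) {
  ns <- length(maps)
  stopifnot(length(tumor_masks) == ns, length(wm_masks) == ns,
            length(grades) == ns)
  ratios <- rep(NA_real_, ns)
  for (s in seq_len(ns)) {
    if (!any(tumor_masks[[s]]) || !any(wm_masks[[s]]))
      stop("empty mask for subject ", s, call. = FALSE)
    wm <- mean(maps[[s]][wm_masks[[s]]], na.rm = TRUE)
    if (!is.finite(wm) || wm == 0) next
    ratios[s] <- mean(maps[[s]][tumor_masks[[s]]], na.rm = TRUE) / wm
  }
  keep <- is.finite(ratios)
  grades <- as.character(grades)[keep]
  ratios_k <- ratios[keep]
  hi <- ratios_k[grades == "high"]; lo <- ratios_k[grades == "low"]
  if (length(hi) < 2L || length(lo) < 2L)
    stop("insufficient data: need at least two subjects per grade group",
         call. = FALSE)
  p <- if (paired) wilcoxon_signed_rank(hi, lo)$p else
    stats::wilcox.test(hi, lo, exact = FALSE)$p.value
  auc <- roc_auc(grades == "high", ratios_k)$auc
  list(ratios = stats::setNames(ratios_k, grades), p = p, auc = auc,
       excluded = which(!keep))
}

#' Repeated-split penalized logistic classification of the fitting algorithm
#'
#' Asks whether reader scores alone identify which fitting algorithm
#' produced a map set. The score table is reshaped to one row per (patient,
#' rater, algorithm) with 21 predictors (7 maps x 3 features); each
#' repetition draws a random train/test split (default 120/48), fits an
#' L1-penalized logistic regression of algorithm on the training scores with
#' the penalty chosen by 5-fold cross-validation, and evaluates the held-out
#' AUC. Selection frequencies count how often each predictor carries a
#' non-zero coefficient.
#'
#' @param scores A [generate_scores()] table (or any data.frame with columns
#'   patient, rater, algorithm, map, feature, score).
#' @param n_train,n_test Split sizes; must sum to the number of reshaped
#'   rows.
#' @param reps Number of random splits.
#' @param seed Integer seed; the whole experiment is deterministic given it.
#' @param lambda Which cross-validated penalty to use, `"lambda.1se"`
#'   (default, sparser) or `"lambda.min"`.
#' @return A list of class `"algo_classification"`: `auc` (per repetition),
#'   `mean_auc`, `lowest_auc`, `frac_auc1`, `selection_freq` (named, per
#'   predictor), `reps`.
#' @export
classify_algorithm <- function(scores, n_train = 120, n_test = 48,
                               reps = 1000, seed = 1L,
                               lambda = c("lambda.1se", "lambda.min")) {
  lambda <- match.arg(lambda)
  wide <- reshape_scores(scores)
  X <- as.matrix(wide[, -(1:3)])
  yv <- wide$algorithm == "BM"
  nr <- nrow(wide)
  if (n_train + n_test != nr)
    stop(sprintf("n_train + n_test (%d) must equal the number of rows (%d)",
                 n_train + n_test, nr), call. = FALSE)
  set.seed(seed)
  aucs <- numeric(reps)
  sel <- matrix(0, reps, ncol(X), dimnames = list(NULL, colnames(X)))
  for (rp in seq_len(reps)) {
    repeat {
      tr <- sample(nr, n_train)
      if (length(unique(yv[tr])) == 2L && length(unique(yv[-tr])) == 2L) break
    }
    cv <- glmnet::cv.glmnet(X[tr, ], factor(yv[tr]), family = "binomial",
                            alpha = 1, nfolds = 5)
    pred <- as.vector(stats::predict(cv, X[-tr, ], s = lambda,
                                     type = "link"))
    aucs[rp] <- roc_auc(yv[-tr], pred)$auc
    cf <- as.matrix(stats::coef(cv, s = lambda))[-1L, 1L]
    sel[rp, ] <- cf != 0
  }
  structure(list(auc = aucs, mean_auc = mean(aucs), lowest_auc = min(aucs),
                 frac_auc1 = mean(aucs == 1), selection_freq = colMeans(sel),
                 reps = reps),
            class = "algo_classification")
}

#' @export
print.algo_classification <- function(x, ...) {
  cat(sprintf(paste0("<algo_classification> %d repetitions: mean AUC %.3f, ",
                     "lowest %.3f, AUC = 1 in %.0f%%\n"),
              x$reps, x$mean_auc, x$lowest_auc, 100 * x$frac_auc1))
  top <- sort(x$selection_freq, decreasing = TRUE)[1:3]
  cat("top predictors:",
      paste(sprintf("%s (%.0f%%)", names(top), 100 * top), collapse = ", "),
      "\n")
  invisible(x)
}

# Long score table -> one row per (patient, rater, algorithm) with 21
# map-by-feature predictor columns.
reshape_scores <- function(scores) {
  need <- c("patient", "rater", "algorithm", "map", "feature", "score")
  if (!all(need %in% names(scores)))
    stop("score table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  scores$pred <- paste(scores$map, scores$feature, sep = ".")
  wide <- stats::reshape(
    scores[, c("patient", "rater", "algorithm", "pred", "score")],
    idvar = c("patient", "rater", "algorithm"), timevar = "pred",
    direction = "wide")
  names(wide) <- sub("^score\\.", "", names(wide))
  wide[order(wide$patient, wide$rater, wide$algorithm), ]
}
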