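test_that("recovery report handles exact and shifted estimates", {
  truth <- list(ve = array(0.4, c(4, 4, 1)))
  exact <- recovery_report(truth, list(ve = truth$ve))
  expect_equal(exact$bias, 0)
  expect_equal(exact$rmse, 0)
  expect_equal(exact$r, 1)
  expect_equal(exact$oor_frac, 0)
  shifted <- recovery_report(truth, list(ve = truth$ve + 0.1))
  expect_equal(shifted$bias, 0.1, tolerance = 1e-12)
  expect_equal(shifted$rmse, 0.1, tolerance = 1e-12)
})

test_that("recovery report matches direct summation on random maps", {
  set.seed(41)
  tv <- array(runif(60, 0, 0.8), c(60))
  ev <- tv + rnorm(60, 0.02, 0.1)
  ev[c(3, 7)] <- NA
  rep <- recovery_report(list(ve = tv), list(ve = ev))
  ok <- !is.na(ev)
  d <- ev[ok] - tv[ok]
  expect_equal(rep$bias, sum(d) / length(d), tolerance = 1e-12)
  expect_equal(rep$rmse, sqrt(sum(d^2) / length(d)), tolerance = 1e-12)
  expect_equal(rep$r, cor(tv[ok], ev[ok]), tolerance = 1e-12)
  expect_equal(rep$oor_frac, mean(ev[ok] < 0 | ev[ok] > 1), tolerance = 1e-12)
  expect_gte(rep$rmse, abs(rep$bias))
  expect_error(recovery_report(list(ve = 1), list(ve = 2)),
               "insufficient data")
})

test_that("ROC AUC equals the exhaustive pairwise oracle", {
  set.seed(42)
  for (i in 1:10) {
    n <- sample(6:20, 1)
    labels <- c(TRUE, FALSE, runif(n - 2) > 0.5)
    scores <- sample(1:5, n, replace = TRUE)   # heavy ties
    expect_equal(roc_auc(labels, scores)$auc,
                 pairwise_auc_oracle(labels, scores), tolerance = 1e-12)
  }
})

test_that("ROC AUC is 1 for separation, ~0.5 for noise, errors one-class", {
  expect_equal(roc_auc(c(rep(TRUE, 5), rep(FALSE, 5)),
                       c(6:10, 1:5))$auc, 1)
  set.seed(43)
  labels <- runif(10000) > 0.5
  expect_lt(abs(roc_auc(labels, rnorm(10000))$auc - 0.5), 0.02)
  expect_error(roc_auc(rep(TRUE, 5), 1:5), "both classes")
})

test_that("ROC AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(44)
  labels <- runif(50) > 0.4
  scores <- rnorm(50) + labels
  ours <- roc_auc(labels, scores)$auc
  theirs <- as.numeric(pROC::auc(pROC::roc(
    labels, scores, direction = "<", levels = c(FALSE, TRUE), quiet = TRUE)))
  expect_equal(ours, theirs, tolerance = 1e-12)
})

test_that("signed-rank test reproduces hand-checkable cases", {
  same <- wilcoxon_signed_rank(1:8, 1:8)
  expect_true(same$degenerate)
  expect_equal(same$p, 1)
  all_pos <- wilcoxon_signed_rank(c(2, 4, 6, 8, 10, 12), c(1, 2, 3, 4, 5, 6))
  expect_equal(all_pos$W, 21)
  expect_equal(all_pos$p, 2 / 64)
})

test_that("exact signed-rank mode matches the generating-polynomial oracle", {
  set.seed(45)
  for (i in 1:10) {
    n <- sample(4:12, 1)
    d <- round(rnorm(n), 1)          # rounding induces occasional ties
    d <- d[d != 0]
    if (length(d) < 3) next
    ours <- wilcoxon_signed_rank(d)
    expect_true(ours$exact)
    expect_equal(ours$p, genpoly_wilcoxon_oracle(d), tolerance = 1e-12)
  }
})

test_that("signed-rank agrees with stats::wilcox.test in both regimes", {
  set.seed(46)
  x <- rnorm(10); y <- rnorm(10)
  expect_equal(wilcoxon_signed_rank(x, y)$p,
               wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value,
               tolerance = 1e-12)
  x2 <- rnorm(40); y2 <- rnorm(40)
  expect_equal(wilcoxon_signed_rank(x2, y2)$p,
               wilcox.test(x2, y2, paired = TRUE, exact = FALSE,
                           correct = TRUE)$p.value,
               tolerance = 1e-10)
})

test_that("grade discrimination separates a planted vp effect", {
  set.seed(47)
  n <- 20
  grades <- rep(c("high", "low"), each = n / 2)
  maps <- tumor <- wm <- vector("list", n)
  for (s in seq_len(n)) {
    m <- array(1, c(4, 4, 1))
    tumor[[s]] <- array(c(rep(TRUE, 4), rep(FALSE, 12)), c(4, 4, 1))
    wm[[s]] <- array(c(rep(FALSE, 12), rep(TRUE, 4)), c(4, 4, 1))
    lift <- if (grades[s] == "high") 3 else 1
    m[tumor[[s]]] <- lift * exp(rnorm(4, 0, 0.2))
    maps[[s]] <- m
  }
  out <- grade_discrimination(maps, tumor, wm, grades)
  expect_gt(out$auc, 0.9)
  expect_lt(out$p, 0.05)
})

test_that("grade discrimination is null-calibrated and guards degeneracy", {
  set.seed(48)
  n <- 40
  grades <- rep(c("high", "low"), each = n / 2)
  maps <- lapply(seq_len(n), function(s) array(exp(rnorm(8)), c(8, 1, 1)))
  tumor <- rep(list(array(c(rep(TRUE, 4), rep(FALSE, 4)), c(8, 1, 1))), n)
  wm <- rep(list(array(c(rep(FALSE, 4), rep(TRUE, 4)), c(8, 1, 1))), n)
  out <- grade_discrimination(maps, tumor, wm, grades)
  expect_lt(abs(out$auc - 0.5), 0.25)
  expect_error(grade_discrimination(maps[1:2], tumor[1:2], wm[1:2],
                                    c("high", "low")),
               "insufficient data")
})

test_that("subjects with zero white-matter mean are excluded", {
  set.seed(49)
  n <- 10
  grades <- rep(c("high", "low"), each = n / 2)
  maps <- lapply(seq_len(n), function(s) array(runif(8, 1, 2), c(8, 1, 1)))
  tumor <- rep(list(array(c(rep(TRUE, 4), rep(FALSE, 4)), c(8, 1, 1))), n)
  wm <- rep(list(array(c(rep(FALSE, 4), rep(TRUE, 4)), c(8, 1, 1))), n)
  maps[[3]][wm[[3]]] <- 0
  out <- grade_discrimination(maps, tumor, wm, grades)
  expect_equal(out$excluded, 3)
  expect_equal(length(out$ratios), n - 1)
})

test_that("algorithm classification is deterministic given a seed", {
  st <- generate_scores(n_patients = 42, seed = 50)
  a <- classify_algorithm(st, reps = 2, seed = 51)
  b <- classify_algorithm(st, reps = 2, seed = 51)
  expect_identical(a$auc, b$auc)
  expect_identical(a$selection_freq, b$selection_freq)
  expect_error(classify_algorithm(st, n_train = 100, n_test = 48, reps = 1),
               "must equal")
})

test_that("a strong real algorithm effect is detected with high AUC", {
  st <- generate_scores(n_patients = 42,
                        effects = list(algorithm = 1.518), seed = 52)
  out <- classify_algorithm(st, reps = 10, seed = 53)
  expect_gt(out$mean_auc, 0.8)
  expect_true(all(out$auc >= 0 & out$auc <= 1))
})
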