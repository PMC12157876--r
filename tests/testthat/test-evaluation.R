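test_that("window segmentation follows the stride arithmetic", {
  plan <- windowing_plan(10, 0.2)
  expect_equal(plan$stride_s, 8)
  w <- segment_windows(stats::rnorm(12000), 100, plan)
  expect_length(w, 14L) # floor((12000 - 1000)/800) + 1
  expect_equal(attr(w[[1]], "start"), 1L)
  expect_equal(attr(w[[2]], "start"), 801)
  expect_true(all(lengths(w) == 1000L))
  expect_length(segment_windows(stats::rnorm(1000), 100, plan), 1L)
  expect_warning(out <- segment_windows(stats::rnorm(900), 100, plan),
                 "shorter")
  expect_length(out, 0L)
})

test_that("window counts agree with brute-force enumeration", {
  set.seed(20)
  for (i in 1:100) {
    n <- sample(1000:20000, 1)
    window_s <- sample(5:60, 1)
    overlap <- stats::runif(1, 0, 0.9)
    plan <- windowing_plan(window_s, overlap)
    fs <- 100
    w <- window_s * fs
    if (n < w) next
    stride <- round(plan$stride_s * fs)
    got <- length(suppressWarnings(segment_windows(numeric(n), fs, plan)))
    expect_equal(got, brute_window_count(n, w, stride))
  }
})

test_that("grouped folds partition subjects with balanced sizes", {
  fa <- grouped_kfold(paste0("S", 1:5), k = 5, seed = 1)
  expect_equal(lengths(fa$folds), rep(1L, 5))
  ids <- paste0("S", 1:163)
  grp <- rep(c("control", "pd"), c(72, 91))
  fa <- grouped_kfold(ids, grp, k = 10, seed = 2)
  expect_true(all(lengths(fa$folds) %in% c(16L, 17L)))
  expect_setequal(unlist(fa$folds), ids)
  expect_equal(anyDuplicated(unlist(fa$folds)), 0L)
  # stratification: each fold's PD share close to the cohort share
  pd_per_fold <- vapply(fa$folds, function(f) sum(grp[match(f, ids)] == "pd"),
                        integer(1))
  expect_true(all(pd_per_fold %in% 9:10))
  expect_error(grouped_kfold(paste0("S", 1:3), k = 4), "exceeds")
  expect_error(grouped_kfold(c("a", "a"), k = 2), "unique")
})

test_that("fold draws never leak subjects between train and test", {
  ids <- paste0("S", 1:37)
  grp <- rep(c("control", "pd"), length.out = 37)
  for (seed in 1:100) {
    fa <- grouped_kfold(ids, grp, k = 5, seed = seed)
    for (f in seq_len(fa$k)) {
      test_ids <- fa$folds[[f]]
      train_ids <- unlist(fa$folds[-f])
      expect_length(intersect(train_ids, test_ids), 0L)
    }
  }
})

test_that("confusion-count metrics match hand arithmetic", {
  truth <- rep(c(1, 1, 0, 0), c(9, 1, 8, 2))
  pred <- rep(c(1, 0, 0, 1), c(9, 1, 8, 2))
  m <- classification_metrics(truth, pred)
  expect_equal(m$acc, 0.85)
  expect_equal(m$tpr, 0.9)
  expect_equal(m$tnr, 0.8)
  expect_equal(c(m$tp, m$fn, m$tn, m$fp), c(9, 1, 8, 2))
})

test_that("AUC follows the midrank convention and matches pROC", {
  truth <- c(1, 1, 1, 0, 0)
  m <- classification_metrics(truth, truth, scores = c(0.9, 0.8, 0.7, 0.2, 0.1))
  expect_equal(m$auc, 1.0)
  m <- classification_metrics(truth, truth, scores = rep(0.5, 5))
  expect_equal(m$auc, 0.5)
  set.seed(30)
  for (i in 1:20) {
    y <- sample(0:1, 40, replace = TRUE, prob = c(0.4, 0.6))
    if (length(unique(y)) < 2) next
    s <- round(stats::runif(40), 2) # rounding forces ties
    ours <- classification_metrics(y, y, scores = s)$auc
    ref <- suppressMessages(as.numeric(pROC::auc(y, s, direction = "<")))
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})

test_that("single-class truth leaves the undefined rate NA", {
  m <- classification_metrics(c(1, 1), c(1, 0))
  expect_true(is.na(m$tnr))
  expect_equal(m$tpr, 0.5)
})

test_that("subject aggregation is the arithmetic mean", {
  expect_equal(aggregate_subject_score(c(2.1, 2.3, 2.5)), 2.3)
  expect_equal(aggregate_subject_score(5), 5)
  expect_error(aggregate_subject_score(numeric(0)), "no window")
  set.seed(31)
  for (i in 1:10) {
    x <- stats::rnorm(sample(1:20, 1))
    expect_equal(aggregate_subject_score(x), sum(x) / length(x))
  }
})

test_that("regression metrics match hand computations", {
  m <- regression_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(m$r2, 1)
  expect_equal(m$mae, 0)
  expect_equal(m$rmse, 0)
  m <- regression_metrics(c(1, 2, 3), rep(2, 3))
  expect_equal(m$r2, 0)
  m <- regression_metrics(c(1, 2, 3), c(1, 2, 4))
  expect_equal(m$r2, 0.5) # SSres 1, SStot 2
  expect_equal(m$mae, 1 / 3)
  expect_equal(m$rmse, sqrt(1 / 3))
  expect_equal(m$mse, m$rmse^2, tolerance = 1e-12)
  expect_warning(m <- regression_metrics(c(2, 2, 2), c(1, 2, 3)), "constant")
  expect_true(is.na(m$r2))
})

test_that("SMOTE balances counts by segment interpolation", {
  set.seed(32)
  x <- rbind(matrix(stats::rnorm(20 * 4), 20),
             matrix(stats::rnorm(5 * 4, mean = 10), 5))
  y <- rep(c("a", "b"), c(20, 5))
  bal <- smote_balance(x, y, k_neighbors = 3, seed = 1)
  expect_equal(as.integer(table(bal$labels)), c(20L, 20L))
  # originals preserved verbatim
  expect_equal(bal$x[1:25, ], x)
  # synthetic points lie within the minority bounding segment structure:
  # each coordinate between the min and max of the minority class
  synth <- bal$x[26:40, , drop = FALSE]
  xb <- x[21:25, , drop = FALSE]
  for (j in 1:4) {
    expect_true(all(synth[, j] >= min(xb[, j]) - 1e-9))
    expect_true(all(synth[, j] <= max(xb[, j]) + 1e-9))
  }
  # already balanced input returned unchanged
  bal2 <- smote_balance(x[1:10, ], rep(c("a", "b"), each = 5))
  expect_identical(bal2$x, x[1:10, ])
  expect_error(smote_balance(x[1:21, ], rep(c("a", "b"), c(20, 1))),
               "at least 2")
})

test_that("synthetic SMOTE points are affine combinations of neighbours", {
  set.seed(33)
  x <- matrix(stats::rnorm(8 * 2), 8)
  y <- rep(c("a", "b"), c(6, 2))
  bal <- smote_balance(x, y, k_neighbors = 1, seed = 2)
  minority <- x[7:8, ]
  synth <- bal$x[-(1:8), , drop = FALSE]
  # with k = 1 and 2 minority points, every synthetic point lies on the
  # segment between the two
  dirn <- minority[2, ] - minority[1, ]
  for (i in seq_len(nrow(synth))) {
    lam <- (synth[i, 1] - minority[1, 1]) / dirn[1]
    expect_gte(lam, -1e-9)
    expect_lte(lam, 1 + 1e-9)
    expect_equal(synth[i, ], minority[1, ] + lam * dirn, tolerance = 1e-9)
  }
})

test_that("Wilcoxon signed-rank: exact enumeration and edge cases", {
  r <- wilcoxon_signed_rank(c(2, 4, 6), c(1, 2, 3)) # differences 1, 2, 3
  expect_equal(r$w_minus, 0)
  expect_equal(r$p_value, 0.25)
  expect_equal(r$method, "exact")
  same <- wilcoxon_signed_rank(1:5, 1:5)
  expect_true(same$degenerate)
  expect_equal(same$p_value, 1)
  # antisymmetry
  a <- c(5, 3, 8, 1, 9, 2)
  b <- c(4, 6, 2, 7, 3, 8)
  expect_equal(wilcoxon_signed_rank(a, b)$p_value,
               wilcoxon_signed_rank(b, a)$p_value)
})

test_that("exact Wilcoxon p-values match wilcox.test on tie-free data", {
  set.seed(34)
  for (i in 1:20) {
    n <- sample(4:15, 1)
    a <- stats::rnorm(n)
    b <- stats::rnorm(n)
    ours <- wilcoxon_signed_rank(a, b)
    ref <- stats::wilcox.test(a, b, paired = TRUE, exact = TRUE)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-9)
  }
})

test_that("large-sample Wilcoxon uses a tie-corrected normal approximation", {
  set.seed(35)
  a <- stats::rnorm(60, 0.3)
  b <- stats::rnorm(60)
  ours <- wilcoxon_signed_rank(a, b)
  expect_equal(ours$method, "normal approximation")
  ref <- stats::wilcox.test(a, b, paired = TRUE, exact = FALSE,
                            correct = FALSE)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-6)
})
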