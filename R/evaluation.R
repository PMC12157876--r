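#' Windowing plan
#'
#' Overlapping sliding windows: by convention 10-60 s in 10 s increments
#' with 20% overlap, giving a stride of `window_s * (1 - overlap_frac)`.
#'
#' @param window_s Window length in seconds (> 0).
#' @param overlap_frac Fractional overlap in `[0, 1)`.
#' @return List of class `"windowing_plan"` with derived `stride_s`.
#' @export
windowing_plan <- function(window_s = 10, overlap_frac = 0.2) {
  if (window_s <= 0) stop("window_s must be positive")
  if (overlap_frac < 0 || overlap_frac >= 1)
    stop("overlap_frac must lie in [0, 1)")
  structure(list(window_s = window_s, overlap_frac = overlap_frac,
                 stride_s = window_s * (1 - overlap_frac)),
            class = "windowing_plan")
}

#' Segment a series into full-length overlapping windows
#'
#' Windows start at multiples of the stride (in samples); a partial tail is
#' dropped, so the count is `floor((n - w) / stride) + 1` with
#' `w = window_s * fs` and `stride = round(stride_s * fs)`.
#'
#' @param series Numeric signal.
#' @param fs Sampling frequency (Hz).
#' @param plan A [windowing_plan()].
#' @return List of numeric windows, each carrying attribute `start` (1-based
#'   sample index). A series shorter than one window yields an empty list
#'   with a warning.
#' @export
segment_windows <- function(series, fs, plan = windowing_plan()) {
  stopifnot(inherits(plan, "windowing_plan"))
  n <- length(series)
  w <- round(plan$window_s * fs)
  stride <- round(plan$stride_s * fs)
  if (n < w) {
    warning("series (", n, " samples) shorter than one window (", w,
            " samples)")
    return(list())
  }
  starts <- seq(1L, n - w + 1L, by = stride)
  lapply(starts, function(s)
    structure(series[s:(s + w - 1L)], start = s))
}

#' Subject-grouped stratified k-fold assignment
#'
#' Subjects (never windows) are partitioned into `k` folds so no subject's
#' windows can span folds. Assignment is stratified by group label and
#' greedily balanced: each subject goes to the currently smallest fold, so
#' total fold sizes differ by at most one.
#'
#' @param subject_ids Character vector of unique subject ids.
#' @param groups Group label per subject (used for stratification).
#' @param k Number of folds (`<=` number of subjects).
#' @param seed Seed for the shuffle within strata.
#' @return Object of class `"fold_assignment"`: list with `folds` (list of
#'   id vectors) and `k`.
#' @export
grouped_kfold <- function(subject_ids, groups = rep("all",
                                                    length(subject_ids)),
                          k, seed = 1) {
  if (anyDuplicated(subject_ids)) stop("subject ids must be unique")
  n <- length(subject_ids)
  if (k > n) stop("k = ", k, " exceeds the number of subjects (", n, ")")
  if (k < 2L) stop("k must be at least 2")
  folds <- rep(list(character(0)), k)
  with_rng(seed, {
    for (g in unique(groups)) {
      ids <- sample(subject_ids[groups == g])
      for (id in ids) {
        sizes <- lengths(folds)
        tgt <- which.min(sizes)
        folds[[tgt]] <- c(folds[[tgt]], id)
      }
    }
  })
  structure(list(folds = folds, k = k), class = "fold_assignment")
}

#' @export
print.fold_assignment <- function(x, ...) {
  cat(sprintf("<fold_assignment> %d folds, sizes: %s\n", x$k,
              paste(lengths(x$folds), collapse = ", ")))
  invisible(x)
}

#' Classification metrics with PD as the positive class
#'
#' Accuracy, true positive rate (sensitivity for PD), true negative rate
#' (specificity), and the area under the ROC curve computed as the midrank
#' Mann-Whitney statistic (ties get midranks, so all-equal scores give AUC
#' 0.5). With single-class truth the undefined rate is reported `NA`, not 0.
#'
#' @param truth True labels (0/1, `"control"`/`"pd"`, or factor; pd = 1).
#' @param predicted Predicted labels, same encodings.
#' @param scores Optional numeric score for the positive class (e.g. the pd
#'   softmax probability) used for AUC.
#' @return List of class `"eval_metrics"` with `acc`, `tpr`, `tnr`, `auc`
#'   and the confusion counts `tp`, `fn`, `tn`, `fp`.
#' @export
classification_metrics <- function(truth, predicted, scores = NULL) {
  y <- .encode_labels(truth)
  p <- .encode_labels(predicted)
  if (length(y) != length(p)) stop("truth and predicted are not aligned")
  tp <- sum(y == 1 & p == 1)
  fn <- sum(y == 1 & p == 0)
  tn <- sum(y == 0 & p == 0)
  fp <- sum(y == 0 & p == 1)
  auc <- NA_real_
  if (!is.null(scores) && tp + fn > 0 && tn + fp > 0) {
    r <- rank(scores) # midranks under ties
    npos <- tp + fn
    nneg <- tn + fp
    auc <- (sum(r[y == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
  }
  structure(list(acc = (tp + tn) / length(y),
                 tpr = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
                 tnr = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
                 auc = auc, tp = tp, fn = fn, tn = tn, fp = fp),
            class = "eval_metrics")
}

#' @export
print.eval_metrics <- function(x, ...) {
  if (!is.null(x$acc))
    cat(sprintf("ACC %.3f  TPR %s  TNR %s  AUC %s\n", x$acc,
                format(x$tpr, digits = 3), format(x$tnr, digits = 3),
                format(x$auc, digits = 3)))
  if (!is.null(x$r2))
    cat(sprintf("R2 %s  MAE %.3f  RMSE %.3f  MSE %.3f\n",
                format(x$r2, digits = 3), x$mae, x$rmse, x$mse))
  invisible(x)
}

#' Average window-level predictions into one subject-level score
#'
#' @param window_predictions Numeric vector of per-window predictions for
#'   one subject (non-empty).
#' @return Their arithmetic mean.
#' @export
aggregate_subject_score <- function(window_predictions) {
  if (length(window_predictions) == 0L)
    stop("no window predictions to aggregate")
  mean(window_predictions)
}

#' Regression metrics
#'
#' `r2 = 1 - SSres/SStot` plus MAE, RMSE and MSE. Constant actual values
#' leave R2 undefined (`NA` with a warning).
#'
#' @param actual,predicted Aligned numeric vectors (n >= 2).
#' @return List of class `"eval_metrics"` with `r2`, `mae`, `rmse`, `mse`.
#' @export
regression_metrics <- function(actual, predicted) {
  if (length(actual) != length(predicted))
    stop("actual and predicted are not aligned")
  if (length(actual) < 2L) stop("need at least 2 observations")
  ss_res <- sum((actual - predicted)^2)
  ss_tot <- sum((actual - mean(actual))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else {
    warning("constant actual values: R2 undefined")
    NA_real_
  }
  mse <- mean((actual - predicted)^2)
  structure(list(r2 = r2, mae = mean(abs(actual - predicted)),
                 rmse = sqrt(mse), mse = mse),
            class = "eval_metrics")
}

#' SMOTE minority oversampling
#'
#' Balances a two-class training set by interpolating synthetic minority
#' samples: each synthetic point lies on the segment between a minority
#' sample and one of its `k_neighbors` nearest minority neighbours
#' (`s = x + lambda * (n - x)`, `lambda ~ U(0, 1)`). Originals are
#' preserved; an already balanced input is returned unchanged. Intended for
#' flattened GAF-image vectors of the training split only.
#'
#' @param x Numeric feature matrix, one row per sample.
#' @param labels Two-class label vector.
#' @param k_neighbors Number of nearest minority neighbours considered.
#' @param seed RNG seed.
#' @return List with balanced `x` and `labels` (originals first, synthetic
#'   rows appended).
#' @export
smote_balance <- function(x, labels, k_neighbors = 5, seed = 1) {
  x <- as.matrix(x)
  if (nrow(x) != length(labels)) stop("x and labels are not aligned")
  tab <- table(labels)
  if (length(tab) != 2L) stop("smote_balance expects exactly two classes")
  if (tab[1] == tab[2]) return(list(x = x, labels = labels))
  minority <- names(tab)[which.min(tab)]
  need <- abs(diff(as.integer(tab)))
  min_idx <- which(labels == minority)
  if (length(min_idx) < 2L)
    stop("minority class must have at least 2 members")
  xm <- x[min_idx, , drop = FALSE]
  k <- min(k_neighbors, nrow(xm) - 1L)
  d <- as.matrix(stats::dist(xm))
  diag(d) <- Inf
  nn <- apply(d, 1L, function(r) order(r)[seq_len(k)])
  nn <- matrix(nn, nrow = k) # k x n_min
  synth <- with_rng(seed, {
    base_i <- rep_len(seq_len(nrow(xm)), need)[sample(need)]
    lam <- stats::runif(need)
    nb_pick <- vapply(base_i, function(i) nn[sample(k, 1L), i], integer(1))
    xm[base_i, , drop = FALSE] +
      lam * (xm[nb_pick, , drop = FALSE] - xm[base_i, , drop = FALSE])
  })
  list(x = rbind(x, synth),
       labels = c(labels, rep(minority, need)))
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are dropped; absolute differences are ranked with
#' midranks under ties. For `n <= 25` retained pairs the two-sided p-value
#' is exact, from dynamic-programming enumeration of all `2^n` sign
#' assignments of the rank sum; beyond that a normal approximation with tie
#' correction is used. All-zero differences give the degenerate result
#' `p = 1`.
#'
#' @param paired_a,paired_b Aligned numeric vectors.
#' @return List with `statistic` (`min(W+, W-)`), `w_plus`, `w_minus`,
#'   `p_value` (two-sided), `n` (retained pairs), `method`, and a
#'   `degenerate` flag.
#' @export
wilcoxon_signed_rank <- function(paired_a, paired_b) {
  if (length(paired_a) != length(paired_b))
    stop("paired vectors must be aligned")
  d <- paired_a - paired_b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    return(list(statistic = 0, w_plus = 0, w_minus = 0, p_value = 1,
                n = 0L, method = "degenerate", degenerate = TRUE))
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  w_minus <- sum(r) - w_plus
  if (n <= 25L) {
    # DP over the distribution of W+ under random signs. Midranks are
    # multiples of 1/2, so work on doubled ranks to stay integral.
    r2 <- as.integer(round(2 * r))
    tot <- sum(r2)
    dist <- numeric(tot + 1L) # index s+1 holds count of sum s
    dist[1] <- 1
    for (ri in r2) {
      shifted <- c(numeric(ri), dist[seq_len(tot + 1L - ri)])
      dist <- dist + shifted
    }
    dist <- dist / 2^n
    mu <- tot / 2
    obs_dev <- abs(round(2 * w_plus) - mu)
    s_vals <- seq_along(dist) - 1
    p <- sum(dist[abs(s_vals - mu) >= obs_dev - 1e-9])
    method <- "exact"
  } else {
    mu <- sum(r) / 2
    sigma <- sqrt(sum(r^2) / 4) # midrank form; equals the tie-corrected SD
    z <- (w_plus - mu) / sigma
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation"
  }
  list(statistic = min(w_plus, w_minus), w_plus = w_plus, w_minus = w_minus,
       p_value = min(p, 1), n = n, method = method, degenerate = FALSE)
}
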