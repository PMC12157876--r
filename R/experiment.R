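# 32-bit FNV-1a over a JSON rendering of the resolved config, so every
# artifact can be traced to the exact configuration that produced it.
config_hash <- function(config) {
  txt <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                          force = TRUE)
  bytes <- utf8ToInt(as.character(txt))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b)) # keep in int range
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Encode a cohort into a window-level GAF image dataset
#'
#' For every recording the per-foot sensor sums are formed (optionally from
#' an ablated sensor keep-set), scaled to unit peak force, optionally
#' perturbed with Gaussian observation noise, segmented into overlapping
#' windows, and encoded as multi-channel GASF images. Constant (degenerate)
#' windows are dropped and counted, never imputed.
#'
#' @param recordings List of [gait_recording()]s.
#' @param subjects Subject table ([load_demographics()]).
#' @param plan A [windowing_plan()].
#' @param side Image side in pixels.
#' @param keep_sensors Sensor subset used for the per-foot sums.
#' @param noise_sigma Gaussian noise SD on the unit-normalized force scale
#'   (0 = no perturbation, bit-identical to the unperturbed path).
#' @param channel_policy See [window_to_image()].
#' @param noise_seed Seed for the noise substreams (one per recording).
#' @return List with `images` (`(n, side, side, 3)` array), `meta`
#'   (data.frame: `subject_id`, `group`, `walk_index`, `start`), and
#'   `dropped` (degenerate window count).
#' @export
build_image_dataset <- function(recordings, subjects,
                                plan = windowing_plan(), side = 64,
                                keep_sensors = 1:8, noise_sigma = 0,
                                channel_policy = "left-right-mean",
                                noise_seed = 1) {
  images <- list()
  meta <- list()
  dropped <- 0L
  for (ri in seq_along(recordings)) {
    rec <- recordings[[ri]]
    left <- foot_sum_series(rec, "left", keep_sensors)
    right <- foot_sum_series(rec, "right", keep_sensors)
    peak <- max(left, right)
    if (peak <= 0) next
    left <- left / peak
    right <- right / peak
    if (noise_sigma > 0) {
      left <- add_gaussian_noise(left, noise_sigma,
                                 seed = substream_seed(noise_seed, 2L * ri))
      right <- add_gaussian_noise(right, noise_sigma,
                                  seed = substream_seed(noise_seed,
                                                        2L * ri + 1L))
    }
    wl <- suppressWarnings(segment_windows(left, rec$fs, plan))
    wr <- suppressWarnings(segment_windows(right, rec$fs, plan))
    for (wi in seq_along(wl)) {
      img <- tryCatch(window_to_image(wl[[wi]], wr[[wi]], side = side,
                                      channel_policy = channel_policy),
                      degenerate_window = function(e) NULL)
      if (is.null(img)) {
        dropped <- dropped + 1L
        next
      }
      images[[length(images) + 1L]] <- img
      meta[[length(meta) + 1L]] <- data.frame(
        subject_id = rec$subject_id, group = rec$group,
        walk_index = rec$walk_index, start = attr(wl[[wi]], "start"))
    }
  }
  if (length(images) == 0L)
    stop("no usable windows (all inputs short or degenerate)")
  list(images = abind_images(images), meta = do.call(rbind, meta),
       dropped = dropped)
}

.resolve_task <- function(task) {
  if (task == "classify") return(list(kind = "classify", target = NULL))
  m <- regmatches(task, regexec("^regress:(.+)$", task))[[1]]
  if (length(m) == 0L)
    stop("task must be 'classify' or 'regress:<score>'")
  target <- switch(m[2], tug = , tug_s = "tug_s", updrs = "updrs",
                   updrsm = "updrsm", hy = , hoehn_yahr = "hoehn_yahr",
                   stop("unknown score '", m[2], "'"))
  list(kind = "regress", target = target)
}

#' Assemble an experiment configuration
#'
#' Collects every knob of a classification or severity-regression run into
#' one resolved, hashable object: the data source (an in-memory cohort, a
#' cohort directory, or synthetic generator parameters), the task, the
#' windowing plan, image encoding, model overrides, cross-validation plan
#' and perturbations. All defaults are filled in here so the echo in the
#' report is complete.
#'
#' @param data One of: a list with `recordings` and `subjects`; a directory
#'   path ([read_cohort()] dialect); or `list(synthetic = list(...))` with
#'   [generate_cohort()] arguments.
#' @param task `"classify"` or `"regress:<score>"` with score one of `tug`,
#'   `updrs`, `updrsm`, `hoehn_yahr`.
#' @param windowing A [windowing_plan()].
#' @param side GAF image side (pixels).
#' @param channel_policy See [window_to_image()].
#' @param model Named list of [cnn_spec()] overrides (e.g. `epochs`,
#'   `batch_size`).
#' @param cv List: folds `k`, `seed`, and `grouping` (`"subject"` for
#'   leakage-safe grouped folds, `"window"` for the naive mode).
#' @param noise_sigma,keep_sensors,smote,gender Perturbation arms: Gaussian
#'   noise SD on the unit signal scale; sensor keep-set; SMOTE balancing of
#'   the training split; optional gender subgroup filter.
#' @param seed Master seed (fans out to generator, noise, folds, models).
#' @return List of class `"run_config"`.
#' @export
experiment_config <- function(data, task = "classify",
                              windowing = windowing_plan(), side = 64,
                              channel_policy = "left-right-mean",
                              model = list(),
                              cv = list(k = 5, seed = NULL,
                                        grouping = "subject"),
                              noise_sigma = 0, keep_sensors = 1:8,
                              smote = FALSE, gender = NULL, seed = 1) {
  if (is.null(cv$k)) cv$k <- 5
  if (is.null(cv$seed)) cv$seed <- substream_seed(seed, 11L)
  if (is.null(cv$grouping)) cv$grouping <- "subject"
  if (!cv$grouping %in% c("subject", "window"))
    stop("cv$grouping must be 'subject' or 'window'")
  .resolve_task(task) # validates
  if (!is.null(gender)) gender <- match.arg(gender, c("male", "female"))
  structure(list(data = data, task = task, windowing = windowing,
                 side = side, channel_policy = channel_policy, model = model,
                 cv = cv, noise_sigma = noise_sigma,
                 keep_sensors = as.integer(keep_sensors), smote = smote,
                 gender = gender, seed = seed),
            class = "run_config")
}

.resolve_data <- function(config) {
  data <- config$data
  if (is.character(data)) return(read_cohort(data))
  if (!is.null(data$synthetic)) {
    args <- data$synthetic
    if (is.null(args$seed)) args$seed <- substream_seed(config$seed, 3L)
    return(do.call(generate_cohort, args))
  }
  if (!is.null(data$recordings) && !is.null(data$subjects)) return(data)
  stop("config$data must be a cohort list, a directory, or synthetic params")
}

#' Run a full classification or regression experiment
#'
#' Executes the pipeline end to end: resolve the data source, form per-foot
#' sums (honouring the sensor keep-set), add any noise arm, window, encode
#' as GAF images, cross-validate the CNN with subject-grouped stratified
#' folds, and compute window-level, per-fold and subject-level metrics. The
#' returned report echoes the resolved configuration, its hash and all
#' derived seeds, and never mixes subjects between a fold's train and test
#' sides.
#'
#' @param config An [experiment_config()].
#' @param verbose Print fold progress.
#' @return Object of class `"gait_experiment"`: list with `config`,
#'   `config_hash`, `folds`, `predictions` (one row per test window),
#'   `fold_metrics`, `pooled` (window-level), `subject_level`, and
#'   `dropped_windows`.
#' @export
run_experiment <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  task <- .resolve_task(config$task)
  cohort <- .resolve_data(config)
  subjects <- cohort$subjects
  recordings <- cohort$recordings
  if (!is.null(config$gender)) {
    keep_ids <- subjects$subject_id[subjects$gender == config$gender]
    subjects <- subjects[subjects$subject_id %in% keep_ids, ]
    recordings <- Filter(function(r) r$subject_id %in% keep_ids, recordings)
  }
  if (task$kind == "classify") {
    if (length(unique(subjects$group)) < 2L)
      stop("classification requires both control and pd subjects")
  } else {
    has_score <- !is.na(subjects[[task$target]])
    if (!any(has_score))
      stop("regression on '", task$target,
           "' requires scored (pd) subjects; none present")
    subjects <- subjects[has_score, ]
    recordings <- Filter(function(r) r$subject_id %in% subjects$subject_id,
                         recordings)
  }
  ds <- build_image_dataset(recordings, subjects, plan = config$windowing,
                            side = config$side,
                            keep_sensors = config$keep_sensors,
                            noise_sigma = config$noise_sigma,
                            channel_policy = config$channel_policy,
                            noise_seed = substream_seed(config$seed, 7L))
  meta <- ds$meta
  n_img <- nrow(meta)

  if (task$kind == "classify") {
    y <- as.integer(meta$group == "pd")
  } else {
    y <- subjects[[task$target]][match(meta$subject_id, subjects$subject_id)]
  }

  # fold assignment
  if (config$cv$grouping == "subject") {
    uniq <- unique(meta$subject_id)
    grp <- meta$group[match(uniq, meta$subject_id)]
    fa <- grouped_kfold(uniq, grp, k = config$cv$k, seed = config$cv$seed)
    fold_of_window <- lapply(fa$folds, function(ids)
      which(meta$subject_id %in% ids))
  } else {
    fa <- NULL
    fold_id <- with_rng(config$cv$seed,
                        sample(rep_len(seq_len(config$cv$k), n_img)))
    fold_of_window <- split(seq_len(n_img), fold_id)
  }

  spec_args <- c(list(input_side = config$side), config$model)
  if (is.null(spec_args$fc_units))
    spec_args$fc_units <- if (task$kind == "classify") 128L else 512L
  spec <- do.call(cnn_spec, spec_args)

  preds <- rep(NA_real_, n_img)
  scores <- rep(NA_real_, n_img)
  fold_metrics <- list()
  for (f in seq_along(fold_of_window)) {
    test_i <- fold_of_window[[f]]
    train_i <- setdiff(seq_len(n_img), test_i)
    if (config$cv$grouping == "subject" &&
        length(intersect(meta$subject_id[train_i],
                         meta$subject_id[test_i])) > 0L)
      stop("internal error: subject leakage across folds")
    xtr <- ds$images[train_i, , , , drop = FALSE]
    ytr <- y[train_i]
    if (isTRUE(config$smote) && task$kind == "classify") {
      flat <- matrix(xtr, nrow = length(train_i))
      bal <- smote_balance(flat, ytr,
                           seed = substream_seed(config$seed, 300L + f))
      xtr <- array(bal$x, c(nrow(bal$x), config$side, config$side, 3L))
      ytr <- as.integer(bal$labels)
    }
    model <- gait_cnn(xtr, ytr,
                      task = if (task$kind == "classify") "classify"
                             else "regress",
                      spec = spec, validation_fraction = 0.15,
                      seed = substream_seed(config$seed, 100L + f))
    if (task$kind == "classify") {
      pr <- predict(model, ds$images[test_i, , , , drop = FALSE])
      scores[test_i] <- pr[, "pd"]
      preds[test_i] <- as.integer(pr[, "pd"] >= pr[, "control"])
      fold_metrics[[f]] <- classification_metrics(y[test_i], preds[test_i],
                                                  scores[test_i])
    } else {
      preds[test_i] <- predict(model, ds$images[test_i, , , , drop = FALSE])
      fold_metrics[[f]] <- regression_metrics(y[test_i], preds[test_i])
    }
    if (verbose)
      message(sprintf("fold %d/%d done", f, length(fold_of_window)))
  }

  predictions <- data.frame(meta, truth = y, predicted = preds,
                            score = scores,
                            fold = NA_integer_)
  for (f in seq_along(fold_of_window))
    predictions$fold[fold_of_window[[f]]] <- f

  if (task$kind == "classify") {
    pooled <- classification_metrics(y, preds, scores)
    agg <- stats::aggregate(cbind(truth = truth, score = score) ~ subject_id,
                            data = predictions, FUN = mean)
    subj_pred <- as.integer(stats::aggregate(predicted ~ subject_id,
                                             data = predictions,
                                             FUN = mean)$predicted >= 0.5)
    subject_level <- classification_metrics(as.integer(agg$truth > 0.5),
                                            subj_pred, agg$score)
  } else {
    agg_t <- stats::aggregate(truth ~ subject_id, data = predictions,
                              FUN = mean)
    agg_p <- stats::aggregate(predicted ~ subject_id, data = predictions,
                              FUN = aggregate_subject_score)
    pooled <- regression_metrics(y, preds)
    subject_level <- regression_metrics(agg_t$truth, agg_p$predicted)
  }

  structure(list(config = config, config_hash = config_hash(config),
                 task = config$task, folds = fa,
                 predictions = predictions, fold_metrics = fold_metrics,
                 pooled = pooled, subject_level = subject_level,
                 dropped_windows = ds$dropped, n_windows = n_img),
            class = "gait_experiment")
}

#' @export
print.gait_experiment <- function(x, ...) {
  cat(sprintf("<gait_experiment> %s, %d windows, %d folds (hash %s)\n",
              x$task, x$n_windows, length(x$fold_metrics), x$config_hash))
  cat("Window-level pooled: ")
  print(x$pooled)
  cat("Subject-level: ")
  print(x$subject_level)
  invisible(x)
}

#' Write a machine-readable experiment report
#'
#' Emits `report.json` (config echo, hash, seeds, per-fold and pooled
#' metrics) and `predictions.csv` (one row per test window) into `dir`.
#'
#' @param report A [run_experiment()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_experiment_report <- function(report, dir) {
  stopifnot(inherits(report, "gait_experiment"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  json_path <- file.path(dir, "report.json")
  csv_path <- file.path(dir, "predictions.csv")
  payload <- list(
    task = report$task,
    config_hash = report$config_hash,
    config = report$config[setdiff(names(report$config), "data")],
    n_windows = report$n_windows,
    dropped_windows = report$dropped_windows,
    fold_metrics = lapply(report$fold_metrics, unclass),
    pooled = unclass(report$pooled),
    subject_level = unclass(report$subject_level))
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  utils::write.csv(report$predictions, csv_path, row.names = FALSE)
  invisible(c(json_path, csv_path))
}
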