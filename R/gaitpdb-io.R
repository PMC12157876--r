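#' Construct a gait recording
#'
#' A `gait_recording` holds one walking trial of one subject: 8 vertical
#' ground reaction force (VGRF) channels per foot plus the per-foot totals,
#' sampled on a regular clock (100 Hz in the public insole archives).
#'
#' @param subject_id Character scalar, e.g. `"GaPt03"`. Unique within a cohort.
#' @param study_tag One of `"Ga"`, `"Ju"`, `"Si"` (originating laboratory).
#' @param group `"control"` or `"pd"`.
#' @param walk_index Positive integer; walks beyond the first may be altered
#'   gait conditions depending on the study.
#' @param fs Sampling frequency in Hz.
#' @param time_s Numeric vector of sample times in seconds, strictly
#'   increasing with step `1/fs`.
#' @param sensors_left,sensors_right Numeric matrices with 8 columns
#'   (sensor channels, Newtons) and one row per sample.
#' @param total_left,total_right Numeric vectors, per-foot force totals in
#'   Newtons. Must match the row sums of the sensor matrices within
#'   `sum_tolerance`.
#' @param sum_tolerance Absolute tolerance (Newtons, per sample) for the
#'   stored-total versus recomputed-sum consistency check. The default 0.5 N
#'   absorbs file rounding.
#'
#' @return An object of class `"gait_recording"`.
#' @seealso [parse_walk_file()], [foot_sum_series()], [generate_subject()]
#' @export
gait_recording <- function(subject_id, study_tag, group, walk_index, fs,
                           time_s, sensors_left, sensors_right,
                           total_left, total_right, sum_tolerance = 0.5) {
  study_tag <- match.arg(study_tag, c("Ga", "Ju", "Si"))
  group <- match.arg(group, c("control", "pd"))
  stopifnot(is.character(subject_id), length(subject_id) == 1L,
            length(walk_index) == 1L, walk_index >= 1,
            is.numeric(fs), fs > 0)
  sensors_left <- as.matrix(sensors_left)
  sensors_right <- as.matrix(sensors_right)
  n <- length(time_s)
  if (n < 1L)
    stop("gait_recording: empty time vector")
  if (ncol(sensors_left) != 8L || ncol(sensors_right) != 8L)
    stop("gait_recording: sensor matrices must have 8 columns")
  lens <- c(nrow(sensors_left), nrow(sensors_right),
            length(total_left), length(total_right))
  if (any(lens != n))
    stop("gait_recording: all channels must share the length of time_s")
  dt <- diff(time_s)
  if (n > 1L) {
    if (any(dt <= 0))
      stop("gait_recording: time_s must be strictly increasing")
    if (max(abs(dt - 1 / fs)) > 0.25 / fs)
      stop("gait_recording: time step inconsistent with fs = ", fs, " Hz")
  }
  dev_l <- max(abs(rowSums(sensors_left) - total_left))
  dev_r <- max(abs(rowSums(sensors_right) - total_right))
  if (max(dev_l, dev_r) > sum_tolerance)
    stop(sprintf(paste0("gait_recording: per-foot total disagrees with the ",
                        "sum of its 8 sensors (max deviation %.3g N > %.3g N)"),
                 max(dev_l, dev_r), sum_tolerance))
  structure(list(subject_id = subject_id, study_tag = study_tag,
                 group = group, walk_index = as.integer(walk_index),
                 fs = fs, time_s = as.numeric(time_s),
                 sensors_left = sensors_left, sensors_right = sensors_right,
                 total_left = as.numeric(total_left),
                 total_right = as.numeric(total_right)),
            class = "gait_recording")
}

#' @export
print.gait_recording <- function(x, ...) {
  cat(sprintf("<gait_recording> %s walk %d (%s, %s)\n",
              x$subject_id, x$walk_index, x$study_tag, x$group))
  cat(sprintf("  %d samples @ %g Hz (%.1f s), peak total force L/R = %.0f/%.0f N\n",
              length(x$time_s), x$fs, length(x$time_s) / x$fs,
              max(x$total_left), max(x$total_right)))
  invisible(x)
}

#' Parse a walk file name into its components
#'
#' File names follow `<Tag><Co|Pt><subject>_<walk>`, e.g. `"GaPt03_01"`:
#' study tag `Ga`, patient group, subject 03, walk 1. `Co` marks controls and
#' `Pt` patients.
#'
#' @param name Walk file name, with or without a `.txt` extension.
#' @return A list with `subject_id` (tag + group code + number, e.g.
#'   `"GaPt03"`), `study_tag`, `group`, and integer `walk_index`.
#' @export
parse_walk_name <- function(name) {
  base <- sub("\\.txt$", "", basename(name))
  m <- regmatches(base, regexec("^(Ga|Ju|Si)(Co|Pt)([0-9]{2,3})_([0-9]{1,2})$",
                                base))[[1]]
  if (length(m) == 0L)
    stop("walk file name '", base, "' does not match the ",
         "<Ga|Ju|Si><Co|Pt><nn>_<walk> convention")
  list(subject_id = paste0(m[2], m[3], m[4]),
       study_tag = m[2],
       group = if (m[3] == "Co") "control" else "pd",
       walk_index = as.integer(m[5]))
}

#' Parse one per-walk VGRF text file
#'
#' Each non-empty line holds 19 whitespace-separated numbers: time in
#' seconds, 8 left-foot sensor forces, 8 right-foot sensor forces, and the
#' left and right per-foot totals (Newtons). Tabs and runs of spaces are both
#' accepted.
#'
#' @param text_lines Character vector of file lines.
#' @param name The walk file name (encodes study tag, group, subject, walk).
#' @param sum_tolerance Passed to [gait_recording()].
#' @return A [gait_recording()].
#' @examples
#' lines <- c("0.00 50 50 50 50 50 50 50 0 0 0 0 0 0 0 0 0 350 0",
#'            "0.01 50 50 50 50 50 50 50 0 0 0 0 0 0 0 0 0 350 0")
#' rec <- parse_walk_file(lines, "GaPt03_01")
#' rec$group
#' @export
parse_walk_file <- function(text_lines, name, sum_tolerance = 0.5) {
  meta <- parse_walk_name(name)
  keep <- nzchar(trimws(text_lines))
  lines <- text_lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0L)
    stop("walk file '", name, "' has no data lines")
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf != 19L)) {
    bad <- which(nf != 19L)[1]
    stop(sprintf("walk file '%s': line %d has %d fields, expected 19",
                 name, lineno[bad], nf[bad]))
  }
  vals <- suppressWarnings(as.numeric(unlist(fields, use.names = FALSE)))
  if (anyNA(vals)) {
    bad <- ceiling(which(is.na(vals))[1] / 19)
    stop(sprintf("walk file '%s': non-numeric field on line %d",
                 name, lineno[bad]))
  }
  mat <- matrix(vals, ncol = 19L, byrow = TRUE)
  time_s <- mat[, 1]
  fs <- if (nrow(mat) > 1L) 1 / stats::median(diff(time_s)) else 100
  gait_recording(subject_id = meta$subject_id, study_tag = meta$study_tag,
                 group = meta$group, walk_index = meta$walk_index,
                 fs = round(fs), time_s = time_s,
                 sensors_left = mat[, 2:9, drop = FALSE],
                 sensors_right = mat[, 10:17, drop = FALSE],
                 total_left = mat[, 18], total_right = mat[, 19],
                 sum_tolerance = sum_tolerance)
}

#' Read a per-walk VGRF file from disk
#'
#' @param path File path; the base name must follow the walk naming
#'   convention (see [parse_walk_name()]).
#' @param ... Passed to [parse_walk_file()].
#' @return A [gait_recording()].
#' @export
read_walk_file <- function(path, ...) {
  parse_walk_file(readLines(path), basename(path), ...)
}

#' Serialize a gait recording to the per-walk text dialect
#'
#' Numbers are written with millisecond time resolution and milli-Newton
#' force resolution, which round-trips through [parse_walk_file()] to file
#' precision.
#'
#' @param rec A [gait_recording()].
#' @param path Optional output path; when `NULL` the lines are returned.
#' @return Invisibly, the character vector of file lines.
#' @export
write_walk_file <- function(rec, path = NULL) {
  stopifnot(inherits(rec, "gait_recording"))
  mat <- cbind(rec$time_s, rec$sensors_left, rec$sensors_right,
               rec$total_left, rec$total_right)
  lines <- apply(round(mat, 3), 1L, function(r)
    paste(formatC(r, format = "f", digits = 3), collapse = "\t"))
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Canonical file name for a recording
#' @param rec A [gait_recording()].
#' @return e.g. `"GaPt03_01.txt"`.
#' @export
walk_file_name <- function(rec) {
  sprintf("%s_%02d.txt", rec$subject_id, rec$walk_index)
}

.hy_levels <- c(0, 1, 1.5, 2, 2.5, 3, 4, 5)

#' Load a demographics table into a subject table
#'
#' Validates one row per subject carrying group, gender, age, walking speed
#' and — for patients — the four clinical severity scores (Hoehn & Yahr,
#' UPDRS, UPDRS motor, Timed Up and Go). Patient rows missing any score and
#' control rows carrying scores are flagged `incomplete` rather than dropped.
#' Scores outside their usual printed ranges raise warnings, not errors.
#'
#' @param table_rows A data.frame with columns `subject_id`, `group`
#'   (`control`/`pd`), `gender` (`male`/`female`), `age`, `walking_speed`,
#'   and optionally `hoehn_yahr`, `updrs`, `updrsm`, `tug_s`.
#' @return A data.frame of class `"subject_table"`, one row per subject,
#'   with a logical `incomplete` column appended.
#' @export
load_demographics <- function(table_rows) {
  df <- as.data.frame(table_rows, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "gender", "age", "walking_speed")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("demographics table lacks columns: ",
         paste(missing_cols, collapse = ", "))
  for (sc in c("hoehn_yahr", "updrs", "updrsm", "tug_s"))
    if (!sc %in% names(df)) df[[sc]] <- NA_real_
  if (nrow(df) == 0L) {
    df$incomplete <- logical(0)
    class(df) <- c("subject_table", "data.frame")
    return(df)
  }
  if (anyDuplicated(df$subject_id))
    stop("duplicate subject id(s): ",
         paste(unique(df$subject_id[duplicated(df$subject_id)]),
               collapse = ", "))
  if (!all(df$group %in% c("control", "pd")))
    stop("group column must be 'control' or 'pd'")
  if (!all(df$gender %in% c("male", "female")))
    stop("gender column must be 'male' or 'female'")
  if (any(df$age <= 0)) stop("age must be positive")

  is_pd <- df$group == "pd"
  scores <- df[, c("hoehn_yahr", "updrs", "updrsm", "tug_s")]
  has_any <- rowSums(!is.na(scores)) > 0
  has_all <- rowSums(!is.na(scores)) == 4L
  df$incomplete <- (is_pd & !has_all) | (!is_pd & has_any)
  if (any(df$incomplete))
    warning(sum(df$incomplete), " subject(s) flagged incomplete ",
            "(patients missing scores or controls carrying scores)")

  chk <- function(x, ok, what) {
    bad <- !is.na(x) & !ok(x)
    if (any(bad))
      warning("out-of-range ", what, " for subject(s): ",
              paste(df$subject_id[bad], collapse = ", "))
  }
  chk(df$hoehn_yahr, function(x) x %in% .hy_levels, "Hoehn & Yahr stage")
  chk(df$updrs, function(x) x >= 0 & x <= 199, "UPDRS")
  chk(df$updrsm, function(x) x >= 0 & x <= 108, "UPDRS motor score")
  chk(df$tug_s, function(x) x > 0, "TUG time")
  both <- !is.na(df$updrs) & !is.na(df$updrsm)
  if (any(both & df$updrsm > df$updrs))
    warning("UPDRS motor sub-score exceeds total UPDRS for subject(s): ",
            paste(df$subject_id[both & df$updrsm > df$updrs], collapse = ", "))
  class(df) <- c("subject_table", "data.frame")
  df
}

#' Sum VGRF sensor channels into a per-foot gait marker
#'
#' The per-foot sum of the 8 sensor channels is the 1-D gait signal fed to
#' the windowing and image-encoding stages. A subset of sensors can be kept
#' to emulate hardware ablation; with all 8 kept the sum equals the stored
#' per-foot total within file tolerance.
#'
#' @param rec A [gait_recording()].
#' @param foot `"left"` or `"right"`.
#' @param keep_sensors Non-empty subset of `1:8`.
#' @return Numeric vector of summed forces (Newtons), one value per sample.
#' @export
foot_sum_series <- function(rec, foot = c("left", "right"),
                            keep_sensors = 1:8) {
  stopifnot(inherits(rec, "gait_recording"))
  foot <- match.arg(foot)
  keep_sensors <- as.integer(keep_sensors)
  if (length(keep_sensors) == 0L)
    stop("keep_sensors must name at least one sensor")
  if (!all(keep_sensors %in% 1:8))
    stop("keep_sensors must be a subset of 1:8")
  sens <- if (foot == "left") rec$sensors_left else rec$sensors_right
  rowSums(sens[, keep_sensors, drop = FALSE])
}

#' Write a cohort (walk files + demographics) to a directory
#'
#' Emits one per-walk text file per recording plus `demographics.csv`, the
#' same dialect [read_cohort()] consumes.
#'
#' @param recordings List of [gait_recording()] objects.
#' @param subjects A subject table (see [load_demographics()]).
#' @param dir Output directory, created if needed.
#' @param force Overwrite into a non-empty directory.
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(recordings, subjects, dir, force = FALSE) {
  if (dir.exists(dir) && length(dir(dir)) > 0L && !force)
    stop("output directory '", dir, "' is not empty (use force = TRUE)")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (rec in recordings) {
    p <- file.path(dir, walk_file_name(rec))
    write_walk_file(rec, p)
    paths <- c(paths, p)
  }
  demo <- file.path(dir, "demographics.csv")
  utils::write.csv(as.data.frame(subjects), demo, row.names = FALSE)
  invisible(c(paths, demo))
}

#' Read a cohort directory
#'
#' Reads `demographics.csv` and every walk file matching the naming
#' convention. Walk files listed in neither place are ignored; demographics
#' rows whose walk files are absent produce a warning and are kept (they
#' simply contribute no windows downstream).
#'
#' @param dir Directory produced by [write_cohort()] (or hand-assembled in
#'   the same dialect).
#' @param exclude_altered Drop altered-gait walks (dual-task / stimulated
#'   conditions identified by walk index; see `altered_walks`). Default TRUE.
#' @param altered_walks Named list mapping study tag to the walk indices
#'   regarded as altered conditions in that study.
#' @return List with `recordings` (list of [gait_recording()]) and
#'   `subjects` (subject table).
#' @export
read_cohort <- function(dir, exclude_altered = TRUE,
                        altered_walks = list(Ga = 2L)) {
  demo_path <- file.path(dir, "demographics.csv")
  if (!file.exists(demo_path))
    stop("no demographics.csv in '", dir, "'")
  subjects <- load_demographics(utils::read.csv(demo_path))
  files <- list.files(dir, pattern = "^(Ga|Ju|Si)(Co|Pt)[0-9]+_[0-9]+\\.txt$",
                      full.names = TRUE)
  recordings <- lapply(files, read_walk_file)
  if (exclude_altered && length(recordings)) {
    keep <- vapply(recordings, function(r) {
      alt <- altered_walks[[r$study_tag]]
      is.null(alt) || !(r$walk_index %in% alt)
    }, logical(1))
    recordings <- recordings[keep]
  }
  ids <- vapply(recordings, `[[`, "", "subject_id")
  orphan <- setdiff(subjects$subject_id, ids)
  if (length(orphan))
    warning("no walk files for subject(s): ", paste(orphan, collapse = ", "))
  unknown <- setdiff(ids, subjects$subject_id)
  if (length(unknown))
    warning("walk files without demographics row: ",
            paste(unique(unknown), collapse = ", "), " (skipped)")
  recordings <- recordings[ids %in% subjects$subject_id]
  list(recordings = recordings, subjects = subjects)
}
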