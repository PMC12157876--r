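make_lines <- function(n = 5, fs = 100, left = rep(50, 8), right = rep(30, 8)) {
  vapply(seq_len(n) - 1L, function(i)
    paste(c(sprintf("%.2f", i / fs), left, right, sum(left), sum(right)),
          collapse = " "), character(1))
}

test_that("walk file names decode study tag, group, subject and walk", {
  m <- parse_walk_name("GaPt03_01")
  expect_equal(m$study_tag, "Ga")
  expect_equal(m$group, "pd")
  expect_equal(m$subject_id, "GaPt03")
  expect_equal(m$walk_index, 1L)

  m <- parse_walk_name("JuCo14_02.txt")
  expect_equal(m$study_tag, "Ju")
  expect_equal(m$group, "control")
  expect_equal(m$subject_id, "JuCo14")
  expect_equal(m$walk_index, 2L)

  expect_error(parse_walk_name("XxPt01_01"), "convention")
  expect_error(parse_walk_name("GaXx01_01"), "convention")
})

test_that("parse_walk_file maps 19 columns in file order", {
  left <- c(10, 20, 30, 40, 50, 60, 70, 80)
  right <- c(1, 2, 3, 4, 5, 6, 7, 8)
  rec <- parse_walk_file(make_lines(3, left = left, right = right),
                         "GaPt03_01")
  expect_s3_class(rec, "gait_recording")
  expect_equal(rec$group, "pd")
  expect_equal(rec$fs, 100)
  expect_equal(diff(rec$time_s), rep(0.01, 2))
  expect_equal(unname(rec$sensors_left[1, ]), left)
  expect_equal(unname(rec$sensors_right[2, ]), right)
  expect_equal(rec$total_left, rep(360, 3))
  expect_equal(rec$total_right, rep(36, 3))
})

test_that("malformed lines are rejected with their line number", {
  lines <- make_lines(3)
  lines[2] <- "0.01 1 2 3"
  expect_error(parse_walk_file(lines, "GaPt03_01"), "line 2")
  lines <- make_lines(3)
  lines[3] <- sub("^0.02", "abc", lines[3])
  expect_error(parse_walk_file(lines, "GaPt03_01"), "line 3")
})

test_that("total column inconsistent with sensor sum is a consistency error", {
  lines <- make_lines(3)
  parts <- strsplit(lines[2], " ")[[1]]
  parts[18] <- "999" # stored left total far from the sensor sum
  lines[2] <- paste(parts, collapse = " ")
  expect_error(parse_walk_file(lines, "GaPt03_01"), "disagrees")
})

test_that("write/parse round-trips all numeric fields to file precision", {
  rec <- generate_subject(gait_profile(), duration_s = 3, seed = 11,
                          subject_id = "SiCo02", group = "control",
                          study_tag = "Si")
  lines <- write_walk_file(rec)
  rec2 <- parse_walk_file(lines, walk_file_name(rec))
  expect_equal(rec2$time_s, rec$time_s, tolerance = 1e-9)
  expect_equal(unname(rec2$sensors_left), unname(round(rec$sensors_left, 3)))
  expect_equal(rec2$total_left, round(rec$total_left, 3), tolerance = 1e-9)
  expect_equal(rec2$subject_id, rec$subject_id)
  expect_equal(rec2$walk_index, rec$walk_index)
})

test_that("every generated walk file parses without error", {
  co <- tiny_cohort()
  for (rec in co$recordings) {
    lines <- write_walk_file(rec)
    expect_no_error(parse_walk_file(lines, walk_file_name(rec)))
  }
})

test_that("foot_sum_series matches the stored totals and supports ablation", {
  rec <- tiny_cohort()$recordings[[1]]
  expect_equal(foot_sum_series(rec, "left"), rec$total_left,
               tolerance = 1e-9)
  expect_equal(foot_sum_series(rec, "right"), rec$total_right,
               tolerance = 1e-9)
  # ablation keep-set: remaining four sensors per foot
  kept <- foot_sum_series(rec, "left", keep_sensors = c(1, 4, 5, 8))
  expect_equal(kept, rowSums(rec$sensors_left[, c(1, 4, 5, 8)]))
  expect_true(all(kept <= rec$total_left + 1e-9))
  expect_error(foot_sum_series(rec, "left", keep_sensors = integer(0)),
               "at least one")
  # single-sample sanity: channels [1..8], keep {1,2} -> 3
  one <- gait_recording("GaCo01", "Ga", "control", 1, 100, 0,
                        matrix(1:8, 1), matrix(1:8, 1), 36, 36)
  expect_equal(foot_sum_series(one, "left", 1:2), 3)
})

test_that("demographics loading flags inconsistent rows and rejects dupes", {
  df <- data.frame(subject_id = c("GaCo01", "GaPt01"),
                   group = c("control", "pd"),
                   gender = c("male", "female"),
                   age = c(60, 70), walking_speed = c(1.2, 1.0),
                   hoehn_yahr = c(NA, 2), updrs = c(NA, 30),
                   updrsm = c(NA, 18), tug_s = c(NA, 12))
  subj <- load_demographics(df)
  expect_s3_class(subj, "subject_table")
  expect_false(any(subj$incomplete))

  # control carrying a score -> incomplete flag, not an error
  df2 <- df
  df2$updrs[1] <- 10
  expect_warning(subj2 <- load_demographics(df2), "incomplete")
  expect_true(subj2$incomplete[1])

  # PD row missing a score -> incomplete
  df3 <- df
  df3$tug_s[2] <- NA
  expect_warning(subj3 <- load_demographics(df3), "incomplete")
  expect_true(subj3$incomplete[2])

  df4 <- rbind(df, df[2, ])
  expect_error(load_demographics(df4), "duplicate")

  empty <- load_demographics(df[0, ])
  expect_equal(nrow(empty), 0L)

  # out-of-range score warns but does not error
  df5 <- df
  df5$hoehn_yahr[2] <- 1.7
  expect_warning(load_demographics(df5), "Hoehn")
})

test_that("cohort write/read round-trips through a directory", {
  co <- tiny_cohort()
  dir <- withr::local_tempdir()
  write_cohort(co$recordings, co$subjects, dir, force = TRUE)
  expect_error(write_cohort(co$recordings, co$subjects, dir), "not empty")
  back <- read_cohort(dir)
  expect_equal(length(back$recordings), length(co$recordings))
  expect_setequal(back$subjects$subject_id, co$subjects$subject_id)
  ids <- vapply(back$recordings, `[[`, "", "subject_id")
  expect_setequal(ids, co$subjects$subject_id)
})
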