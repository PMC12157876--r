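test_that("profile and link constructors validate their domains", {
  expect_error(gait_profile(cycle_mean_s = 0), "positive")
  expect_error(gait_profile(cycle_cv = 1), "cycle_cv")
  expect_error(gait_profile(asymmetry = 1), "asymmetry")
  expect_error(severity_link(tug = c(8, -1)), "increasing")
})

test_that("identical seed and arguments give bitwise-identical recordings", {
  a <- generate_subject(gait_profile(), duration_s = 5, seed = 3)
  b <- generate_subject(gait_profile(), duration_s = 5, seed = 3)
  expect_identical(a, b)
  c <- generate_subject(gait_profile(), duration_s = 5, seed = 4)
  expect_false(identical(a$total_left, c$total_left))
})

test_that("control default produces the expected stance count in 10 s", {
  # 10 s / 1.1 s per cycle ~ 9 stance episodes per foot
  for (seed in 1:5) {
    rec <- generate_subject(gait_profile(), duration_s = 10, seed = seed)
    expect_gte(count_stance_episodes(rec$total_left), 8)
    expect_lte(count_stance_episodes(rec$total_left), 10)
    expect_gte(count_stance_episodes(rec$total_right), 8)
    expect_lte(count_stance_episodes(rec$total_right), 10)
  }
})

test_that("feet alternate: no mid-recording interval with both feet unloaded", {
  rec <- generate_subject(gait_profile(), duration_s = 20, seed = 5)
  combined <- rec$total_left + rec$total_right
  thr <- 0.05 * max(combined)
  # trim the ramp-in/out, then look for >= 1 s of simultaneous unloading
  mid <- combined[100:(length(combined) - 100)]
  runs <- rle(mid < thr)
  low <- runs$lengths[runs$values]
  expect_true(length(low) == 0 || max(low) < rec$fs)
})

test_that("recordings satisfy the declared invariants", {
  co <- tiny_cohort()
  for (rec in co$recordings) {
    expect_true(all(rec$total_left >= 0))
    expect_true(all(rec$total_right >= 0))
    expect_equal(rowSums(rec$sensors_left), rec$total_left, tolerance = 1e-9)
    expect_true(all(rec$sensors_left >= 0))
    expect_equal(diff(rec$time_s), rep(1 / rec$fs, length(rec$time_s) - 1))
  }
})

test_that("cycle duration mean and CV are recoverable from the signal", {
  prof <- gait_profile(cycle_mean_s = 1.2, cycle_cv = 0.08)
  rec <- generate_subject(prof, duration_s = 120, seed = 21)
  onsets <- stance_onset_times(rec$total_left, rec$fs)
  gaps <- diff(onsets)
  gaps <- gaps[gaps > 0.5 * prof$cycle_mean_s] # guard against split episodes
  expect_equal(mean(gaps), prof$cycle_mean_s, tolerance = 0.1)
  expect_equal(stats::sd(gaps) / mean(gaps), prof$cycle_cv, tolerance = 0.5)
})

test_that("PD cohorts walk slower than controls (fewer stance episodes)", {
  co <- generate_cohort(20, 20, duration_s = 10, seed = 9)
  groups <- vapply(co$recordings, `[[`, "", "group")
  peaks <- vapply(co$recordings, function(r)
    count_stance_episodes(r$total_left), numeric(1))
  expect_lt(mean(peaks[groups == "pd"]), mean(peaks[groups == "control"]))
  tt <- stats::t.test(peaks[groups == "pd"], peaks[groups == "control"],
                      alternative = "less")
  expect_lt(tt$p.value, 0.01)
})

test_that("asymmetry statistic is monotone in the asymmetry parameter", {
  lr_gap <- function(asym) {
    gaps <- vapply(1:10, function(s) {
      rec <- generate_subject(gait_profile(asymmetry = asym),
                              duration_s = 15, seed = 400 + s)
      qL <- stats::quantile(rec$total_left, 0.95)
      qR <- stats::quantile(rec$total_right, 0.95)
      (qL - qR) / (qL + qR)
    }, numeric(1))
    mean(gaps)
  }
  stats <- vapply(c(0, 0.1, 0.2, 0.3), lr_gap, numeric(1))
  expect_true(all(diff(stats) >= 0))
})

test_that("zero-noise severity link reproduces the affine TUG mapping", {
  link <- severity_link()
  for (z in c(0, 0.25, 0.6, 1)) {
    sc <- scores_from_z(link, z, noise_scale = 0)
    expect_equal(sc$tug_s, link$tug[1] + link$tug[2] * z)
    expect_lte(sc$updrsm, sc$updrs)
    expect_true(sc$hoehn_yahr %in% link$hy_values)
  }
  # Hoehn & Yahr thresholds
  expect_equal(scores_from_z(link, 0.5, 0)$hoehn_yahr, 2)
  expect_equal(scores_from_z(link, 0.7, 0)$hoehn_yahr, 2.5)
  expect_equal(scores_from_z(link, 0.9, 0)$hoehn_yahr, 3)
})

test_that("cohort structure: ids unique, scores only on PD, z recorded", {
  co <- generate_cohort(3, 5, duration_s = 6, seed = 2)
  subj <- co$subjects
  expect_equal(anyDuplicated(subj$subject_id), 0L)
  expect_equal(sum(subj$group == "pd"), 5L)
  expect_true(all(is.na(subj$tug_s[subj$group == "control"])))
  expect_true(all(!is.na(subj$tug_s[subj$group == "pd"])))
  expect_true(all(subj$latent_severity[subj$group == "pd"] >= 0 &
                    subj$latent_severity[subj$group == "pd"] <= 1))
  empty <- generate_cohort(0, 0, seed = 1)
  expect_equal(length(empty$recordings), 0L)
  expect_equal(nrow(empty$subjects), 0L)
})

test_that("cohorts are reproducible from the master seed", {
  a <- generate_cohort(2, 2, duration_s = 5, seed = 31)
  b <- generate_cohort(2, 2, duration_s = 5, seed = 31)
  expect_identical(a$recordings, b$recordings)
  expect_identical(a$subjects, b$subjects)
})

test_that("add_gaussian_noise honours sigma and seed", {
  x <- sin(seq(0, 10, length.out = 1e5))
  expect_identical(add_gaussian_noise(x, 0), x)
  y1 <- add_gaussian_noise(x, 0.05, seed = 5)
  y2 <- add_gaussian_noise(x, 0.05, seed = 5)
  expect_identical(y1, y2)
  expect_equal(stats::sd(y1 - x), 0.05, tolerance = 0.02) # in [0.049, 0.051]
  expect_gt(stats::sd(y1 - x), 0.049)
  expect_lt(stats::sd(y1 - x), 0.051)
  expect_error(add_gaussian_noise(x, -1), "non-negative")
})
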