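# RNG plumbing: a single cohort seed fans out to per-subject substreams via a
# counter, so cohorts are reproducible even if subjects are generated in a
# different order. Substream seeds stay below 2^31 - 1.
substream_seed <- function(seed, counter) {
  as.integer(((as.double(seed) %% 2147483647) * 2654435 +
                as.double(counter) * 100003) %% 2147483647)
}

with_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
        rm(".Random.seed", envir = .GlobalEnv)
    } else assign(".Random.seed", old, envir = .GlobalEnv)
  })
  set.seed(seed)
  expr
}

#' Gait profile for the synthetic generator
#'
#' Parameters governing one subject's simulated walking pattern. The stance
#' waveform is the characteristic M-shape of vertical ground reaction force:
#' a heel-strike bump followed by a toe-off bump.
#'
#' @param cycle_mean_s Mean gait-cycle duration (seconds, heel-strike to
#'   heel-strike of the same foot).
#' @param cycle_cv Coefficient of variation of cycle durations (unitless,
#'   in `[0, 1)`), the stride-to-stride variability.
#' @param amplitude_n Peak stance force (Newtons, roughly body weight).
#' @param asymmetry Fractional left/right imbalance in `[0, 1)`: the right
#'   foot's amplitude is scaled by `1 - asymmetry` and its phase offset is
#'   shifted away from the ideal half cycle.
#' @param freeze_rate_hz Expected freezing episodes per second (0 disables).
#' @param noise_sigma Additive observation noise SD on the unit-normalized
#'   force scale.
#' @return A list of class `"gait_profile"`.
#' @seealso [generate_subject()], [default_profiles()]
#' @export
gait_profile <- function(cycle_mean_s = 1.1, cycle_cv = 0.03,
                         amplitude_n = 700, asymmetry = 0.02,
                         freeze_rate_hz = 0, noise_sigma = 0.02) {
  if (!(cycle_mean_s > 0)) stop("cycle_mean_s must be positive")
  if (cycle_cv < 0 || cycle_cv >= 1) stop("cycle_cv must lie in [0, 1)")
  if (!(amplitude_n > 0)) stop("amplitude_n must be positive")
  if (asymmetry < 0 || asymmetry >= 1) stop("asymmetry must lie in [0, 1)")
  if (freeze_rate_hz < 0) stop("freeze_rate_hz must be non-negative")
  if (noise_sigma < 0) stop("noise_sigma must be non-negative")
  structure(list(cycle_mean_s = cycle_mean_s, cycle_cv = cycle_cv,
                 amplitude_n = amplitude_n, asymmetry = asymmetry,
                 freeze_rate_hz = freeze_rate_hz, noise_sigma = noise_sigma),
            class = "gait_profile")
}

#' Default group profiles
#'
#' Control and parkinsonian cohorts are separable but overlapping: patients
#' walk with a longer mean cycle, higher stride-to-stride variability and
#' more left/right asymmetry, consistent with the direction of the walking
#' speed gap between groups in public insole cohorts.
#'
#' @return Named list with `control` and `pd` [gait_profile()]s.
#' @export
default_profiles <- function() {
  list(control = gait_profile(cycle_mean_s = 1.1, cycle_cv = 0.03,
                              amplitude_n = 700, asymmetry = 0.02),
       pd = gait_profile(cycle_mean_s = 1.35, cycle_cv = 0.10,
                         amplitude_n = 650, asymmetry = 0.12))
}

#' Severity link: latent severity to gait parameters and clinical scores
#'
#' A latent severity `z` in `[0, 1]` drives both the gait profile (longer
#' cycles, more variability, more asymmetry as `z` grows) and the four
#' clinical scores. TUG is strictly increasing in `z` before noise. Hoehn &
#' Yahr is emitted by thresholding `z` into stages {2, 2.5, 3}, mirroring
#' the stage mix typical of ambulatory insole cohorts. The UPDRS motor
#' sub-score is generated as a noisy fraction of UPDRS and clamped so it
#' never exceeds the total.
#'
#' @param cycle_mean,cycle_cv,asymmetry Length-2 numeric `(intercept, slope)`
#'   affine maps from `z` to the corresponding [gait_profile()] field.
#' @param tug `(intercept, slope)` affine map from `z` to TUG seconds;
#'   slope must be positive. `tug_sd` is the additive noise SD (seconds).
#' @param updrs `(intercept, slope)` map to UPDRS points, noise `updrs_sd`.
#' @param updrsm_frac Fraction of UPDRS forming the expected motor score;
#'   noise `updrsm_sd`.
#' @param hy_breaks Thresholds on `z` separating stages; `hy_values` the
#'   emitted stages.
#' @return A list of class `"severity_link"`.
#' @export
severity_link <- function(cycle_mean = c(1.2, 0.3), cycle_cv = c(0.05, 0.10),
                          asymmetry = c(0.05, 0.15),
                          tug = c(8, 8), tug_sd = 0.5,
                          updrs = c(15, 40), updrs_sd = 6,
                          updrsm_frac = 0.6, updrsm_sd = 3,
                          hy_breaks = c(0.55, 0.85),
                          hy_values = c(2, 2.5, 3)) {
  if (tug[2] <= 0) stop("TUG must be strictly increasing in severity")
  if (length(hy_values) != length(hy_breaks) + 1L)
    stop("hy_values must have one more element than hy_breaks")
  structure(list(cycle_mean = cycle_mean, cycle_cv = cycle_cv,
                 asymmetry = asymmetry, tug = tug, tug_sd = tug_sd,
                 updrs = updrs, updrs_sd = updrs_sd,
                 updrsm_frac = updrsm_frac, updrsm_sd = updrsm_sd,
                 hy_breaks = hy_breaks, hy_values = hy_values),
            class = "severity_link")
}

#' Gait profile implied by a latent severity
#'
#' @param link A [severity_link()].
#' @param z Latent severity in `[0, 1]`.
#' @param base Base [gait_profile()] supplying the fields the link does not
#'   set (amplitude, freezing, noise).
#' @return A [gait_profile()].
#' @export
profile_from_z <- function(link, z, base = default_profiles()$pd) {
  stopifnot(inherits(link, "severity_link"), z >= 0, z <= 1)
  gait_profile(cycle_mean_s = link$cycle_mean[1] + link$cycle_mean[2] * z,
               cycle_cv = min(link$cycle_cv[1] + link$cycle_cv[2] * z, 0.5),
               amplitude_n = base$amplitude_n,
               asymmetry = min(link$asymmetry[1] + link$asymmetry[2] * z, 0.9),
               freeze_rate_hz = base$freeze_rate_hz,
               noise_sigma = base$noise_sigma)
}

#' Clinical scores implied by a latent severity
#'
#' With `noise_scale = 0` the mapping is the exact affine form of the link
#' (TUG) and its deterministic derived quantities, which makes the link
#' testable; with the default `noise_scale = 1` the stated noise SDs apply.
#'
#' @param link A [severity_link()].
#' @param z Latent severity in `[0, 1]`.
#' @param noise_scale Multiplier on the link's noise SDs.
#' @return One-row data.frame with `hoehn_yahr`, `updrs`, `updrsm`, `tug_s`.
#' @export
scores_from_z <- function(link, z, noise_scale = 1) {
  stopifnot(inherits(link, "severity_link"), z >= 0, z <= 1)
  tug <- link$tug[1] + link$tug[2] * z +
    noise_scale * stats::rnorm(1, 0, link$tug_sd)
  tug <- max(tug, 3)
  updrs <- link$updrs[1] + link$updrs[2] * z +
    noise_scale * stats::rnorm(1, 0, link$updrs_sd)
  updrs <- round(min(max(updrs, 5), 108))
  updrsm <- link$updrsm_frac * updrs +
    noise_scale * stats::rnorm(1, 0, link$updrsm_sd)
  updrsm <- round(min(max(updrsm, 0), updrs))
  hy <- link$hy_values[findInterval(z, link$hy_breaks) + 1L]
  data.frame(hoehn_yahr = hy, updrs = updrs, updrsm = updrsm, tug_s = tug)
}

# One foot's force trace: stance episodes at the given heel-strike times,
# each an M-shaped pair of Gaussian bumps (heel-strike then toe-off peak).
# Returns the total plus the two bump components, which later drive the
# phase-dependent split of the total across the 8 insole sensors.
.foot_trace <- function(n, fs, heel_times, cycle_durs, amps) {
  total <- numeric(n)
  heel <- numeric(n)
  toe <- numeric(n)
  for (k in seq_along(heel_times)) {
    stance <- 0.62 * cycle_durs[k]
    i0 <- max(1L, floor(heel_times[k] * fs) + 1L)
    i1 <- min(n, ceiling((heel_times[k] + stance) * fs) + 1L)
    if (i0 > n || i1 < 1L || i1 < i0) next
    tt <- ((i0:i1) - 1) / fs - heel_times[k]
    sd <- 0.16 * stance
    b1 <- amps[k] * exp(-((tt - 0.28 * stance) / sd)^2 / 2)
    b2 <- 0.95 * amps[k] * exp(-((tt - 0.72 * stance) / sd)^2 / 2)
    idx <- i0:i1
    heel[idx] <- heel[idx] + b1
    toe[idx] <- toe[idx] + b2
    total[idx] <- total[idx] + b1 + b2
  }
  list(total = total, heel = heel, toe = toe)
}

# Split a foot total across 8 sensor channels. Base spatial weights are
# modulated by the heel/toe phase balance (heel-side sensors load early in
# stance, toe-side late), then renormalized per sample so the 8 channels sum
# exactly to the total.
.sensor_split <- function(total, heel, toe) {
  base <- c(0.10, 0.12, 0.13, 0.15, 0.15, 0.13, 0.12, 0.10)
  gamma <- c(0.8, 0.6, 0.3, 0.0, 0.0, -0.3, -0.6, -0.8) # + = heel-weighted
  frac_heel <- heel / (heel + toe + 1e-9)
  w <- outer(frac_heel - 0.5, gamma) # n x 8
  w <- sweep(1 + w, 2L, base, `*`)
  w[w < 1e-3] <- 1e-3
  w <- w / rowSums(w)
  w * total
}

#' Generate one synthetic gait recording
#'
#' Simulates a walking trial: per-foot vertical ground reaction force totals
#' alternate between near-zero swing phases and M-shaped stance bumps, the
#' two feet are anti-phase (about half a cycle apart), cycle durations are
#' drawn i.i.d. with the profile's mean and coefficient of variation, and
#' the 8 per-sensor channels are a non-negative decomposition of the foot
#' total (summing to it exactly). Identical arguments and seed give a
#' bitwise-identical recording.
#'
#' @param profile A [gait_profile()].
#' @param duration_s Recording length in seconds (>= `1/fs`).
#' @param fs Sampling frequency in Hz.
#' @param seed Integer seed for this recording's private RNG stream.
#' @param subject_id,group,study_tag,walk_index Identity of the emitted
#'   [gait_recording()].
#' @return A [gait_recording()].
#' @examples
#' rec <- generate_subject(gait_profile(), duration_s = 10, seed = 1)
#' range(rec$total_left)
#' @export
generate_subject <- function(profile, duration_s = 60, fs = 100, seed = 1,
                             subject_id = "GaCo01", group = "control",
                             study_tag = "Ga", walk_index = 1L) {
  stopifnot(inherits(profile, "gait_profile"))
  if (duration_s < 1 / fs) stop("duration_s must be at least one sample")
  with_rng(seed, {
    n <- round(duration_s * fs)
    k_max <- ceiling(duration_s / profile$cycle_mean_s * 1.6) + 8L
    sd_c <- profile$cycle_cv * profile$cycle_mean_s
    cyc_l <- pmax(stats::rnorm(k_max, profile$cycle_mean_s, sd_c),
                  0.4 * profile$cycle_mean_s)
    cyc_r <- pmax(stats::rnorm(k_max, profile$cycle_mean_s, sd_c),
                  0.4 * profile$cycle_mean_s)
    amp_l <- profile$amplitude_n * pmax(1 + 0.04 * stats::rnorm(k_max), 0.5)
    amp_r <- amp_l * (1 - profile$asymmetry) *
      pmax(1 + 0.04 * stats::rnorm(k_max), 0.5) / pmax(1, 1)
    start <- stats::runif(1, 0.05, 0.2)
    heel_l <- start + c(0, cumsum(cyc_l[-k_max]))
    offset <- cyc_l * (0.5 + 0.25 * profile$asymmetry)
    heel_r <- heel_l + offset
    left <- .foot_trace(n, fs, heel_l, cyc_l, amp_l)
    right <- .foot_trace(n, fs, heel_r, cyc_r, amp_r)

    if (profile$freeze_rate_hz > 0) {
      n_ep <- stats::rpois(1, profile$freeze_rate_hz * duration_s)
      if (n_ep > 0) {
        for (e in seq_len(n_ep)) {
          t0 <- stats::runif(1, 0, duration_s)
          len <- stats::runif(1, 0.8, 2.0)
          idx <- which(((seq_len(n) - 1) / fs) >= t0 &
                         ((seq_len(n) - 1) / fs) < t0 + len)
          left$total[idx] <- left$total[idx] * 0.05
          left$heel[idx] <- left$heel[idx] * 0.05
          left$toe[idx] <- left$toe[idx] * 0.05
          right$total[idx] <- right$total[idx] * 0.05
          right$heel[idx] <- right$heel[idx] * 0.05
          right$toe[idx] <- right$toe[idx] * 0.05
        }
      }
    }
    if (profile$noise_sigma > 0) {
      scl <- profile$amplitude_n
      left$total <- pmax(left$total +
                           stats::rnorm(n, 0, profile$noise_sigma * scl), 0)
      right$total <- pmax(right$total +
                            stats::rnorm(n, 0, profile$noise_sigma * scl), 0)
    }
    sens_l <- .sensor_split(left$total, left$heel, left$toe)
    sens_r <- .sensor_split(right$total, right$heel, right$toe)
    gait_recording(subject_id = subject_id, study_tag = study_tag,
                   group = group, walk_index = walk_index, fs = fs,
                   time_s = (seq_len(n) - 1) / fs,
                   sensors_left = sens_l, sensors_right = sens_r,
                   total_left = rowSums(sens_l), total_right = rowSums(sens_r))
  })
}

#' Generate a synthetic cohort
#'
#' Controls receive mild per-subject variation around the control profile;
#' patients receive a per-subject latent severity `z ~ Uniform(0, 1)` that
#' the [severity_link()] maps to gait parameters and four clinical scores.
#' The emitted demographics mirror the structure of public insole cohorts
#' (gender mix, ages, walking speed decreasing with severity).
#'
#' @param n_control,n_pd Subject counts (>= 0).
#' @param control_profile,pd_profile Group [gait_profile()]s.
#' @param severity A [severity_link()].
#' @param duration_s,fs Recording length (seconds) and sampling rate (Hz).
#' @param seed Master seed; per-subject substreams are derived from it, so
#'   the cohort is reproducible under reordering.
#' @return List with `recordings` (one [gait_recording()] per subject) and
#'   `subjects` (a subject table; patients carry scores and their latent
#'   severity in column `latent_severity`).
#' @export
generate_cohort <- function(n_control, n_pd,
                            control_profile = default_profiles()$control,
                            pd_profile = default_profiles()$pd,
                            severity = severity_link(),
                            duration_s = 60, fs = 100, seed = 1) {
  stopifnot(n_control >= 0, n_pd >= 0)
  recordings <- list()
  rows <- list()
  for (i in seq_len(n_control)) {
    id <- sprintf("GaCo%02d", i)
    meta_seed <- substream_seed(seed, 2L * i)
    prof <- with_rng(meta_seed, {
      gait_profile(
        cycle_mean_s = max(stats::rnorm(1, control_profile$cycle_mean_s, 0.06), 0.6),
        cycle_cv = max(control_profile$cycle_cv * exp(0.2 * stats::rnorm(1)), 0.005),
        amplitude_n = max(stats::rnorm(1, control_profile$amplitude_n, 70), 300),
        asymmetry = min(max(control_profile$asymmetry + 0.01 * abs(stats::rnorm(1)), 0), 0.9),
        freeze_rate_hz = control_profile$freeze_rate_hz,
        noise_sigma = control_profile$noise_sigma)
    })
    demo <- with_rng(meta_seed + 1L, data.frame(
      subject_id = id, group = "control",
      gender = sample(c("male", "female"), 1, prob = c(0.54, 0.46)),
      age = round(max(stats::rnorm(1, 63.6, 8.6), 35)),
      walking_speed = round(max(stats::rnorm(1, 1.24, 0.16), 0.4), 2),
      hoehn_yahr = NA_real_, updrs = NA_real_, updrsm = NA_real_,
      tug_s = NA_real_, latent_severity = NA_real_))
    recordings[[id]] <- generate_subject(
      prof, duration_s = duration_s, fs = fs,
      seed = substream_seed(seed, 2L * i + 1L),
      subject_id = id, group = "control")
    rows[[id]] <- demo
  }
  for (i in seq_len(n_pd)) {
    id <- sprintf("GaPt%02d", i)
    meta_seed <- substream_seed(seed, 10000L + 2L * i)
    sub <- with_rng(meta_seed, {
      z <- stats::runif(1)
      list(z = z,
           scores = scores_from_z(severity, z),
           gender = sample(c("male", "female"), 1, prob = c(0.64, 0.36)),
           age = round(max(stats::rnorm(1, 66.3, 9.4), 35)),
           speed = round(max(1.24 - 0.4 * z + stats::rnorm(1, 0, 0.12), 0.3), 2),
           amp = max(stats::rnorm(1, pd_profile$amplitude_n, 70), 300))
    })
    prof <- profile_from_z(severity, sub$z, base = pd_profile)
    prof$amplitude_n <- sub$amp
    recordings[[id]] <- generate_subject(
      prof, duration_s = duration_s, fs = fs,
      seed = substream_seed(seed, 10000L + 2L * i + 1L),
      subject_id = id, group = "pd")
    rows[[id]] <- data.frame(
      subject_id = id, group = "pd", gender = sub$gender, age = sub$age,
      walking_speed = sub$speed,
      hoehn_yahr = sub$scores$hoehn_yahr, updrs = sub$scores$updrs,
      updrsm = sub$scores$updrsm, tug_s = sub$scores$tug_s,
      latent_severity = sub$z)
  }
  subjects <- if (length(rows)) do.call(rbind, unname(rows)) else
    data.frame(subject_id = character(0), group = character(0),
               gender = character(0), age = numeric(0),
               walking_speed = numeric(0), hoehn_yahr = numeric(0),
               updrs = numeric(0), updrsm = numeric(0), tug_s = numeric(0),
               latent_severity = numeric(0))
  subjects <- suppressWarnings(load_demographics(subjects))
  list(recordings = unname(recordings), subjects = subjects)
}

#' Add seeded Gaussian observation noise to a signal
#'
#' @param x Numeric signal on the unit-normalized scale.
#' @param sigma Noise standard deviation (>= 0). `sigma = 0` returns `x`
#'   unchanged.
#' @param seed Optional integer seed for a private RNG stream.
#' @return `x + e`, `e ~ N(0, sigma^2)` i.i.d.
#' @export
add_gaussian_noise <- function(x, sigma, seed = NULL) {
  if (!is.numeric(sigma) || length(sigma) != 1L || is.na(sigma) || sigma < 0)
    stop("sigma must be a single non-negative number")
  if (sigma == 0) return(x)
  draw <- function() x + stats::rnorm(length(x), 0, sigma)
  if (is.null(seed)) draw() else with_rng(seed, draw())
}
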