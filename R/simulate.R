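#' Simulation configuration for a synthetic screening cohort
#'
#' Bundles and validates every parameter of the synthetic-data generator.
#' Population defaults emulate a pre-operative hip-arthroplasty cohort:
#' flexed-seated tilt changes are wide and occur in both anterior and
#' posterior directions (about 43% of patients exceed the 13-degree
#' mobility threshold), step-up changes are markedly narrower, and the
#' radiographic reference carries its own measurement noise. Device-side
#' noise has three components: white accelerometer noise, slow sinusoidal
#' postural sway, and occasional transient knock artefacts that the
#' stable-window selection must reject.
#'
#' @param n_patients Number of patients (> 0).
#' @param fs_delta_mean,fs_delta_sd Population mean/SD of the true
#'   flexed-seated tilt change (degrees).
#' @param su_delta_mean,su_delta_sd Same for step-up (degrees).
#' @param standing_pitch_mean,standing_pitch_sd Population distribution of
#'   the true standing pelvic pitch (degrees).
#' @param reference_noise_sd SD of Gaussian noise added to the true deltas
#'   to form the radiograph-like reference measurement (degrees).
#' @param accel_white_sd White accelerometer noise SD, in g, per channel.
#' @param sway_amplitude_deg Amplitude of sinusoidal postural sway in pitch
#'   (degrees).
#' @param sway_freq_hz Sway frequency (Hz).
#' @param knock_prob Probability that a capture contains a transient knock
#'   artefact.
#' @param knock_magnitude_g Peak acceleration of a knock burst (g).
#' @param su_error_slope Magnitude-dependent device error for step-up: an
#'   extra Gaussian pitch error with SD `su_error_slope * |true delta|`,
#'   emulating the observed correlation between step-up error and movement
#'   magnitude.
#' @param duration_s Capture hold duration in seconds (>= 0.3).
#' @param sample_rate_hz Sampling rate (default 200 Hz).
#' @param threshold_deg Mobility threshold used for ground-truth labels.
#' @param seed Integer seed; a fixed seed makes [simulate_cohort()] output
#'   bit-identical across runs.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 32,
                       fs_delta_mean = -10, fs_delta_sd = 12,
                       su_delta_mean = 2, su_delta_sd = 4,
                       standing_pitch_mean = 5, standing_pitch_sd = 5,
                       reference_noise_sd = 2,
                       accel_white_sd = 0.01,
                       sway_amplitude_deg = 1, sway_freq_hz = 0.3,
                       knock_prob = 0.1, knock_magnitude_g = 0.5,
                       su_error_slope = 0.1,
                       duration_s = 5, sample_rate_hz = 200,
                       threshold_deg = 13,
                       seed = NULL) {
  cfg <- list(
    n_patients = n_patients,
    fs_delta_mean = fs_delta_mean, fs_delta_sd = fs_delta_sd,
    su_delta_mean = su_delta_mean, su_delta_sd = su_delta_sd,
    standing_pitch_mean = standing_pitch_mean,
    standing_pitch_sd = standing_pitch_sd,
    reference_noise_sd = reference_noise_sd,
    accel_white_sd = accel_white_sd,
    sway_amplitude_deg = sway_amplitude_deg, sway_freq_hz = sway_freq_hz,
    knock_prob = knock_prob, knock_magnitude_g = knock_magnitude_g,
    su_error_slope = su_error_slope,
    duration_s = duration_s, sample_rate_hz = sample_rate_hz,
    threshold_deg = threshold_deg,
    seed = seed
  )
  check_field <- function(name, ok) {
    v <- cfg[[name]]
    if (is.null(v) || length(v) != 1L || !is.numeric(v) || !is.finite(v) ||
        !ok(v)) {
      stop("invalid simulation config field `", name, "`", call. = FALSE)
    }
  }
  check_field("n_patients", function(v) v >= 1 && v == round(v))
  for (f in c("fs_delta_sd", "su_delta_sd", "standing_pitch_sd",
              "reference_noise_sd", "accel_white_sd", "sway_amplitude_deg",
              "su_error_slope", "knock_magnitude_g")) {
    check_field(f, function(v) v >= 0)
  }
  check_field("knock_prob", function(v) v >= 0 && v <= 1)
  check_field("sway_freq_hz", function(v) v >= 0)
  check_field("duration_s", function(v) v >= 0.3)
  check_field("sample_rate_hz", function(v) v > 0)
  check_field("threshold_deg", function(v) v >= 0)
  for (f in c("fs_delta_mean", "su_delta_mean", "standing_pitch_mean")) {
    check_field(f, function(v) TRUE)
  }
  if (!is.null(seed)) {
    if (length(seed) != 1L || !is.finite(seed) || seed != round(seed)) {
      stop("invalid simulation config field `seed`", call. = FALSE)
    }
    cfg$seed <- as.integer(seed)
  }
  structure(cfg, class = "sim_config")
}

#' Simulate a static-capture accelerometer trace
#'
#' Generates the signal a sacrum-mounted accelerometer would record while a
#' patient holds a posture: the unit gravity vector rotated by the true
#' pitch about the frontal (Y) axis and by a small roll about the sagittal
#' (X) axis, sampled at `sample_rate_hz`, plus (optionally) white sensor
#' noise, sinusoidal postural sway in pitch, and a transient knock burst.
#' A knock, when present, is confined to the earlier part of the trace so
#' that at least the final 0.5 s remains artefact-free and a stable window
#' always exists.
#'
#' @param true_pitch_deg True pelvic pitch in degrees.
#' @param duration_s Trace duration in seconds (>= 0.3).
#' @param sample_rate_hz Sampling rate (Hz).
#' @param roll_deg True roll in degrees (default 0).
#' @param accel_white_sd White noise SD per channel, g.
#' @param sway_amplitude_deg,sway_freq_hz Sinusoidal pitch sway (random
#'   phase).
#' @param knock If `TRUE`, inject one transient burst (0.15 s raised-cosine
#'   on the X channel) at a random location outside the protected tail.
#' @param knock_magnitude_g Peak burst acceleration, g.
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @return An [accel_trace].
#' @examples
#' tr <- simulate_trace(10, duration_s = 1)
#' all.equal(unique(pitch_from_accel(tr$ax, tr$ay, tr$az)), 10)
#' @export
simulate_trace <- function(true_pitch_deg, duration_s = 5,
                           sample_rate_hz = 200, roll_deg = 0,
                           accel_white_sd = 0, sway_amplitude_deg = 0,
                           sway_freq_hz = 0.3, knock = FALSE,
                           knock_magnitude_g = 0.5, seed = NULL) {
  if (!is.finite(duration_s) || duration_s < 0.3) {
    stop("`duration_s` must be at least 0.3 s (one analysis window), got ",
         duration_s, call. = FALSE)
  }
  if (!is.null(seed)) withr::local_seed(seed)

  n <- as.integer(round(duration_s * sample_rate_hz))
  t <- (seq_len(n) - 1L) / sample_rate_hz

  pitch <- rep(true_pitch_deg, n)
  if (sway_amplitude_deg > 0 && sway_freq_hz > 0) {
    phase <- stats::runif(1, 0, 2 * pi)
    pitch <- pitch + sway_amplitude_deg * sin(2 * pi * sway_freq_hz * t + phase)
  }
  th <- pitch * pi / 180
  ph <- roll_deg * pi / 180
  # gravity in sensor frame after pitch about Y then roll about X
  ax <- -sin(th)
  ay <- sin(ph) * cos(th)
  az <- cos(ph) * cos(th)

  if (accel_white_sd > 0) {
    ax <- ax + stats::rnorm(n, 0, accel_white_sd)
    ay <- ay + stats::rnorm(n, 0, accel_white_sd)
    az <- az + stats::rnorm(n, 0, accel_white_sd)
  }

  if (isTRUE(knock)) {
    burst_s <- 0.15
    burst_n <- max(2L, as.integer(round(burst_s * sample_rate_hz)))
    protected_s <- 0.5 # artefact-free tail so a clean window survives
    latest_start <- duration_s - protected_s - burst_s
    if (latest_start > 0) {
      start_t <- stats::runif(1, 0, latest_start)
      i0 <- as.integer(floor(start_t * sample_rate_hz)) + 1L
      idx <- i0:min(n, i0 + burst_n - 1L)
      shape <- 0.5 * (1 - cos(2 * pi * seq_along(idx) / length(idx)))
      ax[idx] <- ax[idx] + knock_magnitude_g * shape
    }
  }

  accel_trace(t, ax, ay, az, sample_rate_hz = sample_rate_hz)
}

#' Simulate a ground-truthed screening cohort
#'
#' For each synthetic patient, draws a true standing pitch and true
#' flexed-seated / step-up tilt changes from the configured population
#' distributions, generates a four-capture session in protocol order
#' (standing, flexed-seated, standing, step-up) with [simulate_trace()],
#' and produces a radiograph-like reference measurement of each delta (true
#' delta plus Gaussian noise). Device deltas are then measured by running
#' the full pipeline ([screen_session()]) on the simulated traces, so the
#' paired measures reflect genuine end-to-end processing, not shortcuts.
#' Covariates (age, sex, BMI) are drawn from plausible clinic ranges and
#' have no effect on the error structure by default.
#'
#' @param config A [sim_config].
#' @return An object of class `sim_cohort`: list with
#'   \describe{
#'     \item{ground_truth}{tibble of true per-patient values and the true
#'       high-mobility label (`|FS delta| >= threshold`), plus covariates.}
#'     \item{sessions}{list of [session_record] objects.}
#'     \item{paired}{tibble of paired measures, one row per patient x
#'       functional position: `patient_id`, `position`, `device_delta_deg`
#'       (pipeline output), `reference_delta_deg`, `true_delta_deg`,
#'       covariates.}
#'     \item{config}{the configuration used.}
#'   }
#' @export
simulate_cohort <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  if (!is.null(config$seed)) withr::local_seed(config$seed)
  n <- config$n_patients

  truth <- tibble::tibble(
    patient_id = sprintf("P%03d", seq_len(n)),
    standing_pitch_deg = stats::rnorm(n, config$standing_pitch_mean,
                                      config$standing_pitch_sd),
    fs_delta_deg = stats::rnorm(n, config$fs_delta_mean, config$fs_delta_sd),
    su_delta_deg = stats::rnorm(n, config$su_delta_mean, config$su_delta_sd),
    age = round(stats::rnorm(n, 57.4, 9.4)),
    sex = ifelse(stats::runif(n) < 17 / 32, "female", "male"),
    bmi = round(stats::rnorm(n, 29.2, 4.6), 1)
  )
  truth$high_mobility <- abs(truth$fs_delta_deg) >= config$threshold_deg

  ref_fs <- truth$fs_delta_deg +
    stats::rnorm(n, 0, config$reference_noise_sd)
  ref_su <- truth$su_delta_deg +
    stats::rnorm(n, 0, config$reference_noise_sd)

  make_trace <- function(pitch) {
    simulate_trace(
      true_pitch_deg = pitch,
      duration_s = config$duration_s,
      sample_rate_hz = config$sample_rate_hz,
      roll_deg = 0,
      accel_white_sd = config$accel_white_sd,
      sway_amplitude_deg = config$sway_amplitude_deg,
      sway_freq_hz = config$sway_freq_hz,
      knock = stats::runif(1) < config$knock_prob,
      knock_magnitude_g = config$knock_magnitude_g
    )
  }

  sessions <- vector("list", n)
  device_fs <- numeric(n)
  device_su <- numeric(n)
  for (i in seq_len(n)) {
    base <- truth$standing_pitch_deg[i]
    # step-up device error grows with movement magnitude
    su_extra <- if (config$su_error_slope > 0) {
      stats::rnorm(1, 0, config$su_error_slope * abs(truth$su_delta_deg[i]))
    } else 0
    # radiograph tilt of the standing baseline: anchor reference deltas so
    # per-capture reference tilts difference back to ref_fs / ref_su exactly
    ref_standing <- base
    captures <- tibble::tibble(
      position = c("standing", "flexed_seated", "standing", "step_up"),
      trace = list(
        make_trace(base),
        make_trace(base + truth$fs_delta_deg[i]),
        make_trace(base),
        make_trace(base + truth$su_delta_deg[i] + su_extra)
      ),
      reference_tilt_deg = c(ref_standing, ref_standing + ref_fs[i],
                             ref_standing, ref_standing + ref_su[i])
    )
    sess <- suppressWarnings(session_record(
      captures, patient_id = truth$patient_id[i], age = truth$age[i],
      sex = truth$sex[i], bmi = truth$bmi[i],
      min_capture_s = min(5, config$duration_s)
    ))
    sessions[[i]] <- sess
    rep_i <- screen_session(sess, threshold_deg = config$threshold_deg)
    device_fs[i] <-
      rep_i$results$delta_pitch_deg[rep_i$results$position == "flexed_seated"]
    device_su[i] <-
      rep_i$results$delta_pitch_deg[rep_i$results$position == "step_up"]
  }

  paired <- tibble::tibble(
    patient_id = rep(truth$patient_id, 2L),
    position = rep(c("flexed_seated", "step_up"), each = n),
    device_delta_deg = c(device_fs, device_su),
    reference_delta_deg = c(ref_fs, ref_su),
    true_delta_deg = c(truth$fs_delta_deg, truth$su_delta_deg),
    age = rep(truth$age, 2L), sex = rep(truth$sex, 2L),
    bmi = rep(truth$bmi, 2L)
  )

  structure(
    list(ground_truth = truth, sessions = sessions, paired = paired,
         config = config),
    class = "sim_cohort"
  )
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic screening cohort: %d patients, %d paired measures\n",
    nrow(x$ground_truth), nrow(x$paired)))
  cat(sprintf("  true high-mobility prevalence: %.1f%%\n",
              100 * mean(x$ground_truth$high_mobility)))
  invisible(x)
}
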