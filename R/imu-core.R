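#' Pitch and roll from a static acceleration sample
#'
#' For a stationary sensor only gravity acts on the accelerometer, so the
#' measured acceleration vector points along gravity and orientation follows
#' from trigonometry. Pitch (anterior-posterior tilt, rotation about the
#' frontal Y axis) is
#' \deqn{\theta = \arctan\!\left(\frac{-a_x}{\sqrt{a_y^2 + a_z^2}}\right)}
#' and roll (medial-lateral, rotation about the sagittal X axis) is
#' \deqn{\phi = \mathrm{atan2}(a_y, a_z).}
#' Both are returned in degrees. Pitch is invariant under positive scaling of
#' the input vector, so uncalibrated gain does not bias the angle.
#'
#' @param ax,ay,az Acceleration components in g (vectorised; recycled to a
#'   common length).
#' @return Numeric vector of angles in degrees. Pitch lies in \[-90, 90\],
#'   roll in (-180, 180\].
#' @examples
#' pitch_from_accel(0, 0, 1)        # level: 0 degrees
#' pitch_from_accel(-0.5, 0, sqrt(3) / 2)  # 30 degrees anterior
#' roll_from_accel(0, 1, 0)         # 90 degrees
#' @export
pitch_from_accel <- function(ax, ay, az) {
  n <- max(length(ax), length(ay), length(az))
  ax <- rep_len(as.numeric(ax), n)
  ay <- rep_len(as.numeric(ay), n)
  az <- rep_len(as.numeric(az), n)
  norm2 <- ax^2 + ay^2 + az^2
  if (any(!is.finite(norm2))) {
    stop("acceleration samples must be finite", call. = FALSE)
  }
  if (any(norm2 == 0)) {
    stop("zero acceleration vector: no gravity component, pitch undefined",
         call. = FALSE)
  }
  atan2(-ax, sqrt(ay^2 + az^2)) * 180 / pi
}

#' @rdname pitch_from_accel
#' @export
roll_from_accel <- function(ax, ay, az) {
  n <- max(length(ax), length(ay), length(az))
  ay <- rep_len(as.numeric(ay), n)
  az <- rep_len(as.numeric(az), n)
  if (any(!is.finite(ay)) || any(!is.finite(az))) {
    stop("acceleration samples must be finite", call. = FALSE)
  }
  if (any(ay == 0 & az == 0)) {
    stop("ay = az = 0: roll undefined", call. = FALSE)
  }
  atan2(ay, az) * 180 / pi
}

# Causal moving average run forward then backward over a reflect-padded
# signal: zero net phase shift, constant signals pass through unchanged.
ma_forward_backward <- function(x, n_taps) {
  if (n_taps == 1L) return(x)
  L <- length(x)
  pad_l <- rev(x[2:(n_taps + 1L)])
  pad_r <- rev(x[(L - n_taps):(L - 1L)])
  xp <- c(pad_l, x, pad_r)
  k <- rep(1 / n_taps, n_taps)
  fwd <- stats::filter(xp, k, method = "convolution", sides = 1L)
  bwd <- rev(stats::filter(rev(fwd[!is.na(fwd)]), k, method = "convolution",
                           sides = 1L))
  core <- bwd[!is.na(bwd)]
  # after one causal pass each direction we lose (n_taps - 1) samples per
  # side of the padded signal; the original samples sit at a fixed offset
  start <- length(pad_l) - (n_taps - 1L) + 1L
  out <- core[start:(start + L - 1L)]
  as.numeric(out)
}

#' Zero-phase moving-average smoothing of a trace
#'
#' Each acceleration channel is smoothed with a moving average applied
#' forward and then backward, cancelling the filter's phase shift so that
#' stable segments are not displaced in time. Boundaries are reflect-padded
#' to avoid endpoint transients. A constant channel is returned unchanged.
#'
#' @param trace An [accel_trace].
#' @param filter_len_s Filter length in seconds; must round to at least one
#'   sample (a one-sample filter is the identity). Default 0.05 s (10 samples
#'   at 200 Hz).
#' @return A smoothed [accel_trace] of the same length and sampling rate.
#' @export
smooth_zero_phase <- function(trace, filter_len_s = 0.05) {
  fs <- trace_sample_rate(trace)
  n_taps <- max(1L, as.integer(round(filter_len_s * fs)))
  L <- nrow(trace)
  if (L <= n_taps) {
    stop(sprintf(
      "trace too short to filter: %d sample(s) but the moving average spans %d",
      L, n_taps), call. = FALSE)
  }
  out <- trace
  for (ch in c("ax", "ay", "az")) {
    out[[ch]] <- ma_forward_backward(trace[[ch]], n_taps)
  }
  out
}

#' Per-sample tilt series of a trace
#'
#' Computes pitch and roll at every sample, optionally after zero-phase
#' smoothing. Mostly a diagnostic/plotting aid; [select_stable_window()] is
#' the production path.
#'
#' @inheritParams smooth_zero_phase
#' @param smooth If `TRUE` (default) apply [smooth_zero_phase()] first.
#' @return Tibble with columns `t`, `pitch_deg`, `roll_deg`.
#' @export
tilt_series <- function(trace, filter_len_s = 0.05, smooth = TRUE) {
  tr <- if (smooth) smooth_zero_phase(trace, filter_len_s) else trace
  tibble::tibble(
    t = tr$t,
    pitch_deg = pitch_from_accel(tr$ax, tr$ay, tr$az),
    roll_deg = roll_from_accel(tr$ax, tr$ay, tr$az)
  )
}

#' Tilt estimate from the most stable window of a static capture
#'
#' Patients sway and make small unrelated movements during a capture, so a
#' single tilt value is extracted from the most stable segment: the trace is
#' smoothed with a zero-phase moving average, the per-sample pitch series is
#' computed, and candidate windows of length `window_s` starting every
#' `hop_s` are scored by the standard deviation of pitch. The window with the
#' lowest SD wins (ties: earliest window). The reported pitch and roll are
#' means over that window.
#'
#' @inheritParams smooth_zero_phase
#' @param window_s Window length in seconds (default 0.3, i.e. 300 ms).
#' @param hop_s Hop between candidate window starts in seconds (default 0.1).
#' @return One-row tibble: `pitch_deg`, `roll_deg`, `window_start_s`,
#'   `window_end_s`, `window_sd_deg`, `n_windows`.
#' @examples
#' tr <- simulate_trace(true_pitch_deg = 10, duration_s = 2,
#'                      sway_amplitude_deg = 1, seed = 1)
#' select_stable_window(tr)
#' @export
select_stable_window <- function(trace, window_s = 0.3, hop_s = 0.1,
                                 filter_len_s = 0.05) {
  fs <- trace_sample_rate(trace)
  dur <- trace_duration(trace)
  if (dur < window_s) {
    stop(sprintf(
      "trace duration %.3f s is shorter than the required window of %.3f s",
      dur, window_s), call. = FALSE)
  }
  win_n <- max(1L, as.integer(round(window_s * fs)))
  hop_n <- max(1L, as.integer(round(hop_s * fs)))
  L <- nrow(trace)
  win_n <- min(win_n, L)

  tilt <- tilt_series(trace, filter_len_s = filter_len_s,
                      smooth = nrow(trace) > max(1L, round(filter_len_s * fs)))
  starts <- seq.int(1L, L - win_n + 1L, by = hop_n)
  sds <- vapply(starts, function(i) {
    stats::sd(tilt$pitch_deg[i:(i + win_n - 1L)])
  }, numeric(1))
  if (win_n == 1L) sds[] <- 0 # sd of one sample is NA; treat as perfectly stable
  best <- which.min(sds) # which.min takes the earliest minimum
  i0 <- starts[best]
  idx <- i0:(i0 + win_n - 1L)
  tibble::tibble(
    pitch_deg = mean(tilt$pitch_deg[idx]),
    roll_deg = mean(tilt$roll_deg[idx]),
    window_start_s = trace$t[i0],
    window_end_s = trace$t[i0 + win_n - 1L],
    window_sd_deg = sds[best],
    n_windows = length(starts)
  )
}
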