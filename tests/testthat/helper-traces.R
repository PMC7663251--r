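# Shared fixtures: all built in code, no stored data.

# A perfectly static trace: gravity rotated by pitch about Y, roll about X.
static_trace <- function(pitch_deg, duration_s = 1, fs = 200, roll_deg = 0) {
  n <- round(duration_s * fs)
  th <- pitch_deg * pi / 180
  ph <- roll_deg * pi / 180
  accel_trace(
    t = (seq_len(n) - 1) / fs,
    ax = rep(-sin(th), n),
    ay = rep(sin(ph) * cos(th), n),
    az = rep(cos(ph) * cos(th), n),
    sample_rate_hz = fs
  )
}

# Independent brute-force oracle for the stable-window search: enumerate
# every candidate window at the hop, score the SD of the smoothed pitch
# series directly, return the winning window's mean pitch and start index.
brute_force_window <- function(trace, window_s = 0.3, hop_s = 0.1,
                               filter_len_s = 0.05) {
  fs <- attr(trace, "sample_rate_hz")
  sm <- smooth_zero_phase(trace, filter_len_s)
  pitch <- pitch_from_accel(sm$ax, sm$ay, sm$az)
  win_n <- round(window_s * fs)
  hop_n <- round(hop_s * fs)
  starts <- seq(1, length(pitch) - win_n + 1, by = hop_n)
  best_sd <- Inf
  best <- NA
  for (s in starts) {
    v <- sd(pitch[s:(s + win_n - 1)])
    if (v < best_sd) { # strict: earliest minimum wins
      best_sd <- v
      best <- s
    }
  }
  list(start = best, sd = best_sd,
       pitch = mean(pitch[best:(best + win_n - 1)]))
}

# A session built from in-memory traces (durations short for speed; the
# sub-5 s hold warning is expected and suppressed).
make_session <- function(positions, pitches, refs = NULL, duration_s = 1,
                         patient_id = "T001") {
  captures <- tibble::tibble(
    position = positions,
    trace = lapply(pitches, static_trace, duration_s = duration_s),
    reference_tilt_deg = refs %||% rep(NA_real_, length(positions))
  )
  suppressWarnings(session_record(captures, patient_id = patient_id))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
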