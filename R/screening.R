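#' Positions recognised by the capture protocol
#' @export
POSITIONS <- c("standing", "flexed_seated", "step_up")

#' Construct a capture session
#'
#' A session is one patient's ordered sequence of static captures following
#' the clinic protocol: a standing baseline is recorded before each
#' functional position (flexed-seated, step-up), e.g.
#' standing, flexed_seated, standing, step_up. Each capture holds a raw
#' accelerometer trace and, optionally, the radiographic reference tilt
#' measured at the same time (for device validation).
#'
#' @param captures A data frame with one row per capture in protocol order:
#'   column `position` (one of `"standing"`, `"flexed_seated"`, `"step_up"`),
#'   a list-column `trace` of [accel_trace] objects, and optionally
#'   `reference_tilt_deg` (radiograph anterior-pelvic-plane tilt, degrees).
#' @param patient_id Opaque patient identifier.
#' @param age,sex,bmi Optional covariates (years; `"female"`/`"male"`;
#'   kg m^-2).
#' @param min_capture_s Recommended minimum hold duration; captures shorter
#'   than this trigger a warning (the protocol asks for a 5 s hold), but any
#'   capture at least one analysis window long is accepted.
#' @return A tibble of class `session_record` with columns `capture`,
#'   `position`, `trace`, `reference_tilt_deg`; patient id and covariates are
#'   carried as attributes.
#' @export
session_record <- function(captures, patient_id = "anon", age = NA_real_,
                           sex = NA_character_, bmi = NA_real_,
                           min_capture_s = 5) {
  captures <- tibble::as_tibble(captures)
  if (!all(c("position", "trace") %in% names(captures))) {
    stop("`captures` needs columns `position` and `trace`", call. = FALSE)
  }
  bad_pos <- setdiff(unique(captures$position), POSITIONS)
  if (length(bad_pos) > 0L) {
    stop("unknown position label(s): ", paste(bad_pos, collapse = ", "),
         "; expected one of ", paste(POSITIONS, collapse = ", "),
         call. = FALSE)
  }
  if (!("reference_tilt_deg" %in% names(captures))) {
    captures$reference_tilt_deg <- NA_real_
  }
  durs <- vapply(captures$trace, trace_duration, numeric(1))
  if (any(durs < min_capture_s)) {
    warning(sprintf(
      "%d capture(s) shorter than the recommended %g s hold (min %.2f s)",
      sum(durs < min_capture_s), min_capture_s, min(durs)), call. = FALSE)
  }
  functional <- which(captures$position != "standing")
  for (i in functional) {
    if (!any(captures$position[seq_len(i - 1L)] == "standing")) {
      stop(sprintf(
        "protocol violation: capture %d (%s) has no preceding standing baseline",
        i, captures$position[i]), call. = FALSE)
    }
  }
  out <- tibble::tibble(
    capture = seq_len(nrow(captures)),
    position = captures$position,
    trace = captures$trace,
    reference_tilt_deg = captures$reference_tilt_deg
  )
  attr(out, "patient_id") <- patient_id
  attr(out, "covariates") <- list(age = age, sex = sex, bmi = bmi)
  class(out) <- c("session_record", class(out))
  out
}

find_baseline <- function(session, functional_idx) {
  prior <- which(session$position[seq_len(functional_idx - 1L)] == "standing")
  if (length(prior) == 0L) {
    stop(sprintf(
      "protocol violation: no standing capture precedes capture %d (%s)",
      functional_idx, session$position[functional_idx]), call. = FALSE)
  }
  max(prior) # nearest preceding standing
}

#' Tilt change of a functional position relative to its standing baseline
#'
#' Runs [select_stable_window()] on the functional capture and on the
#' nearest preceding standing capture, and returns the signed pitch
#' difference (functional minus standing). Positive values represent an
#' increase in anterior pelvic tilt; if the sensor is mounted upside-down
#' set `anterior_sign = -1` to restore that convention.
#'
#' @param session A [session_record].
#' @param position `"flexed_seated"` or `"step_up"`.
#' @param occurrence Which occurrence of `position` to analyse (default the
#'   first).
#' @inheritParams select_stable_window
#' @param anterior_sign +1 or -1, multiplies device pitch so that positive
#'   means increased anterior tilt.
#' @return One-row tibble: `position`, `baseline_pitch_deg`,
#'   `functional_pitch_deg`, `delta_pitch_deg`, window diagnostics for both
#'   captures, and `reference_delta_deg` when reference tilts are present.
#' @export
tilt_change <- function(session, position, occurrence = 1L, window_s = 0.3,
                        hop_s = 0.1, filter_len_s = 0.05, anterior_sign = 1) {
  stopifnot(anterior_sign %in% c(-1, 1))
  hits <- which(session$position == position)
  if (length(hits) < occurrence) {
    stop(sprintf("session has no %s capture (occurrence %d requested, %d found)",
                 position, occurrence, length(hits)), call. = FALSE)
  }
  fi <- hits[occurrence]
  bi <- find_baseline(session, fi)

  est_b <- select_stable_window(session$trace[[bi]], window_s, hop_s,
                                filter_len_s)
  est_f <- select_stable_window(session$trace[[fi]], window_s, hop_s,
                                filter_len_s)
  base_pitch <- anterior_sign * est_b$pitch_deg
  func_pitch <- anterior_sign * est_f$pitch_deg

  ref_delta <- NA_real_
  if (!is.na(session$reference_tilt_deg[fi]) &&
      !is.na(session$reference_tilt_deg[bi])) {
    ref_delta <- session$reference_tilt_deg[fi] - session$reference_tilt_deg[bi]
  }

  tibble::tibble(
    position = position,
    baseline_capture = bi,
    functional_capture = fi,
    baseline_pitch_deg = base_pitch,
    functional_pitch_deg = func_pitch,
    delta_pitch_deg = func_pitch - base_pitch,
    baseline_window_start_s = est_b$window_start_s,
    baseline_window_sd_deg = est_b$window_sd_deg,
    functional_window_start_s = est_f$window_start_s,
    functional_window_sd_deg = est_f$window_sd_deg,
    reference_delta_deg = ref_delta
  )
}

#' Classify a tilt change against the high-mobility threshold
#'
#' High pelvic mobility is a change in pelvic tilt of at least
#' `threshold_deg` (default 13 degrees) between standing and a functional
#' position. The default `"absolute"` mode counts rotation in either the
#' anterior or posterior direction (boundary inclusive); `"signed"` mode
#' requires the change to be at least `+threshold_deg` anteriorly.
#'
#' @param delta_pitch_deg Numeric vector of tilt changes in degrees.
#' @param threshold_deg Classification threshold in degrees (default 13).
#' @param mode `"absolute"` (default) or `"signed"`.
#' @return Logical vector: `TRUE` = high mobility.
#' @examples
#' classify_mobility(c(15, 13, -14, 5))
#' classify_mobility(-14, mode = "signed")
#' @export
classify_mobility <- function(delta_pitch_deg, threshold_deg = 13,
                              mode = c("absolute", "signed")) {
  mode <- match.arg(mode)
  if (any(!is.finite(delta_pitch_deg))) {
    stop("`delta_pitch_deg` must be finite", call. = FALSE)
  }
  if (!is.finite(threshold_deg) || threshold_deg < 0) {
    stop("`threshold_deg` must be a non-negative finite number", call. = FALSE)
  }
  if (mode == "absolute") {
    abs(delta_pitch_deg) >= threshold_deg
  } else {
    delta_pitch_deg >= threshold_deg
  }
}

#' Screen a session for high pelvic mobility
#'
#' Computes the tilt change for every functional capture in the session
#' (each against its nearest preceding standing baseline), classifies each
#' against the threshold, and raises an overall flag if any functional
#' position classifies as high mobility. Restrict `positions` to
#' `"flexed_seated"` for the flexed-seated-only classifier.
#'
#' @inheritParams tilt_change
#' @inheritParams classify_mobility
#' @param positions Functional positions to include (default both).
#' @return An object of class `screening_report`: list with `patient_id`,
#'   `results` (tibble, one row per functional capture), `high_mobility`
#'   (overall flag), and `params` (the effective processing configuration).
#' @export
screen_session <- function(session, threshold_deg = 13,
                           mode = c("absolute", "signed"),
                           positions = c("flexed_seated", "step_up"),
                           window_s = 0.3, hop_s = 0.1, filter_len_s = 0.05,
                           anterior_sign = 1) {
  mode <- match.arg(mode)
  fidx <- which(session$position %in% positions)
  if (length(fidx) == 0L) {
    stop("session contains no functional captures among: ",
         paste(positions, collapse = ", "), call. = FALSE)
  }
  occ <- stats::ave(seq_along(fidx), session$position[fidx],
                    FUN = seq_along)
  results <- purrr::map2_dfr(session$position[fidx], occ, function(pos, k) {
    tilt_change(session, pos, occurrence = k, window_s = window_s,
                hop_s = hop_s, filter_len_s = filter_len_s,
                anterior_sign = anterior_sign)
  })
  results$high_mobility <- classify_mobility(results$delta_pitch_deg,
                                             threshold_deg, mode)
  structure(
    list(
      patient_id = attr(session, "patient_id"),
      covariates = attr(session, "covariates"),
      results = results,
      high_mobility = any(results$high_mobility),
      params = list(threshold_deg = threshold_deg, mode = mode,
                    positions = positions, window_s = window_s, hop_s = hop_s,
                    filter_len_s = filter_len_s, anterior_sign = anterior_sign)
    ),
    class = "screening_report"
  )
}

#' @export
print.screening_report <- function(x, ...) {
  cat("Pelvic mobility screening report\n")
  cat("  patient:", x$patient_id, "\n")
  cat(sprintf("  threshold: %.1f deg (%s mode), window %.0f ms / hop %.1f s\n",
              x$params$threshold_deg, x$params$mode,
              x$params$window_s * 1000, x$params$hop_s))
  for (i in seq_len(nrow(x$results))) {
    r <- x$results[i, ]
    cat(sprintf("  %-13s delta = %+7.3f deg  -> %s\n", r$position,
                r$delta_pitch_deg,
                if (r$high_mobility) "HIGH mobility" else "low mobility"))
  }
  cat("  overall:", if (x$high_mobility) "HIGH pelvic mobility" else
    "low pelvic mobility", "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname screen_session
#' @param x A `screening_report`.
#' @param ... Unused.
#' @export
tidy.screening_report <- function(x, ...) {
  dplyr::mutate(x$results, patient_id = x$patient_id, .before = 1L)
}

#' @rdname screen_session
#' @export
glance.screening_report <- function(x, ...) {
  tibble::tibble(
    patient_id = x$patient_id,
    n_positions = nrow(x$results),
    max_abs_delta_deg = max(abs(x$results$delta_pitch_deg)),
    threshold_deg = x$params$threshold_deg,
    high_mobility = x$high_mobility
  )
}
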