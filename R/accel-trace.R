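#' Construct an accelerometer trace
#'
#' An `accel_trace` is a tibble with one row per sample and columns `t`
#' (seconds), `ax`, `ay`, `az` (acceleration in units of g). The axis
#' convention follows a sacrum-mounted sensor: X is the sagittal axis
#' (anterior-posterior tilt rotates about Y), Y the frontal axis, Z points
#' away from the body so a level sensor at rest reads roughly (0, 0, 1) g.
#' The nominal sampling rate is carried as an attribute.
#'
#' @param t Numeric vector of sample times in seconds, monotone
#'   non-decreasing.
#' @param ax,ay,az Numeric vectors of acceleration in g, same length as `t`.
#' @param sample_rate_hz Nominal sampling rate in Hz (default 200).
#' @return A tibble of class `accel_trace` with columns `t, ax, ay, az` and
#'   attribute `sample_rate_hz`.
#' @examples
#' tr <- accel_trace(t = (0:9) / 200, ax = 0, ay = 0, az = 1)
#' trace_sample_rate(tr)
#' @export
accel_trace <- function(t, ax, ay, az, sample_rate_hz = 200) {
  n <- length(t)
  if (n < 1L) {
    stop("an accel_trace needs at least one sample", call. = FALSE)
  }
  ax <- vctrs_recycle(ax, n, "ax")
  ay <- vctrs_recycle(ay, n, "ay")
  az <- vctrs_recycle(az, n, "az")
  vals <- c(t, ax, ay, az)
  if (anyNA(vals) || any(!is.finite(vals))) {
    stop("accel_trace samples must be finite (no NA/NaN/Inf)", call. = FALSE)
  }
  if (is.unsorted(t)) {
    stop("sample times `t` must be monotone non-decreasing", call. = FALSE)
  }
  if (!is.numeric(sample_rate_hz) || length(sample_rate_hz) != 1L ||
      !is.finite(sample_rate_hz) || sample_rate_hz <= 0) {
    stop("`sample_rate_hz` must be a single positive number", call. = FALSE)
  }
  out <- tibble::tibble(t = as.numeric(t), ax = as.numeric(ax),
                        ay = as.numeric(ay), az = as.numeric(az))
  attr(out, "sample_rate_hz") <- as.numeric(sample_rate_hz)
  class(out) <- c("accel_trace", class(out))
  out
}

# minimal scalar-or-full-length recycling; avoids a vctrs dependency
vctrs_recycle <- function(x, n, name) {
  if (length(x) == 1L) return(rep(as.numeric(x), n))
  if (length(x) != n) {
    stop(sprintf("`%s` must have length 1 or %d, not %d", name, n, length(x)),
         call. = FALSE)
  }
  as.numeric(x)
}

#' @rdname accel_trace
#' @param trace An `accel_trace`.
#' @export
trace_sample_rate <- function(trace) {
  sr <- attr(trace, "sample_rate_hz")
  if (is.null(sr)) {
    if (nrow(trace) >= 2L) {
      dt <- stats::median(diff(trace$t))
      if (dt > 0) return(1 / dt)
    }
    stop("trace has no `sample_rate_hz` attribute and rate cannot be inferred",
         call. = FALSE)
  }
  sr
}

#' @rdname accel_trace
#' @export
trace_duration <- function(trace) {
  nrow(trace) / trace_sample_rate(trace)
}

as_accel_trace <- function(df, sample_rate_hz = NULL) {
  need <- c("t", "ax", "ay", "az")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("missing trace columns: ", paste(miss, collapse = ", "),
         "; expected schema `t,ax,ay,az`", call. = FALSE)
  }
  if (is.null(sample_rate_hz)) {
    dt <- stats::median(diff(df$t))
    sample_rate_hz <- if (is.finite(dt) && dt > 0) 1 / dt else 200
  }
  accel_trace(df$t, df$ax, df$ay, df$az, sample_rate_hz = sample_rate_hz)
}

#' Read and write accelerometer trace files
#'
#' Traces are plain delimited text with a required header `t,ax,ay,az`:
#' time in seconds and three acceleration channels. Raw channel units can be
#' rescaled to g on ingest via `unit_scale` (e.g. a sensor logging mV).
#' Non-finite samples are rejected.
#'
#' @param path File path of a trace CSV.
#' @param unit_scale Multiplicative factor applied to `ax, ay, az` to convert
#'   them to g (default 1, i.e. already in g).
#' @param sample_rate_hz Nominal sampling rate; if `NULL` it is inferred from
#'   the median time step.
#' @return `read_accel_trace()` returns an [accel_trace];
#'   `write_accel_trace()` returns `path` invisibly.
#' @export
read_accel_trace <- function(path, unit_scale = 1, sample_rate_hz = NULL) {
  if (!file.exists(path)) {
    stop("trace file not found: ", path, call. = FALSE)
  }
  df <- tryCatch(
    readr::read_csv(path, col_types = readr::cols(.default = readr::col_double()),
                    progress = FALSE),
    error = function(e) {
      stop("failed to parse trace file ", path, ": ", conditionMessage(e),
           call. = FALSE)
    }
  )
  need <- c("t", "ax", "ay", "az")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("trace file ", path, " is missing columns: ",
         paste(miss, collapse = ", "), "; expected header `t,ax,ay,az`",
         call. = FALSE)
  }
  bad <- which(!stats::complete.cases(df[need]) |
                 !apply(is.finite(as.matrix(df[need])), 1L, all))
  if (length(bad) > 0L) {
    stop("trace file ", path, " has non-finite samples at data line(s) ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  as_accel_trace(
    tibble::tibble(t = df$t, ax = df$ax * unit_scale,
                   ay = df$ay * unit_scale, az = df$az * unit_scale),
    sample_rate_hz = sample_rate_hz
  )
}

#' @rdname read_accel_trace
#' @param trace An [accel_trace] to serialise.
#' @export
write_accel_trace <- function(trace, path) {
  readr::write_csv(tibble::as_tibble(trace)[, c("t", "ax", "ay", "az")], path)
  invisible(path)
}
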