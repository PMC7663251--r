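#' Processing configuration
#'
#' Single block of all tunables for the screening pipeline, round-trippable
#' through YAML. Defaults are the protocol values: 300 ms stable window,
#' 0.1 s hop, 0.05 s smoothing filter, 13-degree mobility threshold,
#' 1.96 limits-of-agreement multiplier, 200 Hz nominal rate.
#'
#' @param window_s,hop_s,filter_len_s Stable-window parameters (seconds).
#' @param threshold_deg Mobility threshold (degrees).
#' @param loa_k Limits-of-agreement multiplier.
#' @param sample_rate_hz Nominal sampling rate (Hz).
#' @param mode Classification mode, `"absolute"` or `"signed"`.
#' @param anterior_sign +1 or -1 sensor mounting sign.
#' @return A named list of class `run_config`.
#' @export
run_config <- function(window_s = 0.3, hop_s = 0.1, filter_len_s = 0.05,
                       threshold_deg = 13, loa_k = 1.96,
                       sample_rate_hz = 200,
                       mode = c("absolute", "signed"), anterior_sign = 1) {
  mode <- match.arg(mode)
  stopifnot(window_s > 0, hop_s > 0, filter_len_s >= 0, threshold_deg >= 0,
            loa_k >= 0, sample_rate_hz > 0, anterior_sign %in% c(-1, 1))
  structure(
    list(window_s = window_s, hop_s = hop_s, filter_len_s = filter_len_s,
         threshold_deg = threshold_deg, loa_k = loa_k,
         sample_rate_hz = sample_rate_hz, mode = mode,
         anterior_sign = anterior_sign),
    class = "run_config"
  )
}

#' @rdname run_config
#' @param path YAML file to read or write.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' @rdname run_config
#' @param config A `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read and write capture sessions on disk
#'
#' A session lives in a directory with a `session.yaml` manifest
#' (`patient_id`, optional `age`/`sex`/`bmi`, and an ordered `captures` list
#' of `{position, file, reference_tilt_deg}`) plus one trace CSV per
#' capture, paths relative to the manifest.
#'
#' @param path Path to a `session.yaml` manifest (or a directory containing
#'   one).
#' @param unit_scale Passed to [read_accel_trace()].
#' @return `read_session()` returns a [session_record]; `write_session()`
#'   the manifest path, invisibly.
#' @export
read_session <- function(path, unit_scale = 1) {
  if (dir.exists(path)) path <- file.path(path, "session.yaml")
  if (!file.exists(path)) {
    stop("session manifest not found: ", path, call. = FALSE)
  }
  man <- yaml::read_yaml(path)
  if (is.null(man$captures) || length(man$captures) == 0L) {
    stop("session manifest ", path, " lists no captures", call. = FALSE)
  }
  base_dir <- dirname(path)
  captures <- purrr::map_dfr(man$captures, function(cp) {
    if (is.null(cp$position) || is.null(cp$file)) {
      stop("each capture needs `position` and `file` fields", call. = FALSE)
    }
    tibble::tibble(
      position = cp$position,
      trace = list(read_accel_trace(file.path(base_dir, cp$file),
                                    unit_scale = unit_scale)),
      reference_tilt_deg = cp$reference_tilt_deg %||% NA_real_
    )
  })
  session_record(
    captures,
    patient_id = man$patient_id %||% "anon",
    age = man$age %||% NA_real_,
    sex = man$sex %||% NA_character_,
    bmi = man$bmi %||% NA_real_
  )
}

#' @rdname read_session
#' @param session A [session_record].
#' @param dir Directory to write into (created if needed).
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(nrow(session))
  for (i in seq_len(nrow(session))) {
    files[i] <- sprintf("capture_%02d_%s.csv", i, session$position[i])
    write_accel_trace(session$trace[[i]], file.path(dir, files[i]))
  }
  cov <- attr(session, "covariates")
  man <- list(
    patient_id = attr(session, "patient_id"),
    age = unbox_na(cov$age), sex = unbox_na(cov$sex), bmi = unbox_na(cov$bmi),
    captures = purrr::pmap(
      list(session$position, files, session$reference_tilt_deg),
      function(pos, f, ref) {
        c(list(position = pos, file = f),
          if (!is.na(ref)) list(reference_tilt_deg = round(ref, 3)))
      })
  )
  man <- man[!vapply(man, is.null, logical(1))]
  path <- file.path(dir, "session.yaml")
  yaml::write_yaml(man, path)
  invisible(path)
}

unbox_na <- function(x) if (length(x) == 1L && is.na(x)) NULL else x

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read and write paired device/reference measures
#'
#' Paired measures are a CSV with required columns `patient_id`, `position`,
#' `device_delta_deg`, `reference_delta_deg`; extra columns (covariates,
#' true values from a simulator) pass through.
#'
#' @param path CSV path.
#' @return A tibble of paired measures.
#' @export
read_paired_measures <- function(path) {
  if (!file.exists(path)) {
    stop("paired-measures file not found: ", path, call. = FALSE)
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("patient_id", "position", "device_delta_deg",
            "reference_delta_deg")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L || nrow(df) == 0L) {
    stop("paired-measures file ", path, if (nrow(df) == 0L) " is empty;" else
      paste0(" is missing column(s): ", paste(miss, collapse = ", "), ";"),
      " expected schema `", paste(need, collapse = ","), "`", call. = FALSE)
  }
  df
}

#' @rdname read_paired_measures
#' @param pairs Tibble of paired measures.
#' @export
write_paired_measures <- function(pairs, path) {
  pairs <- dplyr::mutate(pairs, dplyr::across(dplyr::where(is.numeric),
                                              ~ round(.x, 3)))
  readr::write_csv(pairs, path)
  invisible(path)
}

#' Run the screening pipeline on a stored session
#'
#' Reads a session from disk, screens it, and writes `report.json` and
#' `report.txt` into `out_dir`. The JSON report echoes the full effective
#' configuration for auditability; angles are serialised with 3 decimals.
#'
#' @param session_path Path to a session manifest (see [read_session()]).
#' @param out_dir Output directory (created if needed).
#' @param config A [run_config].
#' @param fs_only If `TRUE`, classify on the flexed-seated position only.
#' @return The `screening_report`, invisibly.
#' @export
run_screen <- function(session_path, out_dir, config = run_config(),
                       fs_only = FALSE) {
  session <- read_session(session_path)
  positions <- if (fs_only) "flexed_seated" else c("flexed_seated", "step_up")
  report <- screen_session(
    session, threshold_deg = config$threshold_deg, mode = config$mode,
    positions = positions, window_s = config$window_s, hop_s = config$hop_s,
    filter_len_s = config$filter_len_s, anterior_sign = config$anterior_sign
  )
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  payload <- list(
    patient_id = report$patient_id,
    high_mobility = report$high_mobility,
    results = round_angles(tidy(report)),
    config = unclass(config),
    positions = positions
  )
  jsonlite::write_json(payload, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  txt <- utils::capture.output(print(report))
  writeLines(txt, file.path(out_dir, "report.txt"))
  invisible(report)
}

round_angles <- function(df) {
  dplyr::mutate(df, dplyr::across(dplyr::where(is.numeric), ~ round(.x, 3)))
}

#' Run the validation statistics on paired measures
#'
#' Reads a paired-measures CSV and writes a validation report:
#' `validation.json` (Bland-Altman per position, contingency table and
#' diagnostic metrics on the flexed-seated pairs, correlations per
#' position, pooled absolute-error distribution) plus `differences.csv`
#' with per-pair differences.
#'
#' @param pairs_path Paired-measures CSV (see [read_paired_measures()]).
#' @param out_dir Output directory.
#' @param config A [run_config].
#' @return A list with all computed statistics, invisibly.
#' @export
run_validate <- function(pairs_path, out_dir, config = run_config()) {
  pairs <- read_paired_measures(pairs_path)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  by_pos <- split(pairs, pairs$position)
  ba <- purrr::map(by_pos, bland_altman, k = config$loa_k)
  corr <- purrr::map(by_pos, tilt_correlation, method = "spearman")

  fs <- by_pos[["flexed_seated"]]
  cont <- metrics <- NULL
  if (!is.null(fs)) {
    cont <- build_contingency(fs, threshold_deg = config$threshold_deg,
                              mode = config$mode)
    metrics <- diagnostic_metrics(cont)
  }
  errs <- error_distribution(pairs)

  payload <- list(
    config = unclass(config),
    n_pairs = nrow(pairs),
    bland_altman = purrr::map(ba, ~ as.list(round_angles(glance(.x)))),
    correlation = purrr::map(corr, ~ as.list(round_angles(.x))),
    contingency = if (!is.null(cont)) unclass(cont),
    diagnostic_metrics = if (!is.null(metrics))
      as.list(round_angles(metrics)),
    error_distribution = c(
      as.list(round_angles(glance(errs))),
      list(histogram = as.list(errs$histogram))
    )
  )
  jsonlite::write_json(payload, file.path(out_dir, "validation.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  diffs <- dplyr::mutate(
    pairs,
    difference_deg = .data$device_delta_deg - .data$reference_delta_deg,
    mean_deg = (.data$device_delta_deg + .data$reference_delta_deg) / 2
  )
  readr::write_csv(round_angles(diffs), file.path(out_dir, "differences.csv"))

  invisible(list(bland_altman = ba, correlation = corr, contingency = cont,
                 diagnostic_metrics = metrics, error_distribution = errs))
}

#' Simulate a cohort and write it to disk
#'
#' Runs [simulate_cohort()] and writes one session directory per patient
#' (`<out_dir>/<patient_id>/session.yaml` + trace CSVs),
#' `ground_truth.csv`, and `paired_measures.csv`. Re-running with the same
#' seed reproduces identical CSV content.
#'
#' @param config A [sim_config], or a path to a YAML file of [sim_config()]
#'   fields.
#' @param out_dir Output directory.
#' @param seed Optional override of the config seed.
#' @return The `sim_cohort`, invisibly.
#' @export
run_simulate <- function(config = sim_config(), out_dir, seed = NULL) {
  if (is.character(config)) {
    config <- do.call(sim_config, yaml::read_yaml(config))
  }
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  if (!is.null(seed)) {
    config$seed <- as.integer(seed)
  }
  cohort <- simulate_cohort(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (sess in cohort$sessions) {
    write_session(sess, file.path(out_dir, attr(sess, "patient_id")))
  }
  readr::write_csv(round_angles(cohort$ground_truth),
                   file.path(out_dir, "ground_truth.csv"))
  write_paired_measures(cohort$paired,
                        file.path(out_dir, "paired_measures.csv"))
  yaml::write_yaml(unclass(config)[!vapply(unclass(config), is.null,
                                           logical(1))],
                   file.path(out_dir, "sim_config.yaml"))
  invisible(cohort)
}
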