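#' Apply the movement threshold to tracked distances
#'
#' Automated tracking counts only movements larger than the threshold
#' (2 mm by convention) within each stimulus window. The stored distance is
#' therefore the tracked distance when it exceeds the threshold and 0
#' otherwise, which makes the continuous measure (distance, mm) and the
#' discrete measure (response indicator) mutually consistent and produces
#' the truncated-at-zero response-magnitude distributions seen in real data.
#' The rule is idempotent.
#'
#' @param distance Numeric vector of distances in mm.
#' @param threshold Movement threshold in mm (default 2).
#' @return Numeric vector: `distance` where `distance > threshold`, else 0.
#' @examples
#' apply_movement_threshold(c(0, 1.5, 2, 2.1, 10))
#' @export
apply_movement_threshold <- function(distance, threshold = 2) {
  stopifnot(is.numeric(distance), is_number(threshold), threshold >= 0)
  ifelse(distance > threshold, distance, 0)
}

#' Build a validated habituation dataset
#'
#' Bundles a long table of per-fish, per-stimulus distances with its stimulus
#' schedule and movement threshold. Validation enforces the contract the
#' downstream analysis assumes: every (group, condition, phase, fish) trace
#' has exactly one finite, non-negative distance per stimulus. Distances are
#' thresholded on ingestion (see [apply_movement_threshold()]) and a logical
#' `responded` column is derived as `distance_mm > threshold`.
#'
#' @param traces Data frame with columns `fish_id`, `group`, `condition`,
#'   `stimulus_index` (1-based), `distance_mm`, and optionally `phase`
#'   (absent means a single-phase study, stored as `"main"`).
#' @param schedule A [stimulus_schedule()].
#' @param threshold Movement threshold in mm (default 2).
#' @param provenance Free-text or list describing where the data came from
#'   (source file, generator seed and ground truth, ...).
#' @return A tibble of class `habituation_data`, ordered by
#'   (group, condition, phase, fish_id, stimulus_index), with attributes
#'   `schedule`, `threshold` and `provenance`.
#' @export
habituation_data <- function(traces, schedule = stimulus_schedule(),
                             threshold = 2, provenance = "unspecified") {
  stopifnot(inherits(schedule, "stimulus_schedule"))
  if (!is.data.frame(traces)) abort("`traces` must be a data frame.")
  traces <- tibble::as_tibble(traces)

  required <- c("fish_id", "group", "condition", "stimulus_index", "distance_mm")
  missing_cols <- setdiff(required, names(traces))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "missing required column(s): ", paste(missing_cols, collapse = ", ")
    ))
  }
  if (!"phase" %in% names(traces)) traces$phase <- "main"

  traces <- traces |>
    dplyr::mutate(
      fish_id = as.character(.data$fish_id),
      group = as.character(.data$group),
      condition = as.character(.data$condition),
      phase = as.character(.data$phase)
    )

  if (!is.numeric(traces$distance_mm)) {
    abort("`distance_mm` must be numeric.")
  }
  if (anyNA(traces$distance_mm) || any(!is.finite(traces$distance_mm))) {
    abort("`distance_mm` contains missing or non-finite values.")
  }
  if (any(traces$distance_mm < 0)) {
    abort("`distance_mm` contains negative values.")
  }
  si <- traces$stimulus_index
  if (!is.numeric(si) || anyNA(si) || any(si != round(si))) {
    abort("`stimulus_index` must be whole numbers.")
  }
  n_stim <- schedule$n_stimuli
  if (any(si < 1 | si > n_stim)) {
    abort(sprintf(
      "`stimulus_index` out of range: schedule has %d stimuli.", n_stim
    ))
  }

  key <- paste(traces$group, traces$condition, traces$phase, traces$fish_id,
               traces$stimulus_index, sep = "\r")
  if (anyDuplicated(key)) {
    abort("duplicate (group, condition, phase, fish_id, stimulus_index) rows.")
  }
  counts <- traces |>
    dplyr::count(.data$group, .data$condition, .data$phase, .data$fish_id)
  if (any(counts$n != n_stim)) {
    bad <- counts[counts$n != n_stim, ]
    abort(sprintf(
      "ragged traces: %d trace(s) do not have exactly %d stimulus rows (e.g. fish '%s' has %d).",
      nrow(bad), n_stim, bad$fish_id[1], bad$n[1]
    ))
  }

  traces <- traces |>
    dplyr::mutate(
      stimulus_index = as.integer(.data$stimulus_index),
      distance_mm = apply_movement_threshold(.data$distance_mm, threshold),
      responded = .data$distance_mm > threshold
    ) |>
    dplyr::select(
      "fish_id", "group", "condition", "phase", "stimulus_index",
      "distance_mm", "responded"
    ) |>
    dplyr::arrange(
      .data$group, .data$condition, .data$phase, .data$fish_id,
      .data$stimulus_index
    )

  structure(
    traces,
    schedule = schedule,
    threshold = threshold,
    provenance = provenance,
    class = c("habituation_data", class(tibble::tibble()))
  )
}

#' @export
print.habituation_data <- function(x, ...) {
  sched <- attr(x, "schedule")
  n_traces <- nrow(unique(as.data.frame(
    x[, c("group", "condition", "phase", "fish_id")]
  )))
  cat(sprintf(
    "<habituation_data> %d traces x %d stimuli (threshold %g mm)\n",
    n_traces, sched$n_stimuli, attr(x, "threshold")
  ))
  NextMethod()
}

#' Read a long-format response table
#'
#' Ingests the documented reduction of automated-tracking exports: one CSV
#' row per fish per stimulus window, comma-separated, UTF-8, header row,
#' 1-based `stimulus_index`, decimal point. Rows during ISIs do not exist in
#' this schema. The table is validated and thresholded via
#' [habituation_data()].
#'
#' @param file Path or connection to a CSV with columns `fish_id`, `group`,
#'   `condition`, optionally `phase`, `stimulus_index`, `distance_mm`.
#' @param schedule A [stimulus_schedule()] the traces must conform to.
#' @param threshold Movement threshold in mm (default 2).
#' @return A `habituation_data` tibble.
#' @seealso [write_response_table()]
#' @export
read_response_table <- function(file, schedule = stimulus_schedule(),
                                threshold = 2) {
  raw <- readr::read_csv(
    file, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(distance_mm = readr::col_character())
  )
  if (is.character(raw$distance_mm)) {
    # strtod-based conversion keeps the text round trip bit-exact
    num <- suppressWarnings(as.numeric(raw$distance_mm))
    if (anyNA(num) && !anyNA(raw$distance_mm)) {
      abort("`distance_mm` must be numeric.")
    }
    raw$distance_mm <- num
  }
  src <- if (is.character(file)) file else "connection"
  habituation_data(
    raw, schedule = schedule, threshold = threshold,
    provenance = list(source = src)
  )
}

#' Write a habituation dataset as a long-format CSV
#'
#' Writes the documented CSV dialect read by [read_response_table()].
#' Distances are written in full (shortest round-trippable) precision, so a
#' valid dataset round-trips bit-identically through write-then-read.
#'
#' @param data A `habituation_data` tibble.
#' @param file Destination path.
#' @return `file`, invisibly.
#' @export
write_response_table <- function(data, file) {
  stopifnot(inherits(data, "habituation_data"))
  out <- data |>
    dplyr::select(
      "fish_id", "group", "condition", "phase", "stimulus_index",
      "distance_mm"
    ) |>
    # 17 significant digits: doubles survive the text round trip bit-exactly
    dplyr::mutate(distance_mm = sprintf("%.17g", .data$distance_mm))
  readr::write_csv(out, file, progress = FALSE)
  invisible(file)
}

#' Write the result tables of an analysis
#'
#' Emits the deterministic CSV tables a study run produces: a per-group
#' descriptive table (mean and SE of the cumulative distance travelled,
#' rendered at 2 decimals in the conventional `M`, `SE` layout), the
#' bootstrap parameter replicates and their summaries, and the statistical
#' test results. Row order follows input order; no timestamps are written,
#' so identical inputs yield byte-identical files.
#'
#' @param summaries Tibble of group summaries as produced by
#'   [summarize_group()]'s `overall` component (or `tidy()` on it), with
#'   columns `group`, `condition`, `phase`, `n_fish`, `mean_cdt`, `se_cdt`,
#'   `response_probability`.
#' @param fits Either `NULL`, a tibble of bootstrap replicates/summaries, or
#'   a named list of [bootstrap_habituation()] results.
#' @param tests Tibble of test results (possibly 0 rows, which yields a
#'   header-only file).
#' @param dir Output directory, created if needed.
#' @return Named character vector of the files written, invisibly.
#' @export
write_results_tables <- function(summaries, fits, tests, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- c()

  if (!is.null(summaries)) {
    tab <- summaries |>
      dplyr::mutate(
        M = formatC(.data$mean_cdt, format = "f", digits = 2),
        SE = formatC(.data$se_cdt, format = "f", digits = 2)
      ) |>
      dplyr::select(
        "group", "condition", "phase", "n_fish", "M", "SE",
        "response_probability"
      )
    f <- file.path(dir, "group_summary.csv")
    readr::write_csv(tab, f, progress = FALSE)
    files["group_summary"] <- f
  }

  if (!is.null(fits)) {
    if (is.list(fits) && !is.data.frame(fits)) {
      reps <- purrr::imap(fits, function(b, nm) {
        dplyr::mutate(b$replicates, condition = nm, .before = 1)
      }) |> purrr::list_rbind()
      summ <- purrr::imap(fits, function(b, nm) {
        dplyr::mutate(tidy(b), condition = nm, .before = 1)
      }) |> purrr::list_rbind()
    } else {
      reps <- fits
      summ <- NULL
    }
    f <- file.path(dir, "bootstrap_params.csv")
    readr::write_csv(reps, f, progress = FALSE)
    files["bootstrap_params"] <- f
    if (!is.null(summ)) {
      f2 <- file.path(dir, "bootstrap_summary.csv")
      readr::write_csv(summ, f2, progress = FALSE)
      files["bootstrap_summary"] <- f2
    }
  }

  if (!is.null(tests)) {
    if (ncol(tests) == 0) {
      # empty test list: emit the standard header with no rows
      tests <- test_result("", statistic = 0, p_value = 0, n = 0)[0, ]
    }
    f <- file.path(dir, "tests.csv")
    readr::write_csv(tests, f, progress = FALSE)
    files["tests"] <- f
  }

  invisible(files)
}
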