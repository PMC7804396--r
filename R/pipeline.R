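#' Build a run configuration
#'
#' A run is driven either by a study preset (synthetic data with recorded
#' ground truth) or by an input CSV of tracked distances — exactly one of
#' the two.
#'
#' @param preset Study preset name (see [study_presets()]), or `NULL`.
#' @param input Path to a long-format response CSV, or `NULL`.
#' @param schedule [stimulus_schedule()] used when reading `input`.
#' @param seed Master seed for generation and bootstrapping.
#' @param n_boot Bootstrap replicates (>= 2; default 250).
#' @param threshold Movement threshold, mm (default 2).
#' @param fit_method `"anchored"` or `"nls"`.
#' @param output_dir Directory for result tables, or `NULL` to skip writing.
#' @return A `run_config` list.
#' @export
run_config <- function(preset = NULL, input = NULL,
                       schedule = stimulus_schedule(), seed = 1L,
                       n_boot = 250, threshold = 2,
                       fit_method = c("anchored", "nls"),
                       output_dir = NULL) {
  fit_method <- match.arg(fit_method)
  if (is.null(preset) == is.null(input)) {
    abort("exactly one of `preset` or `input` must be given.")
  }
  if (!is_count(n_boot) || n_boot < 2) abort("`n_boot` must be >= 2.")
  if (!is_count(seed)) abort("`seed` must be an integer.")
  if (!is_number(threshold) || threshold < 0) abort("`threshold` must be >= 0.")
  structure(
    list(preset = preset, input = input, schedule = schedule,
         seed = as.integer(seed), n_boot = as.integer(n_boot),
         threshold = threshold, fit_method = fit_method,
         output_dir = output_dir),
    class = "run_config"
  )
}

#' Read a run configuration from a YAML or JSON file
#'
#' Recognised keys: `preset`, `input`, `seed`, `n_boot`, `threshold`,
#' `fit_method`, `output_dir`, and an optional `schedule` block whose
#' entries are passed to [stimulus_schedule()].
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  sched <- if (!is.null(raw$schedule)) {
    do.call(stimulus_schedule, raw$schedule)
  } else {
    stimulus_schedule()
  }
  run_config(
    preset = raw$preset, input = raw$input, schedule = sched,
    seed = raw$seed %||% 1L, n_boot = raw$n_boot %||% 250,
    threshold = raw$threshold %||% 2,
    fit_method = raw$fit_method %||% "anchored",
    output_dir = raw$output_dir
  )
}

#' Run a study end-to-end
#'
#' Orchestrates the full analysis: generate (or ingest) the datasets,
#' summarise each cohort, bootstrap the habituation parameters per
#' condition, and run the design's rank tests — Friedman plus Dunn
#' (Bonferroni-adjusted) pairwise comparisons on the per-fish CDT blocks
#' for multi-condition designs, or a Wilcoxon signed-rank test per group
#' (baseline versus re-test CDT) for paired designs. Per-fish CDT feeds the
#' rank tests because Friedman requires subject-level blocks; the rotated
#' within-subject designs yield complete blocks. Under a fixed seed the run
#' is fully deterministic, and changing `n_boot` alone leaves the summaries
#' untouched (they use no randomness).
#'
#' @param config A [run_config()], or `NULL` to build one from `...`.
#' @param ... Arguments forwarded to [run_config()] when `config` is `NULL`.
#' @param quiet Suppress stage log messages (default `FALSE`).
#' @return An object of class `study_run`: `datasets` (named list of
#'   `habituation_data`), `summaries` (list of `overall` and `per_stimulus`
#'   tibbles), `fits` (named list of [bootstrap_habituation()] results),
#'   `tests` (tibble), `provenance` (list).
#' @examples
#' \donttest{
#' run <- run_study(preset = "study2a", seed = 1, n_boot = 25)
#' run$tests
#' }
#' @export
run_study <- function(config = NULL, ..., quiet = FALSE) {
  if (is.null(config)) config <- run_config(...)
  stopifnot(inherits(config, "run_config"))
  log_stage <- function(stage, ...) {
    if (!quiet) message(sprintf("[%s] %s", stage, sprintf(...)))
  }

  # --- data ---------------------------------------------------------------
  if (!is.null(config$preset)) {
    log_stage("data", "simulating preset '%s' (seed %d)",
              config$preset, config$seed)
    datasets <- simulate_study(config$preset, seed = config$seed,
                               threshold = config$threshold)
    truth <- purrr::map(datasets, ~ attr(.x, "provenance")$ground_truth)
    log_stage("data", "generator ground truth recorded for %d cells",
              length(truth))
  } else {
    log_stage("data", "reading '%s'", config$input)
    ds <- read_response_table(config$input, schedule = config$schedule,
                              threshold = config$threshold)
    datasets <- split_dataset(ds)
    truth <- NULL
  }

  paired <- any(purrr::map_lgl(
    datasets, ~ length(unique(.x$phase)) > 1
  ))

  # --- summaries ----------------------------------------------------------
  log_stage("metrics", "summarising %d dataset(s)", length(datasets))
  summaries <- purrr::map(datasets, summarize_group)
  overall <- purrr::map(summaries, "overall") |> purrr::list_rbind()
  per_stimulus <- purrr::map(summaries, "per_stimulus") |> purrr::list_rbind()

  # --- fits ---------------------------------------------------------------
  log_stage("fit", "bootstrapping %d replicates per cohort (method=%s)",
            config$n_boot, config$fit_method)
  fits <- purrr::imap(datasets, function(d, nm) {
    phases <- unique(d$phase)
    per_phase <- purrr::map(phases, function(ph) {
      bootstrap_habituation(
        d[d$phase == ph, ], n_boot = config$n_boot,
        method = config$fit_method,
        seed = derive_seed(config$seed, paste("boot", nm, ph))
      )
    })
    names(per_phase) <- phases
    per_phase
  }) |> purrr::list_flatten(name_spec = "{outer}.{inner}")
  names(fits) <- sub("\\.main$", "", names(fits))

  # --- tests --------------------------------------------------------------
  if (paired) {
    log_stage("tests", "paired design: Wilcoxon signed-rank per group")
    tests <- purrr::imap(datasets, function(d, nm) {
      dd <- delta_cdt(d)
      res <- wilcoxon_signed_rank(dd$baseline_cdt, dd$retest_cdt,
                                  labels = c("baseline", "retest"))
      dplyr::mutate(res, group = nm, .before = 1)
    }) |> purrr::list_rbind()
  } else if (length(datasets) < 2) {
    log_stage("tests", "single cohort: no between-condition tests to run")
    tests <- test_result("", statistic = 0, p_value = 0, n = 0)[0, ]
  } else {
    log_stage("tests", "blocked design: Friedman + Dunn-Bonferroni on CDT")
    cdt_all <- purrr::map(datasets, fish_cdt) |> purrr::list_rbind()
    blocks <- cdt_all |>
      dplyr::select("fish_id", "condition", "cdt") |>
      tidyr::pivot_wider(names_from = "condition", values_from = "cdt")
    m <- as.matrix(blocks[, -1])
    rownames(m) <- blocks$fish_id
    tests <- dplyr::bind_rows(
      dplyr::mutate(friedman_rank_test(m), group = "all", .before = 1),
      dplyr::mutate(dunn_posthoc(m), group = "all", .before = 1)
    )
  }

  provenance <- list(
    preset = config$preset, input = config$input, seed = config$seed,
    n_boot = config$n_boot, threshold = config$threshold,
    fit_method = config$fit_method,
    ground_truth = truth,
    package_version = as.character(utils::packageVersion("startlehab"))
  )

  if (!is.null(config$output_dir)) {
    log_stage("write", "writing result tables to '%s'", config$output_dir)
    write_results_tables(overall, fits, tests, config$output_dir)
    jsonlite::write_json(
      provenance[c("preset", "input", "seed", "n_boot", "threshold",
                   "fit_method", "package_version")],
      file.path(config$output_dir, "provenance.json"),
      auto_unbox = TRUE, null = "null"
    )
  }

  structure(
    list(
      datasets = datasets,
      summaries = list(overall = overall, per_stimulus = per_stimulus),
      fits = fits,
      tests = tests,
      provenance = provenance
    ),
    class = "study_run"
  )
}

# split a multi-condition dataset into one habituation_data per condition
split_dataset <- function(ds) {
  sched <- attr(ds, "schedule")
  thr <- attr(ds, "threshold")
  prov <- attr(ds, "provenance")
  conds <- unique(ds$condition)
  out <- purrr::map(conds, function(cc) {
    habituation_data(ds[ds$condition == cc, ], schedule = sched,
                     threshold = thr, provenance = prov)
  })
  names(out) <- conds
  out
}

#' @export
print.study_run <- function(x, ...) {
  cat(sprintf(
    "<study_run> %s | %d dataset(s), %d test row(s)\n",
    x$provenance$preset %||% x$provenance$input,
    length(x$datasets), nrow(x$tests)
  ))
  print(x$summaries$overall)
  invisible(x)
}
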