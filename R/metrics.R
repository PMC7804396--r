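#' Per-fish cumulative distance travelled
#'
#' The cumulative distance travelled (CDT) is the sum of the distance
#' travelled (mm) across all stimulus windows of one trace. It is the
#' primary per-fish behavioural measure; a group's value is its mean.
#'
#' @param data A `habituation_data` tibble, or any long table with
#'   `fish_id`, `group`, `condition`, `phase`, `distance_mm` columns.
#' @return A tibble with one row per (group, condition, phase, fish) and a
#'   `cdt` column in mm.
#' @examples
#' ds <- simulate_study("study2a", seed = 1)
#' fish_cdt(ds$`200Hz`)
#' @export
fish_cdt <- function(data) {
  stopifnot(is.data.frame(data))
  data |>
    tibble::as_tibble() |>
    dplyr::summarise(
      cdt = sum(.data$distance_mm),
      .by = c("group", "condition", "phase", "fish_id")
    )
}

#' Summarise one or more cohorts of traces
#'
#' For each (group, condition, phase) cohort, computes the per-stimulus mean
#' and standard error of the distance travelled, the cumulative mean curve,
#' the mean and SE of the per-fish CDT, the response probability (percentage
#' of fish that responded to the first stimulus), and the mean response
#' indicator per stimulus (the discrete measure). SE is the sample SD
#' (n - 1 denominator) divided by sqrt(n); a cohort of one fish gets SE 0
#' with a warning.
#'
#' @param data A `habituation_data` tibble (or compatible long table with a
#'   logical `responded` column).
#' @return An object of class `group_summary`: a list with
#'   `per_stimulus` (tibble: cohort keys, `stimulus_index`, `mean_mm`,
#'   `se_mm`, `cum_mean_mm`, `response_rate`) and `overall` (tibble: cohort
#'   keys, `n_fish`, `mean_cdt`, `se_cdt`, `response_probability` in
#'   percent). `tidy()` returns `overall`.
#' @export
summarize_group <- function(data) {
  stopifnot(is.data.frame(data))
  data <- tibble::as_tibble(data)
  if (nrow(data) == 0) abort("empty group: no traces to summarise.")
  if (!"responded" %in% names(data)) {
    abort("`data` must carry a `responded` column (see `habituation_data()`).")
  }
  keys <- c("group", "condition", "phase")

  per_stim <- data |>
    dplyr::summarise(
      n_fish = dplyr::n(),
      mean_mm = mean(.data$distance_mm),
      se_mm = se_of(.data$distance_mm),
      response_rate = mean(.data$responded),
      .by = dplyr::all_of(c(keys, "stimulus_index"))
    ) |>
    dplyr::arrange(dplyr::pick(dplyr::all_of(c(keys, "stimulus_index")))) |>
    dplyr::mutate(
      cum_mean_mm = cumsum(.data$mean_mm),
      .by = dplyr::all_of(keys)
    )

  if (any(per_stim$n_fish == 1)) {
    warn("cohort(s) of a single fish: standard errors reported as 0.")
  }

  cdt <- fish_cdt(data)
  first <- data |>
    dplyr::filter(.data$stimulus_index == min(.data$stimulus_index)) |>
    dplyr::summarise(
      response_probability = 100 * mean(.data$responded),
      .by = dplyr::all_of(keys)
    )
  overall <- cdt |>
    dplyr::summarise(
      n_fish = dplyr::n(),
      mean_cdt = mean(.data$cdt),
      se_cdt = se_of(.data$cdt),
      .by = dplyr::all_of(keys)
    ) |>
    dplyr::left_join(first, by = keys) |>
    dplyr::arrange(dplyr::pick(dplyr::all_of(keys)))

  structure(
    list(per_stimulus = per_stim |> dplyr::select(-"n_fish"),
         overall = overall),
    class = "group_summary"
  )
}

# SD/sqrt(n); n = 1 yields 0 by convention.
se_of <- function(x) {
  n <- length(x)
  if (n < 2) return(0)
  sd(x) / sqrt(n)
}

#' @export
print.group_summary <- function(x, ...) {
  cat("<group_summary>\n")
  print(x$overall)
  invisible(x)
}

#' @rdname summarize_group
#' @param x A `group_summary`.
#' @param ... Unused.
#' @method tidy group_summary
#' @export
tidy.group_summary <- function(x, ...) x$overall

#' Response probability of a cohort
#'
#' Percentage of fish whose distance in the chosen stimulus window exceeded
#' the movement threshold. The conventional definition uses the first
#' stimulus only; `scope = "any"` is an exposed variant counting fish that
#' responded to at least one stimulus.
#'
#' @param data A `habituation_data` tibble.
#' @param scope `"first"` (default) or `"any"`.
#' @return Tibble with cohort keys and `response_probability` (percent).
#' @export
response_probability <- function(data, scope = c("first", "any")) {
  scope <- match.arg(scope)
  stopifnot(is.data.frame(data))
  keys <- c("group", "condition", "phase")
  if (scope == "first") {
    data |>
      tibble::as_tibble() |>
      dplyr::filter(.data$stimulus_index == min(.data$stimulus_index)) |>
      dplyr::summarise(
        response_probability = 100 * mean(.data$responded),
        .by = dplyr::all_of(keys)
      )
  } else {
    data |>
      tibble::as_tibble() |>
      dplyr::summarise(
        any_response = any(.data$responded),
        .by = dplyr::all_of(c(keys, "fish_id"))
      ) |>
      dplyr::summarise(
        response_probability = 100 * mean(.data$any_response),
        .by = dplyr::all_of(keys)
      )
  }
}

#' Per-fish change in CDT between two phases
#'
#' Pairs each fish's baseline and re-test CDT by identifier and returns the
#' per-fish difference (baseline minus re-test); positive deltas indicate
#' suppressed re-test responding, i.e. retained habituation memory.
#'
#' @param data A `habituation_data` tibble containing both phases.
#' @param baseline,retest Phase labels (defaults `"baseline"`, `"retest"`).
#' @return Tibble with `group`, `condition`, `fish_id`, `baseline_cdt`,
#'   `retest_cdt`, `delta` (mm).
#' @export
delta_cdt <- function(data, baseline = "baseline", retest = "retest") {
  cdt <- fish_cdt(data)
  phases <- unique(cdt$phase)
  if (!all(c(baseline, retest) %in% phases)) {
    abort(sprintf(
      "phases '%s' and '%s' must both be present (found: %s).",
      baseline, retest, paste(phases, collapse = ", ")
    ))
  }
  wide <- cdt |>
    dplyr::filter(.data$phase %in% c(baseline, retest)) |>
    tidyr::pivot_wider(names_from = "phase", values_from = "cdt")
  if (anyNA(wide[[baseline]]) || anyNA(wide[[retest]])) {
    abort("unmatched fish: every fish must appear in both phases.")
  }
  wide |>
    dplyr::transmute(
      .data$group, .data$condition, .data$fish_id,
      baseline_cdt = .data[[baseline]],
      retest_cdt = .data[[retest]],
      delta = .data[[baseline]] - .data[[retest]]
    )
}
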