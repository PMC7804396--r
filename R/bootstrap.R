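#' Fish-level bootstrap of the habituation parameters
#'
#' Each replicate resamples fish with replacement to the original group
#' size, recomputes the per-stimulus mean response curve, and refits the
#' habituation model; resampling whole fish preserves within-fish dependence
#' across stimuli. The parameter standard errors are the standard deviations
#' of the replicate estimates (250 replicates by default); percentile
#' confidence intervals are available from the stored replicates.
#'
#' @param data A `habituation_data` tibble, or a long table with `fish_id`,
#'   `stimulus_index`, `distance_mm` for a single cohort (one group,
#'   condition and phase).
#' @param n_boot Number of bootstrap replicates (default 250).
#' @param method Fit method passed to [fit_habituation()].
#' @param seed Integer seed; results are deterministic given the seed.
#' @param tail_k,dc_bounds Passed to [fit_habituation()].
#' @return An object of class `habituation_boot`: `replicates` (tibble with
#'   one row per replicate: `replicate`, `amplitude`, `offset`,
#'   `decay_constant`, `rss`, `flags`), `summary` (per-parameter mean and
#'   bootstrap SE), `fit` (the point fit to the observed mean curve),
#'   `n_boot`, `n_fish`, `method`, `seed`.
#' @examples
#' ds <- simulate_study("study2a", seed = 1)
#' b <- bootstrap_habituation(ds$`200Hz`, n_boot = 50, seed = 2)
#' tidy(b)
#' @export
bootstrap_habituation <- function(data, n_boot = 250,
                                  method = c("anchored", "nls"),
                                  seed = 1L, tail_k = 5,
                                  dc_bounds = c(0.05, 50)) {
  method <- match.arg(method)
  stopifnot(is.data.frame(data))
  if (!is_count(n_boot) || n_boot < 2) abort("`n_boot` must be >= 2.")
  if (!is_count(seed)) abort("`seed` must be an integer.")
  cohorts <- unique(as.data.frame(
    data[, intersect(c("group", "condition", "phase"), names(data))]
  ))
  if (nrow(cohorts) > 1) {
    abort("`data` spans several cohorts; bootstrap one (group, condition, phase) at a time.")
  }

  mat <- trace_matrix(data)
  n_fish <- nrow(mat)
  if (n_fish < 2) abort("bootstrap needs at least 2 fish.")

  point_fit <- fit_habituation(colMeans(mat), method = method,
                               tail_k = tail_k, dc_bounds = dc_bounds)

  reps <- local_seed(seed, {
    purrr::map(seq_len(n_boot), function(b) {
      take <- sample.int(n_fish, n_fish, replace = TRUE)
      f <- fit_habituation(colMeans(mat[take, , drop = FALSE]),
                           method = method, tail_k = tail_k,
                           dc_bounds = dc_bounds)
      tibble::tibble(
        replicate = b, amplitude = f$amplitude, offset = f$offset,
        decay_constant = f$decay_constant, rss = f$rss,
        flags = paste(f$flags, collapse = ";")
      )
    }) |> purrr::list_rbind()
  })

  summary <- tibble::tibble(
    term = c("amplitude", "offset", "decay_constant"),
    mean = c(mean(reps$amplitude), mean(reps$offset),
             mean(reps$decay_constant, na.rm = TRUE)),
    se = c(boot_sd(reps$amplitude), boot_sd(reps$offset),
           boot_sd(reps$decay_constant)),
    n_na = c(sum(is.na(reps$amplitude)), sum(is.na(reps$offset)),
             sum(is.na(reps$decay_constant)))
  )

  structure(
    list(
      replicates = reps, summary = summary, fit = point_fit,
      n_boot = as.integer(n_boot), n_fish = n_fish, method = method,
      seed = as.integer(seed)
    ),
    class = "habituation_boot"
  )
}

# SD across replicates; identical replicates give exactly 0.
boot_sd <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2 || diff(range(x)) == 0) return(0)
  sd(x)
}

# fish x stimulus matrix, rows ordered by fish_id, columns by stimulus_index
trace_matrix <- function(data) {
  wide <- tibble::as_tibble(data) |>
    dplyr::select("fish_id", "stimulus_index", "distance_mm") |>
    dplyr::arrange(.data$fish_id, .data$stimulus_index) |>
    tidyr::pivot_wider(names_from = "stimulus_index",
                       values_from = "distance_mm")
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$fish_id
  if (anyNA(m)) abort("incomplete traces: every fish needs every stimulus.")
  m
}

#' @export
print.habituation_boot <- function(x, ...) {
  cat(sprintf(
    "<habituation_boot> %d replicates of %d fish (method=%s, seed=%d)\n",
    x$n_boot, x$n_fish, x$method, x$seed
  ))
  print(x$summary)
  invisible(x)
}

#' @rdname bootstrap_habituation
#' @param x A `habituation_boot`.
#' @param ... Unused.
#' @method tidy habituation_boot
#' @export
tidy.habituation_boot <- function(x, ...) {
  tibble::tibble(
    term = x$summary$term,
    estimate = x$summary$mean,
    std.error = x$summary$se
  )
}

#' @rdname bootstrap_habituation
#' @method glance habituation_boot
#' @export
glance.habituation_boot <- function(x, ...) {
  tibble::tibble(
    n_boot = x$n_boot, n_fish = x$n_fish, method = x$method, seed = x$seed,
    rss = x$fit$rss
  )
}

#' Histogram of bootstrap amplitudes on a percent scale
#'
#' Bins the replicate amplitudes as a percentage of a reference amplitude
#' (by default the largest replicate amplitude in this result; pass the
#' maximum across compared conditions to put several conditions on a common
#' axis). Non-positive amplitudes — the truncation spike produced by failed
#' responses — are reported separately as `zero_count`, so
#' `zero_count + sum(count)` equals the number of replicates.
#'
#' @param result A [bootstrap_habituation()] result.
#' @param bins Number of equal-width bins over the positive range
#'   (default 10).
#' @param ref_max Reference amplitude defining 100% (default: the maximum
#'   replicate amplitude in `result`).
#' @return A tibble of class `amplitude_histogram` with `bin_low`,
#'   `bin_high` (percent), `count`; attributes `zero_count`, `ref_max`,
#'   `n_boot`.
#' @export
amplitude_distribution <- function(result, bins = 10, ref_max = NULL) {
  stopifnot(inherits(result, "habituation_boot"),
            is_count(bins), bins >= 1)
  amps <- result$replicates$amplitude
  zero_count <- sum(amps <= 0)
  pos <- amps[amps > 0]
  ref_max <- ref_max %||% if (length(pos)) max(pos) else 1
  stopifnot(is_number(ref_max), ref_max > 0)
  pct <- 100 * pos / ref_max
  top <- max(100, pct)
  breaks <- seq(0, top, length.out = bins + 1)
  # first bin is (0, b1]; positive amplitudes never land on 0
  counts <- tabulate(findInterval(pct, breaks, left.open = TRUE,
                                  rightmost.closed = TRUE),
                     nbins = bins)
  structure(
    tibble::tibble(
      bin_low = breaks[-length(breaks)],
      bin_high = breaks[-1],
      count = counts
    ),
    zero_count = zero_count,
    ref_max = ref_max,
    n_boot = result$n_boot,
    class = c("amplitude_histogram", class(tibble::tibble()))
  )
}
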