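#' First-order exponential habituation response
#'
#' The habituation model describes the mean response magnitude at stimulus n
#' (1-based) as `A * exp(-(n - 1) / Dc) + O`: the first-stimulus response is
#' amplitude plus offset, the long-run steady state is the offset, and one
#' decay constant after the first stimulus the amplitude component has
#' fallen to 1/e (~36.8%) of its initial value.
#'
#' @param amplitude Amplitude A in mm (first-stimulus response above offset).
#' @param offset Offset O in mm (steady-state response after habituation).
#' @param decay_constant Decay constant Dc in stimuli.
#' @param stimulus 1-based stimulus index (vectorised).
#' @return Predicted distance in mm.
#' @examples
#' habituation_response(10, 2, 1, stimulus = 1)   # 12
#' habituation_response(10, 0, 3, stimulus = 4)   # 10 / e
#' @export
habituation_response <- function(amplitude, offset, decay_constant, stimulus) {
  stopifnot(all(stimulus >= 1))
  amplitude * exp(-(stimulus - 1) / decay_constant) + offset
}

#' Fit the habituation model to a mean response curve
#'
#' Extracts the three habituation parameters from a per-stimulus mean
#' response curve.
#'
#' The default `"anchored"` method follows the parameter definitions
#' directly: the offset is the mean of the last `tail_k` points (the
#' steady-state response), the amplitude is the first point minus the
#' offset, and the decay constant is the bounded one-dimensional
#' least-squares minimiser of the residual sum of squares. The decay search
#' scans a log-spaced grid over `dc_bounds` and refines with
#' [stats::optimize()] in the bracketing interval, guarding against local
#' minima on noisy curves. The `"nls"` method is a full three-parameter
#' least-squares fit ([minpack.lm::nlsLM()]) started at the anchored
#' estimate, with the offset kept non-negative and the decay constant kept
#' inside `dc_bounds` (a solution at a bound is flagged
#' `nonidentifiable_Dc` rather than treated as a failure).
#'
#' @param curve Numeric vector (length >= 4) of per-stimulus mean distances.
#' @param method `"anchored"` (default) or `"nls"`.
#' @param tail_k Number of trailing points averaged for the anchored offset
#'   (default 5).
#' @param dc_bounds Search bounds for the decay constant, in stimuli
#'   (default `c(0.05, 50)`).
#' @return An object of class `habituation_fit` with elements `amplitude`,
#'   `offset`, `decay_constant`, `rss`, `method`, `flags` (character vector,
#'   possibly empty: `degenerate_flat`, `negative_A`, `nonidentifiable_Dc`,
#'   `nls_failed`), `fitted`, `curve`.
#' @examples
#' curve <- habituation_response(20, 5, 1.5, 1:20)
#' fit_habituation(curve, method = "nls")
#' @export
fit_habituation <- function(curve, method = c("anchored", "nls"),
                            tail_k = 5, dc_bounds = c(0.05, 50)) {
  method <- match.arg(method)
  if (!is.numeric(curve) || anyNA(curve) || any(!is.finite(curve))) {
    abort("`curve` must be finite numeric.")
  }
  if (length(curve) < 4) abort("`curve` must have at least 4 points.")
  stopifnot(is_count(tail_k) || is_number(tail_k), tail_k >= 1,
            length(dc_bounds) == 2, dc_bounds[1] > 0,
            dc_bounds[2] > dc_bounds[1])
  n <- length(curve)
  idx <- seq_len(n)

  if (diff(range(curve)) == 0) {
    return(new_habituation_fit(
      amplitude = 0, offset = curve[1], decay_constant = NA_real_,
      rss = 0, method = method, flags = "degenerate_flat",
      fitted = rep(curve[1], n), curve = curve,
      tail_k = tail_k, dc_bounds = dc_bounds
    ))
  }

  # anchored estimate (also the nls start)
  offset_a <- mean(tail(curve, tail_k))
  amp_a <- curve[1] - offset_a
  if (amp_a == 0) {
    # first point sits exactly on the tail mean: decay is unconstrained
    fitted <- rep(offset_a, n)
    return(new_habituation_fit(
      amplitude = 0, offset = offset_a, decay_constant = NA_real_,
      rss = sum((curve - fitted)^2), method = method,
      flags = "nonidentifiable_Dc", fitted = fitted, curve = curve,
      tail_k = tail_k, dc_bounds = dc_bounds
    ))
  }
  rss_dc <- function(dc) {
    sum((curve - amp_a * exp(-(idx - 1) / dc) - offset_a)^2)
  }
  grid <- exp(seq(log(dc_bounds[1]), log(dc_bounds[2]), length.out = 60))
  i <- which.min(vapply(grid, rss_dc, numeric(1)))
  lo <- grid[max(i - 1L, 1L)]
  hi <- grid[min(i + 1L, length(grid))]
  dc_a <- optimize(rss_dc, interval = c(lo, hi), tol = 1e-9)$minimum

  anchored <- list(amplitude = amp_a, offset = offset_a, decay_constant = dc_a)

  if (method == "anchored") {
    est <- anchored
    flags <- character()
  } else {
    df <- data.frame(y = curve, nn = idx)
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ A * exp(-(nn - 1) / Dc) + O,
        data = df,
        start = list(A = amp_a, O = max(offset_a, 0), Dc = dc_a),
        lower = c(A = -Inf, O = 0, Dc = dc_bounds[1]),
        upper = c(A = Inf, O = Inf, Dc = dc_bounds[2]),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) {
      est <- anchored
      flags <- "nls_failed"
    } else {
      cf <- stats::coef(fit)
      est <- list(amplitude = unname(cf["A"]), offset = unname(cf["O"]),
                  decay_constant = unname(cf["Dc"]))
      flags <- character()
    }
  }

  fitted <- habituation_response(est$amplitude, est$offset,
                                 est$decay_constant, idx)
  flags <- c(
    flags,
    if (est$amplitude < 0) "negative_A",
    if (at_bound(est$decay_constant, dc_bounds)) "nonidentifiable_Dc"
  )
  new_habituation_fit(
    amplitude = est$amplitude, offset = est$offset,
    decay_constant = est$decay_constant,
    rss = sum((curve - fitted)^2), method = method, flags = flags,
    fitted = fitted, curve = curve, tail_k = tail_k, dc_bounds = dc_bounds
  )
}

at_bound <- function(dc, bounds, rtol = 1e-4) {
  !is.na(dc) &&
    (dc <= bounds[1] * (1 + rtol) || dc >= bounds[2] * (1 - rtol))
}

new_habituation_fit <- function(amplitude, offset, decay_constant, rss,
                                method, flags, fitted, curve, tail_k,
                                dc_bounds) {
  structure(
    list(
      amplitude = amplitude, offset = offset,
      decay_constant = decay_constant, rss = rss, method = method,
      flags = flags %||% character(), fitted = fitted, curve = curve,
      n_stimuli = length(curve), tail_k = tail_k, dc_bounds = dc_bounds
    ),
    class = "habituation_fit"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.habituation_fit <- function(x, ...) {
  cat(sprintf(
    "<habituation_fit> method=%s\n  A = %.4g mm, O = %.4g mm, Dc = %.4g stimuli, RSS = %.4g\n",
    x$method, x$amplitude, x$offset, x$decay_constant, x$rss
  ))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
predict.habituation_fit <- function(object, stimulus = NULL, ...) {
  stimulus <- stimulus %||% seq_len(object$n_stimuli)
  habituation_response(object$amplitude, object$offset,
                       object$decay_constant, stimulus)
}

#' @rdname fit_habituation
#' @param x A `habituation_fit`.
#' @param ... Unused.
#' @method tidy habituation_fit
#' @export
tidy.habituation_fit <- function(x, ...) {
  tibble::tibble(
    term = c("amplitude", "offset", "decay_constant"),
    estimate = c(x$amplitude, x$offset, x$decay_constant)
  )
}

#' @rdname fit_habituation
#' @method glance habituation_fit
#' @export
glance.habituation_fit <- function(x, ...) {
  tibble::tibble(
    rss = x$rss, method = x$method, n_stimuli = x$n_stimuli,
    flags = paste(x$flags, collapse = ";")
  )
}
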