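#' Paired Wilcoxon signed-rank test
#'
#' Compares two paired samples (e.g. per-fish CDT at baseline versus
#' re-test). Zero differences are dropped before ranking, following the
#' standard signed-rank convention. The reported statistic `W` is the sum of
#' positive-difference ranks; because software packages variously report the
#' rank sum itself or a standardised value, the normal deviate `z` (with tie
#' and continuity correction) is reported alongside, explicitly labelled.
#' The p-value comes from exact enumeration of the signed-rank distribution
#' when `n <= 12` after dropping zeros and there are no ties in the absolute
#' differences, and from the tie- and continuity-corrected normal
#' approximation otherwise (`mode = "auto"`); `"exact"` and `"approx"`
#' force a choice.
#'
#' @param values_a,values_b Equal-length numeric vectors, paired by
#'   position.
#' @param mode `"auto"` (default), `"exact"` or `"approx"`.
#' @param labels Length-2 character vector naming the two samples.
#' @return A one-row tibble: `method`, `comparison`, `n` (pairs used after
#'   dropping zero differences), `n_zero`, `statistic` (W), `z`, `p_value`,
#'   `mode`, `flags`.
#' @examples
#' wilcoxon_signed_rank(c(5, 7, 3, 9), c(4, 2, 1, 6))
#' @export
wilcoxon_signed_rank <- function(values_a, values_b,
                                 mode = c("auto", "exact", "approx"),
                                 labels = c("a", "b")) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(values_a), is.numeric(values_b),
            length(values_a) == length(values_b), length(values_a) >= 2,
            !anyNA(values_a), !anyNA(values_b))
  comparison <- paste(labels[1], "Vs", labels[2])

  d <- values_a - values_b
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)

  if (n == 0) {
    n_all <- length(values_a)
    return(test_result(
      method = "wilcoxon_signed_rank", comparison = comparison,
      statistic = n_all * (n_all + 1) / 4, z = 0, p_value = 1,
      n = 0L, n_zero = n_zero, mode = "degenerate", flags = "degenerate"
    ))
  }

  r <- rank(abs(d))
  W <- sum(r[d > 0])
  ties <- anyDuplicated(r) > 0
  use_exact <- switch(mode,
    exact = TRUE,
    approx = FALSE,
    auto = n <= 12 && !ties
  )
  if (use_exact && ties) {
    warn("exact signed-rank p requested with tied ranks; falling back to the normal approximation.")
    use_exact <- FALSE
  }

  # tie-corrected variance and continuity-corrected deviate, for reporting
  mu <- n * (n + 1) / 4
  tie_tab <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
    sum(tie_tab^3 - tie_tab) / 48
  cc <- sign(W - mu) * 0.5
  z <- if (sigma2 > 0) (W - mu - cc) / sqrt(sigma2) else 0

  wt <- suppressWarnings(
    stats::wilcox.test(d, mu = 0, exact = use_exact, correct = TRUE)
  )
  test_result(
    method = "wilcoxon_signed_rank", comparison = comparison,
    statistic = W, z = z, p_value = wt$p.value, n = n, n_zero = n_zero,
    mode = if (use_exact) "exact" else "approx",
    flags = ""
  )
}

#' Friedman rank test on complete blocks
#'
#' Omnibus non-parametric test for differences between conditions measured
#' repeatedly on the same subjects (e.g. per-fish CDT across rotated
#' conditions, with fish as complete blocks). Reports the tie-corrected
#' chi-squared statistic with `k - 1` degrees of freedom.
#'
#' @param block_matrix Numeric matrix or data frame, subjects in rows,
#'   conditions in columns; must be complete (no missing cells).
#' @return A one-row tibble: `method`, `statistic` (chi-squared), `df`,
#'   `p_value`, `n` (subjects).
#' @examples
#' m <- matrix(c(1, 2, 3, 2, 3, 4, 3, 4, 5), nrow = 3, byrow = TRUE)
#' friedman_rank_test(m)  # chi-squared = 6 on strictly ordered rows
#' @export
friedman_rank_test <- function(block_matrix) {
  m <- as_block_matrix(block_matrix)
  if (all(apply(m, 1, function(r) diff(range(r))) == 0)) {
    # every block fully tied: no rank information, null by construction
    return(test_result(
      method = "friedman", comparison = NA_character_, statistic = 0,
      df = as.numeric(ncol(m) - 1), p_value = 1, n = nrow(m)
    ))
  }
  ft <- stats::friedman.test(m)
  test_result(
    method = "friedman", comparison = NA_character_,
    statistic = unname(ft$statistic), df = unname(ft$parameter),
    p_value = ft$p.value, n = nrow(m)
  )
}

#' Dunn's pairwise post-hoc comparisons after a Friedman test
#'
#' Compares all condition pairs via Dunn's procedure on within-block mean
#' ranks: `z = (Rbar_i - Rbar_j) / sqrt(k (k + 1) / (6 n))`, two-sided
#' normal p, Bonferroni-adjusted by the number of pairs tested and capped at
#' 1. The family is all pairs, including control-versus-condition rows.
#'
#' @param block_matrix As in [friedman_rank_test()].
#' @param adjust Adjustment method; only `"bonferroni"` is provided.
#' @return A tibble with one row per pair: `method`, `comparison`
#'   (`"i Vs j"`), `statistic` (z), `p_value`, `adjusted_p`, `n`.
#' @export
dunn_posthoc <- function(block_matrix, adjust = "bonferroni") {
  adjust <- match.arg(adjust, "bonferroni")
  m <- as_block_matrix(block_matrix)
  n <- nrow(m)
  k <- ncol(m)
  ranks <- t(apply(m, 1, rank))
  mean_ranks <- colMeans(ranks)
  se <- sqrt(k * (k + 1) / (6 * n))
  pairs <- utils::combn(k, 2)
  n_pairs <- ncol(pairs)
  labs <- colnames(m)

  purrr::map(seq_len(n_pairs), function(q) {
    i <- pairs[1, q]
    j <- pairs[2, q]
    z <- unname(mean_ranks[i] - mean_ranks[j]) / se
    p <- 2 * pnorm(-abs(z))
    test_result(
      method = "dunn", comparison = paste(labs[i], "Vs", labs[j]),
      statistic = z, p_value = p,
      adjusted_p = min(1, p * n_pairs), n = n
    )
  }) |> purrr::list_rbind()
}

#' Spearman rank correlation
#'
#' Association between two measures (e.g. the mean count of responses and
#' the mean distance travelled per stimulus). The coefficient is the Pearson
#' correlation of average ranks. The two-sided p-value is exact (full
#' permutation enumeration, valid with ties) for `n <= 8` and uses the
#' t approximation `t = r * sqrt((n - 2) / (1 - r^2))` otherwise
#' (`mode = "auto"`).
#'
#' @param x,y Equal-length numeric vectors, `n >= 3`.
#' @param mode `"auto"` (default), `"exact"` or `"approx"`.
#' @return A one-row tibble: `method`, `statistic` (r), `p_value`, `n`,
#'   `mode`, `flags`. Zero variance in either input yields `r = NA` flagged
#'   `degenerate`.
#' @examples
#' spearman_rank(1:10, (1:10)^2)  # r = 1
#' @export
spearman_rank <- function(x, y, mode = c("auto", "exact", "approx")) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y),
            length(x) >= 3, !anyNA(x), !anyNA(y))
  n <- length(x)
  if (sd(x) == 0 || sd(y) == 0) {
    return(test_result(
      method = "spearman", comparison = NA_character_,
      statistic = NA_real_, p_value = NA_real_, n = n,
      mode = "degenerate", flags = "degenerate"
    ))
  }
  rx <- rank(x)
  ry <- rank(y)
  r <- cor(rx, ry)

  use_exact <- switch(mode, exact = TRUE, approx = FALSE, auto = n <= 8)
  if (use_exact && n > 8) {
    warn("exact Spearman p only enumerated for n <= 8; using t approximation.")
    use_exact <- FALSE
  }
  if (use_exact) {
    perms <- permutations(n)
    r_perm <- apply(perms, 1, function(p) cor(rx, ry[p]))
    p_value <- mean(abs(r_perm) >= abs(r) - 1e-12)
  } else {
    if (abs(r) >= 1) {
      p_value <- 0
    } else {
      tt <- r * sqrt((n - 2) / (1 - r^2))
      p_value <- 2 * pt(-abs(tt), df = n - 2)
    }
  }
  test_result(
    method = "spearman", comparison = NA_character_, statistic = r,
    p_value = p_value, n = n, mode = if (use_exact) "exact" else "approx",
    flags = ""
  )
}

# all permutations of 1..n as an n! x n matrix (n <= 8 in practice)
permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    block <- cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
    out[row:(row + nrow(sub) - 1L), ] <- block
    row <- row + nrow(sub)
  }
  out
}

as_block_matrix <- function(block_matrix) {
  m <- as.matrix(block_matrix)
  if (!is.numeric(m)) abort("`block_matrix` must be numeric.")
  if (anyNA(m)) abort("incomplete blocks: `block_matrix` has missing cells.")
  if (nrow(m) < 2 || ncol(m) < 2) {
    abort("`block_matrix` needs >= 2 subjects and >= 2 conditions.")
  }
  if (is.null(colnames(m))) {
    colnames(m) <- paste0("Condt. ", seq_len(ncol(m)))
  }
  m
}

# common TestResult row shape
test_result <- function(method, comparison = NA_character_, statistic,
                        z = NA_real_, df = NA_real_, p_value,
                        adjusted_p = NA_real_, n, n_zero = NA_integer_,
                        mode = NA_character_, flags = "") {
  tibble::tibble(
    method = method,
    comparison = comparison,
    statistic = statistic,
    z = z,
    df = df,
    p_value = p_value,
    adjusted_p = adjusted_p,
    n = as.integer(n),
    n_zero = as.integer(n_zero),
    mode = mode,
    flags = flags
  )
}
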