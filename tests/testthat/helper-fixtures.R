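# Small in-code fixtures shared across test files.

# long table for `n_fish` fish with given per-stimulus distances
make_traces <- function(distances, n_fish = 1, group = "g", condition = "c",
                        phase = NULL, fish_ids = NULL) {
  n_stim <- length(distances)
  fish_ids <- fish_ids %||% sprintf("f%02d", seq_len(n_fish))
  out <- tidyr::expand_grid(
    fish_id = fish_ids,
    stimulus_index = seq_len(n_stim)
  )
  out$group <- group
  out$condition <- condition
  out$distance_mm <- rep(distances, times = n_fish)
  if (!is.null(phase)) out$phase <- phase
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# exact two-sided signed-rank p by full sign enumeration (oracle)
enumerate_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  W_all <- as.vector(signs %*% r)
  p_hi <- mean(W_all >= W_obs)
  p_lo <- mean(W_all <= W_obs)
  min(1, 2 * min(p_hi, p_lo))
}

# tie-corrected Friedman chi-squared from first principles (oracle)
friedman_formula <- function(m) {
  n <- nrow(m)
  k <- ncol(m)
  r <- t(apply(m, 1, rank))
  num <- (k - 1) * sum((colSums(r) - n * (k + 1) / 2)^2)
  den <- sum(r^2) - n * k * (k + 1)^2 / 4
  num / den
}
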