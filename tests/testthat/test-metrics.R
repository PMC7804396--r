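test_that("per-fish CDT sums the distance over all stimuli", {
  expect_identical(fish_cdt(habituation_data(make_traces(rep(0, 20))))$cdt, 0)

  const <- make_traces(rep(1, 20))
  # sub-threshold distances are zeroed on ingestion, so use raw tables here
  const$phase <- "main"
  const$responded <- FALSE
  expect_identical(fish_cdt(const)$cdt, 20)

  set.seed(21)
  for (i in 1:10) {
    d <- runif(20, 0, 30)
    tr <- make_traces(d)
    tr$phase <- "main"
    total <- 0
    for (x in d) total <- total + x  # brute-force accumulation oracle
    expect_equal(fish_cdt(tr)$cdt, total, tolerance = 1e-12)
  }
})

test_that("a single-fish cohort gets SE 0 with a warning and its own trace as mean curve", {
  d <- c(10, 8, 6, 5, rep(4, 16))
  ds <- habituation_data(make_traces(d))
  expect_warning(s <- summarize_group(ds), "single fish")
  expect_equal(s$per_stimulus$mean_mm, apply_movement_threshold(d))
  expect_true(all(s$per_stimulus$se_mm == 0))
  expect_identical(s$overall$se_cdt, 0)
})

test_that("response probability is the percentage of first-stimulus responders", {
  tr <- rbind(
    make_traces(c(0, rep(0, 19)), fish_ids = "f1"),
    make_traces(c(10, rep(0, 19)), fish_ids = "f2")
  )
  ds <- habituation_data(tr)
  suppressWarnings(s <- summarize_group(ds))
  expect_identical(s$overall$response_probability, 50)
  expect_identical(response_probability(ds)$response_probability, 50)
  # "any stimulus" variant counts fish responding at least once
  tr2 <- rbind(
    make_traces(c(0, 5, rep(0, 18)), fish_ids = "f1"),
    make_traces(c(10, rep(0, 19)), fish_ids = "f2")
  )
  ds2 <- habituation_data(tr2)
  expect_identical(response_probability(ds2)$response_probability, 50)
  expect_identical(
    response_probability(ds2, scope = "any")$response_probability, 100
  )
})

test_that("group summaries match column-mean oracles and are permutation-invariant", {
  cfg <- group_config(n_fish = 24, amplitude = 20, offset = 5,
                      decay_constant = 1.5, p_respond = 1,
                      fish_heterogeneity_sd = 0.2, noise_sd = 0.2, seed = 8)
  ds <- habituation_data(simulate_group(cfg))
  s <- summarize_group(ds)

  wide <- tidyr::pivot_wider(
    tibble::as_tibble(ds)[, c("fish_id", "stimulus_index", "distance_mm")],
    names_from = "stimulus_index", values_from = "distance_mm"
  )
  m <- as.matrix(wide[, -1])
  expect_equal(s$per_stimulus$mean_mm, unname(colMeans(m)), tolerance = 1e-12)
  expect_equal(
    s$per_stimulus$se_mm,
    unname(apply(m, 2, sd)) / sqrt(24),
    tolerance = 1e-12
  )

  # CDT curve: nondecreasing, ends at the group mean CDT, equals sum of means
  expect_true(all(diff(s$per_stimulus$cum_mean_mm) >= 0))
  expect_equal(dplyr::last(s$per_stimulus$cum_mean_mm), s$overall$mean_cdt,
               tolerance = 1e-12)
  expect_equal(sum(s$per_stimulus$mean_mm), s$overall$mean_cdt,
               tolerance = 1e-12)

  # shuffling fish order changes nothing
  shuffled <- ds[sample(nrow(ds)), ]
  s2 <- summarize_group(shuffled)
  expect_equal(s$per_stimulus, s2$per_stimulus, tolerance = 1e-12)
  expect_equal(s$overall, s2$overall, tolerance = 1e-12)
})

test_that("delta CDT pairs fish across phases and subtracts re-test from baseline", {
  two_phase <- rbind(
    make_traces(rep(3, 20), n_fish = 4, phase = "baseline"),
    make_traces(rep(3, 20), n_fish = 4, phase = "retest")
  )
  ds <- habituation_data(two_phase)
  expect_true(all(delta_cdt(ds)$delta == 0))

  tb <- make_traces(rep(2.5, 20), n_fish = 4, phase = "baseline")
  tr <- make_traces(rep(1.5, 20), n_fish = 4, phase = "retest")
  tr$distance_mm <- 2.25  # above threshold so nothing is zeroed
  ds2 <- habituation_data(rbind(tb, tr))
  expect_equal(delta_cdt(ds2)$delta, rep(20 * (2.5 - 2.25), 4),
               tolerance = 1e-12)

  missing_fish <- rbind(tb, tr[tr$fish_id != "f01", ])
  expect_error(delta_cdt(habituation_data(missing_fish)), "unmatched fish")

  # simulated paired design equals the hand-paired oracle
  s1 <- simulate_study("study1", seed = 6)
  d <- delta_cdt(s1$`1min`)
  cdt <- fish_cdt(s1$`1min`)
  for (i in seq_len(nrow(d))) {
    b <- cdt$cdt[cdt$fish_id == d$fish_id[i] & cdt$phase == "baseline"]
    r <- cdt$cdt[cdt$fish_id == d$fish_id[i] & cdt$phase == "retest"]
    expect_equal(d$delta[i], b - r, tolerance = 1e-12)
  }
})

test_that("discrete and continuous measures correlate strongly on stimulated conditions", {
  ds <- simulate_study("study2a", seed = 2)
  for (cond in c("200Hz", "400Hz", "600Hz", "800Hz")) {
    s <- summarize_group(ds[[cond]])
    r <- spearman_rank(s$per_stimulus$response_rate,
                       s$per_stimulus$mean_mm)$statistic
    expect_gt(r, 0.5)
  }
})
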