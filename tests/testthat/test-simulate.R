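test_that("the noise-free generator evaluates the habituation model exactly", {
  cfg <- group_config(n_fish = 5, amplitude = 10, offset = 2,
                      decay_constant = 1, p_respond = 1,
                      fish_heterogeneity_sd = 0, noise_sd = 0, seed = 3)
  tr <- simulate_group(cfg, stimulus_schedule())
  expected <- 10 * exp(-(0:19)) + 2
  for (f in unique(tr$fish_id)) {
    d <- tr$distance_mm[tr$fish_id == f][order(tr$stimulus_index[tr$fish_id == f])]
    expect_equal(d, expected, tolerance = 1e-12)
    expect_identical(d[1], 12)
  }
})

test_that("a silent group (p_respond = 0) produces only zeros", {
  cfg <- group_config(n_fish = 10, amplitude = 10, offset = 2,
                      decay_constant = 1, p_respond = 0, seed = 1)
  tr <- simulate_group(cfg)
  expect_true(all(tr$distance_mm == 0))
  ds <- habituation_data(tr)
  expect_identical(response_probability(ds)$response_probability, 0)
})

test_that("generation is deterministic given the seed and leaves the caller's RNG alone", {
  cfg <- group_config(n_fish = 8, amplitude = 10, offset = 1,
                      decay_constant = 1.5, p_respond = 0.7,
                      fish_heterogeneity_sd = 0.2, noise_sd = 0.2, seed = 99)
  a <- simulate_group(cfg)
  set.seed(123)
  before <- .Random.seed
  b <- simulate_group(cfg)
  expect_identical(a, b)
  expect_identical(.Random.seed, before)
})

test_that("stimulus-1 response fraction converges to p_respond (law of large numbers)", {
  p <- 0.6
  n <- 10000
  cfg <- group_config(n_fish = n, amplitude = 10, offset = 2,
                      decay_constant = 1.5, p_respond = p,
                      fish_heterogeneity_sd = 0.2, noise_sd = 0.2, seed = 11)
  tr <- simulate_group(cfg)
  frac <- mean(tr$distance_mm[tr$stimulus_index == 1] > 0)
  expect_lt(abs(frac - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("group means track p * (A exp(-n/Dc) + O) under zero heterogeneity", {
  p <- 0.7
  cfg <- group_config(n_fish = 20000, amplitude = 12, offset = 3,
                      decay_constant = 2, p_respond = p,
                      fish_heterogeneity_sd = 0, noise_sd = 0, seed = 5)
  tr <- simulate_group(cfg)
  means <- tapply(tr$distance_mm, tr$stimulus_index, mean)
  expected <- p * (12 * exp(-(0:19) / 2) + 3)
  expect_equal(unname(as.vector(means)), expected, tolerance = 0.02)
})

test_that("memory carryover scales the re-test amplitude; carryover 1 reproduces baseline", {
  base <- list(n_fish = 6, amplitude = 10, offset = 2, decay_constant = 1.5,
               p_respond = 1, fish_heterogeneity_sd = 0, noise_sd = 0,
               seed = 4)
  cfg_half <- do.call(group_config, c(base, memory_carryover = 0.5))
  tr <- simulate_group(cfg_half, phases = c("baseline", "retest"))
  first_b <- tr$distance_mm[tr$phase == "baseline" & tr$stimulus_index == 1]
  first_r <- tr$distance_mm[tr$phase == "retest" & tr$stimulus_index == 1]
  expect_equal(unique(first_b), 12)
  expect_equal(unique(first_r), 0.5 * 10 + 2)

  cfg_full <- do.call(group_config, c(base, memory_carryover = 1))
  tr2 <- simulate_group(cfg_full, phases = c("baseline", "retest"))
  b <- tr2[tr2$phase == "baseline", c("fish_id", "stimulus_index", "distance_mm")]
  r <- tr2[tr2$phase == "retest", c("fish_id", "stimulus_index", "distance_mm")]
  expect_identical(b$distance_mm, r$distance_mm)
})

test_that("study presets produce the documented designs", {
  s2a <- simulate_study("study2a", seed = 1)
  expect_named(s2a, c("control", "200Hz", "400Hz", "600Hz", "800Hz"))
  for (d in s2a) {
    expect_identical(length(unique(d$fish_id)), 90L)
    expect_identical(nrow(d), 90L * 20L)
  }
  # shared fish ids across conditions -> complete blocks
  expect_identical(unique(s2a$control$fish_id), unique(s2a$`800Hz`$fish_id))

  s1 <- simulate_study("study1", seed = 1)
  expect_named(s1, c("1min", "5min", "15min"))
  for (d in s1) {
    expect_identical(length(unique(d$fish_id)), 48L)
    expect_setequal(unique(d$phase), c("baseline", "retest"))
  }

  s3 <- simulate_study("study3", seed = 1)
  expect_named(s3, c("control", "135lx", "180lx", "240lx"))
  for (d in s3) expect_identical(length(unique(d$fish_id)), 96L)

  expect_error(simulate_study("study9", seed = 1), "unknown preset")

  # ground truth recorded in provenance
  gt <- attr(s2a$`200Hz`, "provenance")$ground_truth
  expect_identical(gt$amplitude, 9)
})

test_that("stream seeds derived from (preset, condition) are stable and distinct", {
  s1 <- derive_seed(1L, "study2a control")
  s2 <- derive_seed(1L, "study2a 200Hz")
  expect_identical(s1, derive_seed(1L, "study2a control"))
  expect_false(s1 == s2)
  expect_true(s1 >= 0 && s1 < 2^31 - 1)
  expect_false(derive_seed(2L, "study2a control") == s1)
})
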