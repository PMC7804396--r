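#' Configure a synthetic group of fish
#'
#' The generator draws, for fish i, a lognormally perturbed amplitude and
#' offset (`A_i = amplitude * exp(eta_i)`, `O_i = offset * exp(nu_i)`,
#' `eta, nu ~ Normal(0, fish_heterogeneity_sd)`), and at stimulus n
#' (n = 0 at the first stimulus) emits, with probability `p_respond`,
#' `max(0, (A_i * exp(-n / decay_constant) + O_i) * (1 + eps))` with
#' `eps ~ Normal(0, noise_sd)`, and 0 otherwise (a failed response). The
#' lognormal fish effect keeps distances non-negative without truncating
#' the mean structure, and failed responses are exact zeros, matching the
#' thresholded storage convention and the zero spike of observed
#' response-magnitude histograms.
#'
#' @param n_fish Number of fish (>= 1).
#' @param amplitude,offset Population amplitude and offset, mm (>= 0).
#' @param decay_constant Population decay constant, in stimuli (> 0).
#' @param p_respond Per-stimulus response probability; a scalar, or a vector
#'   of length `n_stimuli` for sensitivity analyses.
#' @param fish_heterogeneity_sd SD of the log-scale per-fish perturbation of
#'   amplitude and offset (default 0).
#' @param noise_sd SD of the multiplicative per-response noise (default 0).
#' @param memory_carryover Fraction in \[0, 1\]: in every phase after the
#'   first, the per-fish initial amplitude is `memory_carryover * A_i`
#'   (habituation memory retained from the previous phase); 1 reproduces
#'   the first phase in distribution.
#' @param seed Integer seed; generation is deterministic given the seed.
#' @return A `group_config` list.
#' @export
group_config <- function(n_fish,
                         amplitude,
                         offset,
                         decay_constant,
                         p_respond = 1,
                         fish_heterogeneity_sd = 0,
                         noise_sd = 0,
                         memory_carryover = 1,
                         seed = 1L) {
  if (!is_count(n_fish) || n_fish < 1) abort("`n_fish` must be >= 1.")
  if (!is_number(amplitude) || amplitude < 0) abort("`amplitude` must be >= 0 mm.")
  if (!is_number(offset) || offset < 0) abort("`offset` must be >= 0 mm.")
  if (!is_number(decay_constant) || decay_constant <= 0) {
    abort("`decay_constant` must be > 0 stimuli.")
  }
  if (!is.numeric(p_respond) || any(p_respond < 0 | p_respond > 1)) {
    abort("`p_respond` must lie in [0, 1].")
  }
  if (!is_number(fish_heterogeneity_sd) || fish_heterogeneity_sd < 0) {
    abort("`fish_heterogeneity_sd` must be >= 0.")
  }
  if (!is_number(noise_sd) || noise_sd < 0) abort("`noise_sd` must be >= 0.")
  if (!is_number(memory_carryover) || memory_carryover < 0 ||
      memory_carryover > 1) {
    abort("`memory_carryover` must lie in [0, 1].")
  }
  if (!is_count(seed)) abort("`seed` must be an integer.")

  structure(
    list(
      n_fish = as.integer(n_fish),
      amplitude = amplitude,
      offset = offset,
      decay_constant = decay_constant,
      p_respond = p_respond,
      fish_heterogeneity_sd = fish_heterogeneity_sd,
      noise_sd = noise_sd,
      memory_carryover = memory_carryover,
      seed = as.integer(seed)
    ),
    class = "group_config"
  )
}

#' Simulate one group of fish under a stimulus schedule
#'
#' See [group_config()] for the generative model. When several phases are
#' requested (e.g. `c("baseline", "retest")`), the per-fish amplitude and
#' offset draws are shared across phases and every phase after the first
#' starts from `memory_carryover * A_i`, emulating retained habituation
#' memory.
#'
#' @param config A [group_config()].
#' @param schedule A [stimulus_schedule()].
#' @param group,condition Labels stamped on every row.
#' @param phases Character vector of phase labels (default `"main"`).
#' @param fish_ids Optional explicit fish identifiers (length `n_fish`);
#'   defaults to `f001, f002, ...`. Reusing the same ids across conditions
#'   encodes a rotated within-subject design with complete blocks.
#' @return A long tibble with columns `fish_id`, `group`, `condition`,
#'   `phase`, `stimulus_index`, `distance_mm` (raw generator output; pass it
#'   through [habituation_data()] to threshold and validate).
#' @examples
#' cfg <- group_config(n_fish = 4, amplitude = 10, offset = 2,
#'                     decay_constant = 1, seed = 7)
#' simulate_group(cfg, stimulus_schedule())
#' @export
simulate_group <- function(config, schedule = stimulus_schedule(),
                           group = "group1", condition = "stimulated",
                           phases = "main", fish_ids = NULL) {
  stopifnot(inherits(config, "group_config"),
            inherits(schedule, "stimulus_schedule"))
  n_fish <- config$n_fish
  n_stim <- schedule$n_stimuli
  p <- config$p_respond
  if (length(p) == 1L) p <- rep(p, n_stim)
  if (length(p) != n_stim) {
    abort("`p_respond` must be scalar or one value per stimulus.")
  }
  if (is.null(fish_ids)) {
    fish_ids <- sprintf("f%03d", seq_len(n_fish))
  } else if (length(fish_ids) != n_fish) {
    abort("`fish_ids` must have length `n_fish`.")
  }

  decay <- exp(-(seq_len(n_stim) - 1) / config$decay_constant)

  local_seed(config$seed, {
    eta <- rnorm(n_fish, 0, config$fish_heterogeneity_sd)
    nu <- rnorm(n_fish, 0, config$fish_heterogeneity_sd)
    A_i <- config$amplitude * exp(eta)
    O_i <- config$offset * exp(nu)

    out <- purrr::imap(phases, function(phase, k) {
      carry <- if (k == 1L) 1 else config$memory_carryover
      mu <- outer(carry * A_i, decay) + O_i  # n_fish x n_stim
      resp <- matrix(
        rbinom(n_fish * n_stim, 1L, rep(p, each = n_fish)),
        nrow = n_fish
      )
      eps <- matrix(rnorm(n_fish * n_stim, 0, config$noise_sd), nrow = n_fish)
      dist <- resp * pmax(0, mu * (1 + eps))
      tibble::tibble(
        fish_id = rep(fish_ids, times = n_stim),
        group = group,
        condition = condition,
        phase = phase,
        stimulus_index = rep(seq_len(n_stim), each = n_fish),
        distance_mm = as.vector(dist)
      )
    })
    purrr::list_rbind(out) |>
      dplyr::arrange(.data$fish_id, .data$phase, .data$stimulus_index)
  })
}

#' Study design presets
#'
#' Returns the documented generator presets for the five study designs the
#' package ships: a habituation-memory design with baseline and re-test
#' phases (`study1`), vibratory frequency (`study2a`), acoustic power
#' (`study2b`), ISI duration (`study2c`) and light-flash illuminance
#' (`study3`) designs, each with an unstimulated control. Per-condition
#' generator parameters are fixed documented choices that reproduce the
#' ordinal patterns these designs are used to detect (control below every
#' stimulated condition; amplitude falling from 200 to 800 Hz; cumulative
#' distance rising with power; offset rising with ISI; re-test suppression
#' only under partial memory carryover); see the methods vignette.
#'
#' @return Named list of preset descriptions.
#' @export
study_presets <- function() {
  vib <- function(freq, power, isi = 1000) {
    stimulus_schedule(modality = "vibratory", frequency = freq, power = power,
                      isi = isi)
  }
  list(
    study1 = list(
      design = "paired",
      n_fish = 48L,
      phases = c("baseline", "retest"),
      schedule = vib(400, 126, isi = 1000),
      groups = list(
        `1min` = list(p_respond = 0.85, memory_carryover = 0.5),
        `5min` = list(p_respond = 0.77, memory_carryover = 1),
        `15min` = list(p_respond = 0.87, memory_carryover = 1)
      ),
      base = list(amplitude = 10, offset = 2.5, decay_constant = 1.5,
                  fish_heterogeneity_sd = 0.2, noise_sd = 0.2)
    ),
    study2a = list(
      design = "blocked",
      n_fish = 90L,
      conditions = list(
        control = list(p_respond = 0.21, amplitude = 0.3, offset = 2.5,
                       decay_constant = 1.5, schedule = vib(400, 126)),
        `200Hz` = list(p_respond = 0.80, amplitude = 9, offset = 2.5,
                       decay_constant = 1.5, schedule = vib(200, 124)),
        `400Hz` = list(p_respond = 0.622, amplitude = 8, offset = 2.5,
                       decay_constant = 1.5, schedule = vib(400, 126)),
        `600Hz` = list(p_respond = 0.60, amplitude = 6, offset = 2.5,
                       decay_constant = 1.5, schedule = vib(600, 117)),
        `800Hz` = list(p_respond = 0.455, amplitude = 5, offset = 2.5,
                       decay_constant = 1.5, schedule = vib(800, 111))
      ),
      base = list(fish_heterogeneity_sd = 0.2, noise_sd = 0.2)
    ),
    study2b = list(
      design = "blocked",
      n_fish = 120L,
      conditions = list(
        control = list(p_respond = 0.283, amplitude = 0.3, offset = 2.5,
                       decay_constant = 1.5, schedule = vib(400, 126)),
        `100dB` = list(p_respond = 0.342, amplitude = 4, offset = 2.2,
                       decay_constant = 1.5, schedule = vib(400, 100)),
        `108dB` = list(p_respond = 0.442, amplitude = 5, offset = 2.3,
                       decay_constant = 1.5, schedule = vib(400, 108)),
        `118dB` = list(p_respond = 0.533, amplitude = 7, offset = 2.5,
                       decay_constant = 1.5, schedule = vib(400, 118)),
        `126dB` = list(p_respond = 0.65, amplitude = 10, offset = 3,
                       decay_constant = 1.5, schedule = vib(400, 126))
      ),
      base = list(fish_heterogeneity_sd = 0.2, noise_sd = 0.2)
    ),
    study2c = list(
      design = "blocked",
      n_fish = 120L,
      conditions = list(
        control = list(p_respond = 0.30, amplitude = 0.3, offset = 2.5,
                       decay_constant = 1.5, schedule = vib(400, 126)),
        `ISI500ms` = list(p_respond = 0.908, amplitude = 12, offset = 2.2,
                          decay_constant = 1.2, schedule = vib(400, 126, 500)),
        `ISI1s` = list(p_respond = 0.875, amplitude = 11, offset = 2.5,
                       decay_constant = 1.2, schedule = vib(400, 126, 1000)),
        `ISI3s` = list(p_respond = 0.833, amplitude = 10, offset = 3.2,
                       decay_constant = 1.8, schedule = vib(400, 126, 3000)),
        `ISI5s` = list(p_respond = 0.867, amplitude = 10, offset = 4.5,
                       decay_constant = 1.8, schedule = vib(400, 126, 5000))
      ),
      base = list(fish_heterogeneity_sd = 0.2, noise_sd = 0.2)
    ),
    study3 = list(
      design = "blocked",
      n_fish = 96L,
      conditions = list(
        control = list(
          p_respond = 0.563, amplitude = 0.5, offset = 2.8,
          decay_constant = 1.5,
          schedule = stimulus_schedule(modality = "light",
                                       illuminance_step = 0)
        ),
        `135lx` = list(
          p_respond = 0.688, amplitude = 6, offset = 2.8,
          decay_constant = 1.5,
          schedule = stimulus_schedule(modality = "light",
                                       illuminance_step = 135)
        ),
        `180lx` = list(
          p_respond = 0.656, amplitude = 6, offset = 2.8,
          decay_constant = 1.5,
          schedule = stimulus_schedule(modality = "light",
                                       illuminance_step = 180)
        ),
        `240lx` = list(
          p_respond = 0.635, amplitude = 6, offset = 2.8,
          decay_constant = 1.5,
          schedule = stimulus_schedule(modality = "light",
                                       illuminance_step = 240)
        )
      ),
      base = list(fish_heterogeneity_sd = 0.2, noise_sd = 0.2)
    )
  )
}

#' Simulate a full study design
#'
#' Generates one validated dataset per condition (or per re-test group, for
#' the paired habituation-memory design), with the sample sizes, condition
#' labels and schedules of the corresponding design. Fish identifiers are
#' shared across conditions within a study, encoding the rotated
#' within-subject design that yields complete blocks for rank tests.
#' Per-condition random streams are derived deterministically from the
#' master seed and the (preset, condition) labels, so adding a condition
#' does not perturb the others. The generator ground truth is recorded in
#' each dataset's provenance.
#'
#' @param preset One of `"study1"`, `"study2a"`, `"study2b"`, `"study2c"`,
#'   `"study3"`.
#' @param seed Master integer seed.
#' @param threshold Movement threshold in mm applied on ingestion.
#' @return Named list of `habituation_data`, one per condition/group.
#' @examples
#' ds <- simulate_study("study2a", seed = 1)
#' names(ds)
#' @export
simulate_study <- function(preset, seed = 1L, threshold = 2) {
  presets <- study_presets()
  if (!preset %in% names(presets)) {
    abort(sprintf(
      "unknown preset '%s'; available: %s",
      preset, paste(names(presets), collapse = ", ")
    ))
  }
  ps <- presets[[preset]]

  if (ps$design == "paired") {
    cells <- ps$groups
    make_one <- function(nm, cell_params) {
      cfg <- do.call(group_config, c(
        list(n_fish = ps$n_fish, seed = derive_seed(seed, paste(preset, nm))),
        ps$base, cell_params
      ))
      traces <- simulate_group(cfg, ps$schedule, group = nm,
                               condition = "400Hz", phases = ps$phases)
      habituation_data(
        traces, schedule = ps$schedule, threshold = threshold,
        provenance = list(
          generator = "startlehab synthetic (stand-in distributions)",
          preset = preset, group = nm, seed = seed,
          ground_truth = c(ps$base, cell_params, n_fish = ps$n_fish)
        )
      )
    }
  } else {
    cells <- ps$conditions
    make_one <- function(nm, cell_params) {
      sched <- cell_params$schedule
      cell_params$schedule <- NULL
      cfg <- do.call(group_config, c(
        list(n_fish = ps$n_fish, seed = derive_seed(seed, paste(preset, nm))),
        ps$base, cell_params
      ))
      traces <- simulate_group(cfg, sched, group = preset, condition = nm)
      habituation_data(
        traces, schedule = sched, threshold = threshold,
        provenance = list(
          generator = "startlehab synthetic (stand-in distributions)",
          preset = preset, condition = nm, seed = seed,
          ground_truth = c(ps$base, cell_params, n_fish = ps$n_fish)
        )
      )
    }
  }

  purrr::imap(cells, function(cell_params, nm) make_one(nm, cell_params))
}

#' Derive a stream seed from a master seed and a label
#'
#' Deterministic 31-bit polynomial hash, so per-condition random streams are
#' stable under additions elsewhere in a study.
#'
#' @param master Integer master seed.
#' @param label Character scalar naming the stream.
#' @return An integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, label) {
  stopifnot(is_count(master), is.character(label), length(label) == 1L)
  m <- 2147483647  # 2^31 - 1
  h <- as.double(master) %% m
  for (ch in utf8ToInt(label)) {
    h <- (h * 31 + ch) %% m
  }
  as.integer(h)
}

# Evaluate `code` under `seed` without disturbing the caller's RNG state.
local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}
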