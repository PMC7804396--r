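#' Define a stimulus schedule
#'
#' A schedule describes the pulse train presented to a plate of larvae: a
#' fixed number of square-wave stimuli of fixed duration, separated by a
#' fixed interstimulus interval (ISI). Vibratory/acoustic schedules carry a
#' frequency (Hz) and power (dB); light-flash schedules carry an illuminance
#' step (lux) above the baseline illuminance. Movements during ISIs are never
#' quantified, so the schedule defines exactly the analysis windows.
#'
#' @param n_stimuli Number of stimuli in the train (default 20).
#' @param stimulus_duration Stimulus length in ms (default 500).
#' @param isi Interstimulus interval in ms (default 1000).
#' @param modality `"vibratory"` or `"light"`.
#' @param frequency Vibration frequency in Hz (vibratory only).
#' @param power Acoustic power in dB (vibratory only).
#' @param illuminance_step Step increase in illuminance in lux (light only;
#'   0 is allowed and denotes an unstimulated control train).
#' @param baseline_illuminance Ambient illuminance in lux (default 330).
#' @param lead_in,lead_out Idle time in seconds before the first and after
#'   the last stimulus (default 0). Exposed because run durations reported
#'   for tracking sessions often include constant per-run overhead.
#'
#' @return An object of class `stimulus_schedule`. Its `session_duration`
#'   element is `lead_in + (n_stimuli * stimulus_duration +
#'   (n_stimuli - 1) * isi) / 1000 + lead_out`, in seconds.
#' @examples
#' stimulus_schedule(frequency = 400, power = 126, isi = 1000)
#' @export
stimulus_schedule <- function(n_stimuli = 20,
                              stimulus_duration = 500,
                              isi = 1000,
                              modality = c("vibratory", "light"),
                              frequency = 400,
                              power = 126,
                              illuminance_step = NULL,
                              baseline_illuminance = 330,
                              lead_in = 0,
                              lead_out = 0) {
  modality <- match.arg(modality)
  if (!is_count(n_stimuli) || n_stimuli < 1) {
    abort("`n_stimuli` must be a positive integer.")
  }
  if (!is_number(stimulus_duration) || stimulus_duration <= 0) {
    abort("`stimulus_duration` must be > 0 ms.")
  }
  if (!is_number(isi) || isi < 0) abort("`isi` must be >= 0 ms.")
  if (!is_number(lead_in) || lead_in < 0 || !is_number(lead_out) || lead_out < 0) {
    abort("`lead_in` and `lead_out` must be >= 0 s.")
  }

  if (modality == "vibratory") {
    if (!is.null(illuminance_step)) {
      abort("`illuminance_step` applies only to light schedules.")
    }
    if (!is_number(frequency) || frequency <= 0) {
      abort("vibratory schedules need `frequency` > 0 Hz.")
    }
    if (!is_number(power) || power <= 0) {
      abort("vibratory schedules need `power` > 0 dB.")
    }
    illuminance_step <- NULL
  } else {
    if (!missing(frequency) && !is.null(frequency)) {
      abort("`frequency` applies only to vibratory schedules.")
    }
    if (!missing(power) && !is.null(power)) {
      abort("`power` applies only to vibratory schedules.")
    }
    if (is.null(illuminance_step) || !is_number(illuminance_step) ||
        illuminance_step < 0) {
      abort("light schedules need `illuminance_step` >= 0 lux.")
    }
    frequency <- NULL
    power <- NULL
  }

  n_stimuli <- as.integer(n_stimuli)
  session_duration <- lead_in +
    (n_stimuli * stimulus_duration + (n_stimuli - 1L) * isi) / 1000 +
    lead_out

  structure(
    list(
      n_stimuli = n_stimuli,
      stimulus_duration = stimulus_duration,
      isi = isi,
      modality = modality,
      frequency = frequency,
      power = power,
      illuminance_step = illuminance_step,
      baseline_illuminance = baseline_illuminance,
      lead_in = lead_in,
      lead_out = lead_out,
      session_duration = session_duration
    ),
    class = "stimulus_schedule"
  )
}

#' @export
print.stimulus_schedule <- function(x, ...) {
  cat(sprintf(
    "<stimulus_schedule> %d x %g ms %s stimuli, ISI %g ms\n",
    x$n_stimuli, x$stimulus_duration, x$modality, x$isi
  ))
  if (x$modality == "vibratory") {
    cat(sprintf("  frequency %g Hz, power %g dB\n", x$frequency, x$power))
  } else {
    cat(sprintf(
      "  illuminance step +%g lux over %g lux baseline\n",
      x$illuminance_step, x$baseline_illuminance
    ))
  }
  cat(sprintf("  session duration %g s\n", x$session_duration))
  invisible(x)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)
}

is_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}
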