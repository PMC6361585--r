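#' Construct an event schedule
#'
#' An event schedule holds the timestamped stimulus events of a recording
#' session: one row per event with a label, onset time, and duration.  It
#' defines the trial structure for both phasic (sub-second) and sustained
#' (multi-minute) stimuli.
#'
#' @param label character vector of stimulus labels.  The standard vocabulary
#'   is `reward_cue`, `neutral_tone`, `shock_cue`, `footshock`, `siren`,
#'   `bright_light`, `licl`, `saline_ip`, `restraint`, `cocaine`,
#'   `saline_iv`, but any label is allowed.
#' @param onset numeric vector of event onset times in seconds,
#'   non-decreasing.
#' @param duration numeric vector (recycled) of event durations in seconds,
#'   all `>= 0`.
#' @return An object of class `event_schedule`: a data frame with columns
#'   `label`, `onset`, `duration`.
#' @examples
#' sched <- event_schedule(rep("reward_cue", 5), seq(10, 130, by = 30), 2)
#' @export
event_schedule <- function(label, onset, duration = 0) {
  stopifnot(is.character(label), is.numeric(onset))
  duration <- rep_len(as.numeric(duration), length(onset))
  if (length(label) != length(onset))
    stop("label and onset must have equal length")
  if (is.unsorted(onset)) stop("event onsets must be non-decreasing")
  if (any(duration < 0)) stop("event durations must be >= 0")
  out <- data.frame(label = label, onset = as.numeric(onset),
                    duration = duration, stringsAsFactors = FALSE)
  class(out) <- c("event_schedule", "data.frame")
  out
}

#' @export
print.event_schedule <- function(x, ...) {
  cat(sprintf("<event_schedule: %d events, %d labels, span %.1f-%.1f s>\n",
              nrow(x), length(unique(x$label)),
              if (nrow(x)) min(x$onset) else NA, if (nrow(x)) max(x$onset) else NA))
  invisible(x)
}

#' Events of one label
#'
#' @param schedule an [event_schedule()].
#' @param label stimulus label to select.
#' @return The matching rows of the schedule.
#' @export
schedule_events <- function(schedule, label) {
  schedule[schedule$label == label, , drop = FALSE]
}

#' Standard phasic recording session schedule
#'
#' Builds the default phasic session layout: a block of reward-cue trials
#' followed by interleaved phasic aversive and neutral stimuli, all at a
#' fixed inter-trial interval.
#'
#' @param n_reward number of reward-cue trials (default 50).
#' @param n_per_stimulus trials per interleaved stimulus (default 30).
#' @param stimuli labels of the interleaved stimuli.
#' @param iti inter-trial interval in seconds (default 30).
#' @param start onset of the first trial, seconds (default 60, leaving a
#'   pre-session baseline).
#' @param seed optional integer; when given, the interleaving order of the
#'   aversive/neutral block is randomized reproducibly, otherwise stimuli
#'   cycle deterministically.
#' @return An [event_schedule()].  Cue durations are 2 s, footshock 0.01 s,
#'   siren 1 s, bright light 2 s.
#' @export
phasic_schedule <- function(n_reward = 50, n_per_stimulus = 30,
                            stimuli = c("footshock", "siren", "bright_light",
                                        "neutral_tone"),
                            iti = 30, start = 60, seed = NULL) {
  durations <- c(reward_cue = 2, neutral_tone = 2, shock_cue = 2,
                 footshock = 0.01, siren = 1, bright_light = 2)
  labs <- rep(stimuli, each = n_per_stimulus)
  if (!is.null(seed)) {
    labs <- with_seed(seed, sample(labs))
  } else {
    labs <- rep(stimuli, length.out = length(labs))
  }
  all_labs <- c(rep("reward_cue", n_reward), labs)
  onsets <- start + iti * (seq_along(all_labs) - 1)
  dur <- unname(durations[all_labs])
  dur[is.na(dur)] <- 1
  event_schedule(all_labs, onsets, dur)
}

#' Sustained-stimulus session schedule
#'
#' One sustained stimulus (LiCl, restraint, cocaine, or a saline control)
#' delivered after a pre-stimulus baseline.
#'
#' @param stimulus stimulus label, e.g. `"licl"`.
#' @param baseline_min minutes of pre-stimulus baseline (default 15).
#' @param duration_min nominal stimulus duration in minutes (default 30,
#'   covering both response phases).
#' @return An [event_schedule()] with a single event at
#'   `baseline_min * 60` seconds.
#' @export
sustained_schedule <- function(stimulus = "licl", baseline_min = 15,
                               duration_min = 30) {
  event_schedule(stimulus, baseline_min * 60, duration_min * 60)
}
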