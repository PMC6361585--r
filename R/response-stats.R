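# per-trial mean rates over the bins fully inside a window
window_trial_rates <- function(m, window) {
  left <- m$bin_edges[-length(m$bin_edges)]
  right <- m$bin_edges[-1]
  sel <- left >= window[1] - 1e-9 & right <= window[2] + 1e-9
  if (!any(sel)) stop("window [", window[1], ", ", window[2],
                      "] contains no whole bin")
  cnt <- rowSums(m$counts[, sel, drop = FALSE])
  eff <- rowSums(m$eff_width[, sel, drop = FALSE])
  rate <- cnt / eff
  rate[!is.finite(rate)] <- 0
  rate
}

#' Per-neuron response-window significance test
#'
#' The core per-neuron test: per-trial mean firing rate in the response
#' window is paired with per-trial mean rate in the pre-stimulus baseline
#' window and compared with a two-sided Wilcoxon signed-rank test.  A unit
#' is responsive at `p < alpha`; the response direction and magnitude are
#' taken from the window-mean baseline-normalized rate, so the reported
#' sign and direction always agree.
#'
#' By default the paired baseline segment has the same duration as the
#' response window, ending at stimulus onset (falling back to the whole
#' pre-onset baseline when the response window is longer).  Equal-duration
#' pairing keeps the signed-rank test exactly calibrated: with unequal
#' windows the null paired difference of Poisson rates is skewed, which
#' violates the test's symmetry assumption and inflates false positives.
#' The normalization used for the reported magnitude still spans the full
#' pre-onset baseline.
#'
#' @param matrix a [align_and_bin()] trial matrix with at least 6 trials
#'   (the signed-rank minimum for an attainable `p < 0.05`).
#' @param response_window numeric length-2 window in seconds post-onset.
#' @param baseline_window baseline window for the paired test (default:
#'   matched-duration segment ending at onset, as above).
#' @param alpha significance level (default 0.05).
#' @param sd_floor,method passed to [normalize_psth()].
#' @return An object of class `response_profile`: a one-row data frame
#'   with `unit_id`, `stimulus`, `win_start`, `win_end`, `direction`
#'   (`"excited"`, `"inhibited"`, or `"none"`), `p_value`, `magnitude`
#'   (mean normalized rate in the window), and `latency` (seconds; `NA`
#'   for non-responsive units).
#' @export
window_response_test <- function(matrix, response_window,
                                 baseline_window = NULL, alpha = 0.05,
                                 sd_floor = 0.1, method = "zscore") {
  m <- matrix
  if (nrow(m$counts) < 6)
    stop("need at least 6 trials for the signed-rank test")
  if (is.null(baseline_window)) {
    bdur <- min(diff(response_window), -m$window[1])
    baseline_window <- c(-bdur, 0)
  }
  resp <- window_trial_rates(m, response_window)
  base <- window_trial_rates(m, baseline_window)
  d <- resp - base
  p <- if (all(d == 0)) 1 else
    suppressWarnings(stats::wilcox.test(resp, base, paired = TRUE,
                                        exact = FALSE)$p.value)
  psth <- normalize_psth(m, baseline_window, method = method,
                         sd_floor = sd_floor)
  sel <- psth$bin_left >= response_window[1] - 1e-9 &
    psth$bin_left < response_window[2] - 1e-9
  magnitude <- mean(psth$normalized_rate[sel])
  direction <- "none"
  if (is.finite(p) && p < alpha && magnitude != 0)
    direction <- if (magnitude > 0) "excited" else "inhibited"
  latency <- NA_real_
  if (direction != "none")
    latency <- latency_to_extreme(psth, response_window,
                                  direction)$latency
  out <- data.frame(unit_id = m$unit_id, stimulus = m$stimulus,
                    win_start = response_window[1],
                    win_end = response_window[2],
                    direction = direction, p_value = p,
                    magnitude = magnitude, latency = latency,
                    stringsAsFactors = FALSE)
  class(out) <- c("response_profile", "data.frame")
  out
}

#' Standard analysis windows
#'
#' The stimulus-specific response windows used throughout: reward cue
#' 200-400 ms; phasic aversive and neutral stimuli 0-100 ms; putative-DA
#' classification 0-200 ms; ramping classification 200-2000 ms; pDA
#' aversive inhibition 100-500 ms.
#'
#' @return Named list of numeric length-2 windows (seconds).
#' @export
default_windows <- function() {
  list(reward_cue = c(0.2, 0.4), aversive = c(0, 0.1),
       neutral_tone = c(0, 0.1), pda = c(0, 0.2), ramping = c(0.2, 2),
       pda_inhibition = c(0.1, 0.5), pda_early = c(0, 0.1))
}

#' Sustained-stimulus phase windows
#'
#' Initial and rebound phase windows in minutes post-onset for each
#' sustained stimulus: LiCl 0-10 / 20-30, restraint 0-3 / 9-12, cocaine
#' 0-10 / 20-30 (saline controls inherit the windows of the stimulus they
#' control for).
#'
#' @return Named list; each element has `initial` and `rebound`
#'   length-2 windows in minutes.
#' @export
sustained_windows <- function() {
  list(licl = list(initial = c(0, 10), rebound = c(20, 30)),
       restraint = list(initial = c(0, 3), rebound = c(9, 12)),
       cocaine = list(initial = c(0, 10), rebound = c(20, 30)),
       saline_ip = list(initial = c(0, 10), rebound = c(20, 30)),
       saline_iv = list(initial = c(0, 10), rebound = c(20, 30)))
}

#' Classify an RMTg response profile
#'
#' Combines per-stimulus response profiles into the categorical labels
#' used for RMTg population tables, including the valence-encoding flag:
#' inhibition by the reward cue (200-400 ms window) combined with
#' excitation by footshock (0-100 ms window).
#'
#' @param profiles named list of [window_response_test()] results keyed by
#'   stimulus; must include `reward_cue` and `footshock`.
#' @return A list with `valence_encoding` (logical), `tally` (data frame
#'   `stimulus`, `direction`), and `reason` (`NA` or why the label was
#'   withheld).
#' @export
classify_rmtg_profile <- function(profiles) {
  need <- c("reward_cue", "footshock")
  missing <- setdiff(need, names(profiles))
  if (length(missing))
    return(list(valence_encoding = NA,
                tally = NULL,
                reason = paste("missing stimulus:",
                               paste(missing, collapse = ", "))))
  tally <- data.frame(
    stimulus = names(profiles),
    direction = vapply(profiles, function(p) p$direction, ""),
    stringsAsFactors = FALSE, row.names = NULL)
  list(valence_encoding =
         profiles$reward_cue$direction == "inhibited" &&
         profiles$footshock$direction == "excited",
       tally = tally, reason = NA_character_)
}

#' Classify a VTA unit's cell type from its reward-cue response
#'
#' Putative dopamine (pDA) units show significant phasic excitation 0-200
#' ms after reward-cue onset; ramping (putative GABA) units show
#' significant sustained activation 200-2000 ms without the phasic
#' excitation; reward-inhibited units show significant inhibition 0-200
#' ms.  Precedence: pDA > ramping > reward_inhibited > unclassified.
#'
#' @param reward_matrix [align_and_bin()] matrix of reward-cue trials.
#' @param alpha significance level (default 0.05).
#' @param windows window list as [default_windows()].
#' @return A list with `label` (`"pda"`, `"ramping"`,
#'   `"reward_inhibited"`, or `"unclassified"`) and `evidence` (the two
#'   response profiles).
#' @export
classify_vta_cell_type <- function(reward_matrix, alpha = 0.05,
                                   windows = default_windows()) {
  early <- window_response_test(reward_matrix, windows$pda, alpha = alpha)
  late <- window_response_test(reward_matrix, windows$ramping,
                               alpha = alpha)
  label <- if (early$direction == "excited") "pda"
  else if (late$direction == "excited") "ramping"
  else if (early$direction == "inhibited") "reward_inhibited"
  else "unclassified"
  list(label = label, evidence = list(early = early, late = late))
}

#' Classify a pDA unit's aversive response type
#'
#' pDA responses to phasic aversive stimuli fall into immediate inhibition
#' (significant inhibition in the 100-500 ms window without early
#' excitation), delayed inhibition (a brief significant excitation in the
#' 0-100 ms window followed by the 100-500 ms inhibition), excitation only
#' (excitation without the inhibition), or none.
#'
#' @param aversive_matrix [align_and_bin()] matrix of one phasic aversive
#'   stimulus for a pDA-labeled unit.
#' @param alpha significance level (default 0.05).
#' @param early_window,inhibition_window defaults 0-100 ms and 100-500 ms.
#' @return A list with `type` and `evidence` (the two response profiles).
#' @export
classify_aversive_inhibition_type <- function(aversive_matrix,
                                              alpha = 0.05,
                                              early_window = c(0, 0.1),
                                              inhibition_window = c(0.1, 0.5)) {
  early <- window_response_test(aversive_matrix, early_window,
                                alpha = alpha)
  late <- window_response_test(aversive_matrix, inhibition_window,
                               alpha = alpha)
  early_exc <- early$direction == "excited"
  late_inh <- late$direction == "inhibited"
  type <- if (early_exc && late_inh) "delayed_inhibition"
  else if (late_inh) "immediate_inhibition"
  else if (early_exc || late$direction == "excited") "excitation_only"
  else "none"
  list(type = type, evidence = list(early = early, late = late))
}

#' Classify a sustained-stimulus response
#'
#' Per-neuron test of the two response phases of a sustained (multi-minute)
#' stimulus: per-minute firing rates within each phase window are compared
#' with the per-minute rates of the 15 min pre-stimulus baseline by a
#' two-sided rank-sum test (there is no trial structure at this
#' timescale).  A unit is biphasic when both phases are significant.
#'
#' @param train a [spike_train()].
#' @param schedule an [event_schedule()] containing one event of
#'   `stimulus`.
#' @param stimulus sustained stimulus label.
#' @param windows list with `initial` and `rebound` windows in minutes
#'   post-onset; default looked up in [sustained_windows()].
#' @param baseline_min minutes of pre-stimulus baseline (default 15;
#'   required to be available before the onset).
#' @param alpha significance level (default 0.05).
#' @return An object of class `sustained_response`: list with `unit_id`,
#'   `stimulus`, `initial` and `rebound` (each `window`, `direction`,
#'   `p`, or `available = FALSE` when the window exceeds the recording),
#'   and `pattern` (`"biphasic"`, `"initial_only"`, `"rebound_only"`, or
#'   `"none"`).
#' @export
classify_sustained_response <- function(train, schedule, stimulus,
                                        windows = NULL, baseline_min = 15,
                                        alpha = 0.05) {
  if (is.null(windows)) {
    windows <- sustained_windows()[[stimulus]]
    if (is.null(windows))
      stop("no default phase windows for stimulus '", stimulus, "'")
  }
  ev <- schedule_events(schedule, stimulus)
  if (!nrow(ev)) stop("no event with label '", stimulus, "'")
  onset <- ev$onset[1]
  if (onset - baseline_min * 60 < train$session_span[1] - 1e-9)
    stop("session lacks the ", baseline_min, " min pre-stimulus baseline")

  minute_rates <- function(from_min, to_min) {
    t0 <- onset + 60 * from_min
    t1 <- onset + 60 * to_min
    if (t1 > train$session_span[2] + 1e-9) return(NULL)
    nb <- to_min - from_min
    lo <- findInterval(t0 - 1e-12, train$times) + 1L
    hi <- findInterval(t1 - 1e-12, train$times)
    if (hi < lo) return(rep(0, nb))
    tt <- train$times[lo:hi]
    tabulate(pmin(nb, floor((tt - t0) / 60) + 1L), nbins = nb) / 60
  }
  base <- minute_rates(-baseline_min, 0)
  phase_test <- function(w) {
    ph <- minute_rates(w[1], w[2])
    if (is.null(ph))
      return(list(window = w, direction = NA_character_, p = NA_real_,
                  available = FALSE))
    p <- if (all(ph == ph[1]) && all(base == ph[1])) 1 else
      suppressWarnings(stats::wilcox.test(ph, base,
                                          exact = FALSE)$p.value)
    dirn <- "none"
    if (is.finite(p) && p < alpha && mean(ph) != mean(base))
      dirn <- if (mean(ph) > mean(base)) "excited" else "inhibited"
    list(window = w, direction = dirn, p = p, available = TRUE)
  }
  initial <- phase_test(windows$initial)
  rebound <- phase_test(windows$rebound)
  sig <- function(ph) isTRUE(ph$available) && !is.na(ph$direction) &&
    ph$direction != "none"
  pattern <- if (sig(initial) && sig(rebound)) "biphasic"
  else if (sig(initial)) "initial_only"
  else if (sig(rebound)) "rebound_only"
  else "none"
  structure(list(unit_id = train$unit_id, stimulus = stimulus,
                 initial = initial, rebound = rebound, pattern = pattern),
            class = "sustained_response")
}
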