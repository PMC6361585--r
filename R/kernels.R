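#' Stimulus response kernel
#'
#' A multiplicative rate kernel tied to one stimulus label.  While a kernel
#' phase is active the unit's firing rate is multiplied by `gain`
#' (`gain > 1` excitation, `gain < 1` inhibition, `gain = 0` full
#' suppression).  An optional second phase expresses biphasic/opponent
#' responses (e.g. initial excitation followed by rebound inhibition).
#'
#' @param stimulus event label the kernel is locked to.
#' @param latency seconds from event onset to phase start, `>= 0`.
#' @param duration phase duration in seconds, `> 0`.
#' @param gain multiplicative rate factor, finite and `>= 0`.
#' @param second_latency,second_duration,second_gain optional second phase;
#'   the two phases must not overlap in time.
#' @return An object of class `response_kernel`.
#' @examples
#' # brief shock excitation with a delayed rebound inhibition
#' response_kernel("footshock", 0, 0.08, 3,
#'                 second_latency = 0.1, second_duration = 0.4,
#'                 second_gain = 0.2)
#' @export
response_kernel <- function(stimulus, latency, duration, gain,
                            second_latency = NULL, second_duration = NULL,
                            second_gain = NULL) {
  stopifnot(is.character(stimulus), length(stimulus) == 1,
            latency >= 0, duration > 0, is.finite(gain), gain >= 0)
  second <- NULL
  if (!is.null(second_latency)) {
    stopifnot(!is.null(second_duration), !is.null(second_gain),
              second_latency >= 0, second_duration > 0,
              is.finite(second_gain), second_gain >= 0)
    # phases must not overlap
    if (second_latency < latency + duration &&
        latency < second_latency + second_duration)
      stop("kernel phases overlap in time")
    second <- list(latency = second_latency, duration = second_duration,
                   gain = second_gain)
  }
  structure(list(stimulus = stimulus, latency = latency, duration = duration,
                 gain = gain, second = second),
            class = "response_kernel")
}

#' Unit generator configuration
#'
#' Full generative description of one synthetic unit: baseline Poisson rate,
#' stimulus-locked multiplicative kernels, optional burst-cluster process,
#' and optional injectable quality defects.
#'
#' @param unit_id unit identifier (coerced to character).
#' @param baseline_rate baseline firing rate in Hz, `> 0`.
#' @param kernels list of [response_kernel()] objects.
#' @param burst optional list with `cluster_rate` (Hz, rate of burst-cluster
#'   centers), `spikes_per_cluster` (mean spikes per cluster, `>= 1`), and
#'   `within_isi` (mean within-cluster interspike interval, seconds).
#'   Clusters are added as a Neyman-Scott process on top of the
#'   kernel-modulated baseline.
#' @param defects optional list with any of `drift_slope` (Hz/min, linear
#'   drift of the baseline rate), `refractory_fraction` (fraction of spikes
#'   duplicated at +0.5 ms, in `[0, 1]`), `artifact_labels` (event labels at
#'   whose onsets an artifact spike is inserted 1 ms post-onset).
#' @param archetype optional archetype name recorded in ground truth (set
#'   automatically by [archetype_config()]).
#' @return An object of class `unit_gen_config`.
#' @export
unit_gen_config <- function(unit_id, baseline_rate, kernels = list(),
                            burst = NULL, defects = NULL,
                            archetype = "custom") {
  if (!is.numeric(baseline_rate) || baseline_rate <= 0)
    stop("baseline_rate must be > 0")
  stopifnot(all(vapply(kernels, inherits, TRUE, "response_kernel")))
  if (!is.null(defects)) {
    rf <- defects$refractory_fraction
    if (!is.null(rf) && (rf < 0 || rf > 1))
      stop("refractory_fraction must be in [0, 1]")
  }
  if (!is.null(burst)) {
    stopifnot(burst$cluster_rate >= 0, burst$spikes_per_cluster >= 1,
              burst$within_isi > 0)
  }
  structure(list(unit_id = as.character(unit_id),
                 baseline_rate = baseline_rate, kernels = kernels,
                 burst = burst, defects = defects, archetype = archetype),
            class = "unit_gen_config")
}

#' Reference unit archetypes
#'
#' Named generative archetypes used throughout validation, at the reference
#' effect sizes (10 Hz baseline, gain 3 excitation, gain 0.2 inhibition):
#'
#' * `none` - unmodulated baseline unit.
#' * `valence` - RMTg-like valence encoder: reward-cue inhibition in the
#'   200-400 ms window, fast (0-100 ms) excitation to footshock, siren, and
#'   bright light.
#' * `pda` - putative dopamine unit: reward-cue excitation 0-200 ms.
#' * `ramping` - VTA-GABA-like unit: ramping activation 200-2000 ms after
#'   the reward cue, no early phasic excitation.
#' * `reward_inhibited` - reward-cue inhibition 0-200 ms.
#' * `delayed_inhibition` - pDA unit whose aversive response is a brief
#'   0-80 ms excitation followed by 100-400 ms inhibition.
#' * `immediate_inhibition` - pDA unit with aversive inhibition 100-500 ms
#'   and no early excitation.
#' * `excitation_only` - pDA unit with aversive excitation only.
#' * `biphasic_sustained` - opponent response to a sustained stimulus:
#'   rate doubled 0-10 min post-onset, halved 20-30 min.
#'
#' @param archetype one of the names above.
#' @param unit_id unit identifier.
#' @param baseline_rate baseline rate in Hz (default 10).
#' @param gain_exc,gain_inh reference excitation / inhibition gains
#'   (defaults 3 and 0.2).
#' @param sustained_stimulus stimulus label for `biphasic_sustained`
#'   (default `"licl"`).
#' @return A [unit_gen_config()].
#' @export
archetype_config <- function(archetype = c("none", "valence", "pda",
                                           "ramping", "reward_inhibited",
                                           "delayed_inhibition",
                                           "immediate_inhibition",
                                           "excitation_only",
                                           "biphasic_sustained"),
                             unit_id = "u1", baseline_rate = 10,
                             gain_exc = 3, gain_inh = 0.2,
                             sustained_stimulus = "licl") {
  archetype <- match.arg(archetype)
  aversive_exc <- function(labels = c("footshock", "siren", "bright_light"))
    lapply(labels, response_kernel, latency = 0, duration = 0.1,
           gain = gain_exc)
  pda_reward <- response_kernel("reward_cue", 0, 0.2, gain_exc)
  kernels <- switch(
    archetype,
    none = list(),
    valence = c(list(response_kernel("reward_cue", 0.2, 0.2, gain_inh)),
                aversive_exc()),
    pda = list(pda_reward),
    ramping = list(response_kernel("reward_cue", 0.2, 0.6, 1.5),
                   response_kernel("reward_cue", 0.8, 0.6, 2),
                   response_kernel("reward_cue", 1.4, 0.6, 2.5)),
    reward_inhibited = list(response_kernel("reward_cue", 0, 0.2, gain_inh)),
    delayed_inhibition = c(list(pda_reward),
                           lapply(c("footshock", "siren", "bright_light"),
                                  response_kernel, latency = 0,
                                  duration = 0.08, gain = gain_exc,
                                  second_latency = 0.1,
                                  second_duration = 0.3,
                                  second_gain = gain_inh)),
    immediate_inhibition = c(list(pda_reward),
                             lapply(c("footshock", "siren", "bright_light"),
                                    response_kernel, latency = 0.1,
                                    duration = 0.4, gain = gain_inh)),
    excitation_only = c(list(pda_reward), aversive_exc()),
    biphasic_sustained = list(response_kernel(sustained_stimulus, 0, 600, 2,
                                              second_latency = 1200,
                                              second_duration = 600,
                                              second_gain = 0.5))
  )
  unit_gen_config(unit_id, baseline_rate, kernels, archetype = archetype)
}

# Planted per-stimulus category implied by a config's kernels:
# excited / inhibited / biphasic / none.
kernel_truth <- function(config) {
  ks <- config$kernels
  if (!length(ks)) return(data.frame(stimulus = character(),
                                     category = character()))
  labs <- unique(vapply(ks, `[[`, "", "stimulus"))
  cat <- vapply(labs, function(lb) {
    kk <- ks[vapply(ks, function(k) k$stimulus == lb, TRUE)]
    dirs <- unlist(lapply(kk, function(k) {
      d <- character()
      if (k$gain > 1) d <- c(d, "excited")
      if (k$gain < 1) d <- c(d, "inhibited")
      if (!is.null(k$second)) {
        if (k$second$gain > 1) d <- c(d, "excited")
        if (k$second$gain < 1) d <- c(d, "inhibited")
      }
      d
    }))
    if (all(c("excited", "inhibited") %in% dirs)) "biphasic"
    else if ("excited" %in% dirs) "excited"
    else if ("inhibited" %in% dirs) "inhibited"
    else "none"
  }, "")
  data.frame(stimulus = labs, category = unname(cat),
             stringsAsFactors = FALSE)
}
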