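# Simulation drivers shared by the calibration/recovery test blocks.

# Null phasic population: fraction of units called responsive per
# analysis window (reward-cue 200-400 ms, pDA 0-200 ms, ramping
# 200-2000 ms, aversive 0-100 ms, inhibition 100-500 ms).
phasic_null_fractions <- function(n_units = 200, n_trials = 50, seed = 1) {
  sched <- phasic_schedule(n_reward = n_trials, n_per_stimulus = n_trials,
                           stimuli = "footshock", iti = 30)
  len <- max(sched$onset) + 30
  pop <- generate_population(list(list(archetype = "none",
                                       count = n_units)),
                             sched, len, seed)
  res <- vapply(pop$trains, function(st) {
    mr <- align_and_bin(st, sched, "reward_cue", c(-1, 2), 0.05)
    ms <- align_and_bin(st, sched, "footshock", c(-1, 0.5), 0.05)
    c(reward_200_400 =
        window_response_test(mr, c(0.2, 0.4))$direction != "none",
      pda_0_200 =
        window_response_test(mr, c(0, 0.2))$direction != "none",
      ramping_200_2000 =
        window_response_test(mr, c(0.2, 2))$direction != "none",
      aversive_0_100 =
        window_response_test(ms, c(0, 0.1))$direction != "none",
      inhibition_100_500 =
        window_response_test(ms, c(0.1, 0.5))$direction != "none")
  }, logical(5))
  rowMeans(res)
}

# Null sustained population: fraction of units significant per phase.
sustained_null_fractions <- function(n_units = 200, seed = 2) {
  sched <- sustained_schedule("licl")
  pop <- generate_population(list(list(archetype = "none",
                                       count = n_units)),
                             sched, 2700, seed)
  res <- vapply(pop$trains, function(st) {
    out <- classify_sustained_response(st, sched, "licl")
    c(sustained_initial = out$initial$direction != "none",
      sustained_rebound = out$rebound$direction != "none")
  }, logical(2))
  rowMeans(res)
}

# Planted-archetype population at the reference effect sizes: per-unit
# sensitivity for each archetype plus the recovered valence proportion.
phasic_recovery <- function(seed = 3, n_trials = 50) {
  sched <- phasic_schedule(n_reward = n_trials, n_per_stimulus = n_trials,
                           stimuli = "footshock", iti = 30)
  len <- max(sched$onset) + 30
  pop <- generate_population(
    list(list(archetype = "valence", count = 40),
         list(archetype = "pda", count = 10),
         list(archetype = "ramping", count = 10),
         list(archetype = "delayed_inhibition", count = 10),
         list(archetype = "none", count = 30)),
    sched, len, seed)
  arch <- pop$truth$units$archetype
  val <- logical(length(pop$trains))
  ct <- character(length(pop$trains))
  ftype <- rep(NA_character_, length(pop$trains))
  for (i in seq_along(pop$trains)) {
    st <- pop$trains[[i]]
    mr <- align_and_bin(st, sched, "reward_cue", c(-1, 2), 0.05)
    ms <- align_and_bin(st, sched, "footshock", c(-1, 0.5), 0.05)
    profs <- list(reward_cue = window_response_test(mr, c(0.2, 0.4)),
                  footshock = window_response_test(ms, c(0, 0.1)))
    val[i] <- classify_rmtg_profile(profs)$valence_encoding
    ct[i] <- classify_vta_cell_type(mr)$label
    if (ct[i] == "pda")
      ftype[i] <- classify_aversive_inhibition_type(ms)$type
  }
  list(valence_sensitivity = mean(val[arch == "valence"]),
       pda_sensitivity = mean(ct[arch == "pda"] == "pda"),
       ramping_sensitivity = mean(ct[arch == "ramping"] == "ramping"),
       delayed_sensitivity =
         mean(ftype[arch == "delayed_inhibition"] == "delayed_inhibition",
              na.rm = FALSE),
       valence_proportion = mean(val),
       planted_proportion = mean(arch == "valence"))
}

sustained_recovery <- function(seed = 4, n_units = 30) {
  sched <- sustained_schedule("licl")
  pop <- generate_population(
    list(list(archetype = "biphasic_sustained", count = n_units)),
    sched, 2700, seed)
  mean(vapply(pop$trains, function(st)
    classify_sustained_response(st, sched, "licl")$pattern == "biphasic",
    TRUE))
}

# Sham-style vs lesion-style VTA populations: classify every unit, then
# tabulate aversive-inhibited pDA proportions and reward-activated
# proportions per group.
lesion_contrast_run <- function(seed = 5, n_trials = 50) {
  sched <- phasic_schedule(n_reward = n_trials, n_per_stimulus = n_trials,
                           stimuli = "footshock", iti = 30)
  len <- max(sched$onset) + 30
  classify_group <- function(spec, seed) {
    pop <- generate_population(spec, sched, len, seed)
    t(vapply(pop$trains, function(st) {
      mr <- align_and_bin(st, sched, "reward_cue", c(-1, 2), 0.05)
      ms <- align_and_bin(st, sched, "footshock", c(-1, 0.5), 0.05)
      lab <- classify_vta_cell_type(mr)$label
      ftype <- if (lab == "pda")
        classify_aversive_inhibition_type(ms)$type else NA_character_
      c(pda = lab == "pda",
        inhibited = isTRUE(ftype %in% c("immediate_inhibition",
                                        "delayed_inhibition")))
    }, logical(2)))
  }
  sham <- classify_group(
    list(list(archetype = "delayed_inhibition", count = 25),
         list(archetype = "excitation_only", count = 15),
         list(archetype = "none", count = 10)), seed)
  # lesion: inhibition kernels removed, early excitation amplified
  lesion <- classify_group(
    list(list(archetype = "excitation_only", count = 25, gain_exc = 4.5),
         list(archetype = "excitation_only", count = 15),
         list(archetype = "none", count = 10)), seed + 1L)
  inhib_tab <- rbind(
    sham = c(sum(sham[sham[, "pda"], "inhibited"]),
             sum(!sham[sham[, "pda"], "inhibited"])),
    lesion = c(sum(lesion[lesion[, "pda"], "inhibited"]),
               sum(!lesion[lesion[, "pda"], "inhibited"])))
  reward_tab <- rbind(sham = c(sum(sham[, "pda"]), sum(!sham[, "pda"])),
                      lesion = c(sum(lesion[, "pda"]),
                                 sum(!lesion[, "pda"])))
  list(inhibited = compare_proportions(inhib_tab),
       reward = compare_proportions(reward_tab),
       inhibited_prop = inhib_tab[, 1] / rowSums(inhib_tab),
       reward_prop = reward_tab[, 1] / rowSums(reward_tab))
}
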