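phasic_sc <- function(label = "reward_cue", n = 50, iti = 5, start = 10,
                      dur = 2)
  event_schedule(rep(label, n), start + iti * (0:(n - 1)), dur)

bin_mat <- function(cfg, sc, label, seed, post = 0.5) {
  st <- generate_spike_train(cfg, sc, max(sc$onset) + 5, seed = seed)
  align_and_bin(st, sc, label, c(-1, post), 0.05)
}

test_that("identical response and baseline windows give p = 1", {
  sc <- phasic_sc()
  m <- bin_mat(unit_gen_config("u", 10), sc, "reward_cue", 1)
  pr <- window_response_test(m, c(-0.5, 0), baseline_window = c(-0.5, 0))
  expect_equal(pr$p_value, 1)
  expect_equal(pr$direction, "none")
  expect_true(is.na(pr$latency))
})

test_that("planted kernels are detected with the right direction and sign", {
  sc <- phasic_sc()
  exc <- unit_gen_config("u", 10,
                         list(response_kernel("reward_cue", 0, 0.1, 3)))
  inh <- unit_gen_config("u", 10,
                         list(response_kernel("reward_cue", 0.2, 0.2, 0.2)))
  n_exc <- 0; n_inh <- 0
  for (s in 1:20) {
    pe <- window_response_test(bin_mat(exc, sc, "reward_cue", s),
                               c(0, 0.1))
    pi <- window_response_test(bin_mat(inh, sc, "reward_cue", 100 + s),
                               c(0.2, 0.4))
    n_exc <- n_exc + (pe$direction == "excited")
    n_inh <- n_inh + (pi$direction == "inhibited")
    # sign(magnitude) agrees with direction whenever responsive
    for (p in list(pe, pi)) if (p$direction != "none")
      expect_equal(sign(p$magnitude),
                   if (p$direction == "excited") 1 else -1)
  }
  expect_gte(n_exc, 19)
  expect_gte(n_inh, 19)
})

test_that("latency recovers the planted kernel onset at high gain", {
  sc <- phasic_sc()
  # a single-bin kernel gives a unique peak bin, so the first-attainment
  # rule pins the planted onset exactly
  cfg <- unit_gen_config("u", 10,
                         list(response_kernel("reward_cue", 0.10, 0.05, 30)))
  hits <- vapply(1:20, function(s) {
    pr <- window_response_test(bin_mat(cfg, sc, "reward_cue", s),
                               c(0, 0.4))
    pr$latency
  }, 0)
  expect_gte(mean(abs(hits - 0.10) < 1e-9), 0.9)
})

test_that("valence-encoding label needs both reward inhibition and shock excitation", {
  sc <- phasic_schedule(n_reward = 50, n_per_stimulus = 50,
                        stimuli = "footshock", iti = 5, start = 10)
  len <- max(sc$onset) + 5
  mk_profiles <- function(cfg, seed) {
    st <- generate_spike_train(cfg, sc, len, seed = seed)
    profs <- list(
      reward_cue = window_response_test(
        align_and_bin(st, sc, "reward_cue", c(-1, 0.5), 0.05),
        c(0.2, 0.4)),
      footshock = window_response_test(
        align_and_bin(st, sc, "footshock", c(-1, 0.5), 0.05),
        c(0, 0.1)))
    profs
  }
  val <- classify_rmtg_profile(mk_profiles(archetype_config("valence"), 1))
  expect_true(val$valence_encoding)
  non <- classify_rmtg_profile(mk_profiles(archetype_config("none"), 2))
  expect_false(non$valence_encoding)
  expect_true(all(c("reward_cue", "footshock") %in% non$tally$stimulus))
  # missing stimulus: label withheld with a reason
  held <- classify_rmtg_profile(mk_profiles(archetype_config("none"),
                                            3)["reward_cue"])
  expect_true(is.na(held$valence_encoding))
  expect_match(held$reason, "footshock")
})

test_that("VTA cell typing recovers planted archetypes with precedence", {
  sc <- phasic_sc()
  for (case in list(c("pda", "pda"), c("ramping", "ramping"),
                    c("reward_inhibited", "reward_inhibited"))) {
    cfg <- archetype_config(case[1])
    hits <- vapply(1:10, function(s)
      classify_vta_cell_type(bin_mat(cfg, sc, "reward_cue", s,
                                     post = 2))$label, "")
    expect_gte(mean(hits == case[2]), 0.9)
  }
  # a unit significant in both the 0-200 early and 200-2000 late windows
  # is pDA by precedence
  both <- unit_gen_config("u", 10,
                          list(response_kernel("reward_cue", 0, 0.2, 3),
                               response_kernel("reward_cue", 0.2, 1.8, 3)))
  lab <- classify_vta_cell_type(bin_mat(both, sc, "reward_cue", 5,
                                        post = 2))
  expect_equal(lab$label, "pda")
  expect_equal(lab$evidence$late$direction, "excited")
})

test_that("aversive inhibition typing separates immediate from delayed", {
  sc <- phasic_sc("footshock", dur = 0.01)
  del <- unit_gen_config("u", 10,
                         list(response_kernel("footshock", 0, 0.08, 3,
                                              second_latency = 0.1,
                                              second_duration = 0.3,
                                              second_gain = 0.2)))
  imm <- unit_gen_config("u", 10,
                         list(response_kernel("footshock", 0.1, 0.4, 0.2)))
  del_hits <- vapply(1:10, function(s) classify_aversive_inhibition_type(
    bin_mat(del, sc, "footshock", s))$type, "")
  # immediate units carry a ~5% chance of a spurious early excitation, so
  # allow one "delayed" call in ten
  imm_hits <- vapply(1:10, function(s) classify_aversive_inhibition_type(
    bin_mat(imm, sc, "footshock", 50 + s))$type, "")
  expect_true(all(del_hits == "delayed_inhibition"))
  expect_gte(mean(imm_hits == "immediate_inhibition"), 0.9)
  exc <- unit_gen_config("u", 10,
                         list(response_kernel("footshock", 0, 0.1, 4)))
  expect_equal(classify_aversive_inhibition_type(
    bin_mat(exc, sc, "footshock", 3))$type, "excitation_only")
})

test_that("sustained responses classify by phase significance", {
  sc <- sustained_schedule("licl")
  bi <- archetype_config("biphasic_sustained")
  hits <- vapply(1:10, function(s) {
    st <- generate_spike_train(bi, sc, 2700, seed = s)
    classify_sustained_response(st, sc, "licl")$pattern
  }, "")
  expect_true(all(hits == "biphasic"))

  # phase window beyond the recording is marked unavailable
  st <- generate_spike_train(bi, sc, 1500, seed = 1)
  out <- classify_sustained_response(st, sc, "licl")
  expect_false(out$rebound$available)
  expect_true(out$pattern %in% c("initial_only", "none"))

  # missing pre-stimulus baseline is an error
  sc_short <- sustained_schedule("licl", baseline_min = 5)
  st2 <- generate_spike_train(bi, sc_short, 2100, seed = 2)
  expect_error(classify_sustained_response(st2, sc_short, "licl"),
               "baseline")
})

test_that("reward and aversive windows touch disjoint data per trial", {
  # spikes planted only inside 0-100 ms leave the 200-400 ms analysis
  # untouched, and vice versa
  sc <- phasic_sc("footshock", n = 10, dur = 0.01)
  early_spikes <- sort(unlist(lapply(sc$onset, function(o) o + c(0.02, 0.05))))
  late_spikes <- sort(unlist(lapply(sc$onset, function(o) o + c(0.25, 0.35))))
  st_e <- spike_train("u", early_spikes, c(0, max(sc$onset) + 5))
  st_l <- spike_train("u", late_spikes, c(0, max(sc$onset) + 5))
  m_e <- align_and_bin(st_e, sc, "footshock", c(-1, 0.5), 0.05)
  m_l <- align_and_bin(st_l, sc, "footshock", c(-1, 0.5), 0.05)
  expect_equal(sum(valencephys:::window_trial_rates(m_e, c(0.2, 0.4))), 0)
  expect_equal(sum(valencephys:::window_trial_rates(m_l, c(0, 0.1))), 0)
})
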