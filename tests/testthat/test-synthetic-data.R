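sched1 <- event_schedule("reward_cue", 10, 2)

test_that("identical seeds reproduce identical outputs", {
  cfg <- archetype_config("valence")
  sc <- phasic_schedule(n_reward = 10, n_per_stimulus = 5, iti = 5)
  a <- generate_spike_train(cfg, sc, 400, seed = 42)
  b <- generate_spike_train(cfg, sc, 400, seed = 42)
  expect_identical(a$times, b$times)
  pa <- generate_population(list(list(archetype = "valence", count = 3)),
                            sc, 400, seed = 7)
  pb <- generate_population(list(list(archetype = "valence", count = 3)),
                            sc, 400, seed = 7)
  expect_identical(lapply(pa$trains, `[[`, "times"),
                   lapply(pb$trains, `[[`, "times"))
  s1 <- generate_cpp_session(0.3, seed = 5)
  s2 <- generate_cpp_session(0.3, seed = 5)
  expect_identical(s1$occupancy, s2$occupancy)
})

test_that("baseline spike counts match the configured Poisson rate", {
  cfg <- unit_gen_config("u", 10)
  counts <- vapply(1:100, function(s)
    length(generate_spike_train(cfg, sched1, 100, seed = s)$times), 0)
  # mean of 100 seeds within the 99% band around rate x duration = 1000
  se <- sqrt(1000 / 100)
  expect_lt(abs(mean(counts) - 1000), 2.58 * se)
})

test_that("kernel gains shape the local rate as configured", {
  onsets <- seq(10, 10 + 49 * 5, by = 5)
  sc <- event_schedule(rep("footshock", 50), onsets, 0.01)
  # full suppression: zero spikes in all 50 windows
  cfg0 <- unit_gen_config("u", 10,
                          list(response_kernel("footshock", 0, 1, 0)))
  st0 <- generate_spike_train(cfg0, sc, 300, seed = 2)
  inwin <- vapply(onsets, function(o)
    sum(st0$times >= o & st0$times < o + 1), 0)
  expect_equal(sum(inwin), 0)
  # gain 3 on a 10 Hz baseline: empirical window rate within 3 SE of 30 Hz
  cfg3 <- unit_gen_config("u", 10,
                          list(response_kernel("footshock", 0.01, 0.1, 3)))
  cnt <- unlist(lapply(1:20, function(s) {
    st <- generate_spike_train(cfg3, sc, 300, seed = s)
    vapply(onsets, function(o)
      sum(st$times >= o + 0.01 & st$times < o + 0.11), 0)
  }))
  rate <- mean(cnt) / 0.1
  se <- sqrt(mean(cnt) / length(cnt)) / 0.1
  expect_lt(abs(rate - 30), 3 * se)
})

test_that("rate conservation holds across windows for defect-free trains", {
  cfg <- unit_gen_config("u", 8,
                         list(response_kernel("reward_cue", 0, 2, 2)))
  sc <- event_schedule(rep("reward_cue", 20), seq(10, 105, by = 5), 2)
  pooled_in <- 0; pooled_out <- 0
  for (s in 1:100) {
    st <- generate_spike_train(cfg, sc, 120, seed = s)
    pooled_in <- pooled_in + sum(vapply(sc$onset, function(o)
      sum(st$times >= o & st$times < o + 2), 0))
    pooled_out <- pooled_out + sum(st$times >= 110 & st$times < 120)
  }
  # kernel windows: 16 Hz over 40 s x 100 seeds; tail: 8 Hz over 10 s
  expect_lt(abs(pooled_in / 100 / 40 - 16), 3 * sqrt(16 / (40 * 100)))
  expect_lt(abs(pooled_out / 100 / 10 - 8), 3 * sqrt(8 / (10 * 100)))
})

test_that("population ground truth echoes the spec exactly", {
  sc <- phasic_schedule(n_reward = 6, n_per_stimulus = 6, iti = 2,
                        start = 5)
  pop <- generate_population(list(list(archetype = "valence", count = 40),
                                  list(archetype = "none", count = 60)),
                             sc, 700, seed = 1)
  expect_equal(length(pop$trains), 100)
  expect_equal(sum(pop$truth$units$valence_encoding), 40)
  expect_equal(anyDuplicated(pop$truth$units$unit_id), 0)
  # every unit has exactly one truth record
  expect_equal(nrow(pop$truth$units), 100)

  # biphasic sustained kernels are marked biphasic for that stimulus
  sc2 <- sustained_schedule("licl")
  pop2 <- generate_population(
    list(list(archetype = "biphasic_sustained", count = 2)),
    sc2, 2700, seed = 2)
  cats <- pop2$truth$categories
  expect_true(all(cats$category[cats$stimulus == "licl"] == "biphasic"))

  # empty spec: empty population, empty truth
  pop0 <- generate_population(list(), sc, 700, seed = 3)
  expect_equal(length(pop0$trains), 0)
  expect_equal(nrow(pop0$truth$units), 0)
})

test_that("calcium traces are kernel-convolved spikes plus noise", {
  # one spike, no noise: peak at the kernel maximum after the spike
  tr <- spikes_to_calcium(2, 10, frame_rate = 20)
  expect_equal(sum(tr[1:40]), 0)
  kern_peak_frame <- which.max(spikes_to_calcium(0, 5, frame_rate = 20))
  expect_equal(which.max(tr), 40 + kern_peak_frame)
  expect_equal(max(tr), 1)  # peak-normalized kernel
  # no spikes, no noise: identically zero
  expect_equal(spikes_to_calcium(numeric(), 10, 20), rep(0, 200))

  # generated traces: noiseless trace of a silent-ish unit is ~0
  sc <- event_schedule(rep("footshock", 30), seq(10, 10 + 29 * 30, 30),
                       0.01)
  gen <- generate_calcium_traces(
    list(list(archetype = "none", count = 1, baseline_rate = 1e-6)),
    sc, 900, frame_rate = 20, noise_sd = 0, seed = 4)
  expect_equal(gen$traces[[1]]$dF_F, rep(0, 18000))
  expect_error(generate_calcium_traces(list(list(archetype = "none",
                                                 count = 1)),
                                       sc, 900, noise_sd = -1),
               "noise_sd")
})

test_that("planted shock transients exceed baseline in trial averages", {
  sc <- event_schedule(rep("footshock", 30), seq(15, 15 + 29 * 30, 30),
                       0.01)
  gen <- generate_calcium_traces(
    list(list(archetype = "excitation_only", count = 1, gain_exc = 6)),
    sc, 920, frame_rate = 20, noise_sd = 0.05, seed = 5)
  tens <- extract_trials(downsample_trace(gen$traces[[1]], 4))
  tens <- normalize_and_smooth(tens)
  avg <- colMeans(tens$data)
  post <- mean(avg[tens$time >= 0 & tens$time < 2])
  base <- avg[tens$time < 0]
  expect_gt(post, mean(base) + 3 * stats::sd(base) / sqrt(sum(tens$time < 0)))
})

test_that("chamber-transition generator respects bias and partitioning", {
  # symmetric bias: entry counts equal within the binomial 99% band
  s <- generate_cpp_session(0.5, mean_dwell = 5, session_length = 20000,
                            seed = 1)
  ent <- session_summary(s, debounce = 0)$entries
  n <- ent[["paired"]] + ent[["unpaired"]]
  band <- binom_band(n, 0.5)
  expect_gt(ent[["paired"]] / n, band[1])
  expect_lt(ent[["paired"]] / n, band[2])

  # bias 0.2 recovered from entry fractions
  s2 <- generate_cpp_session(0.2, mean_dwell = 4, session_length = 30000,
                             seed = 2)
  e2 <- session_summary(s2, debounce = 0)$entries
  n2 <- e2[["paired"]] + e2[["unpaired"]]
  frac <- e2[["paired"]] / n2
  expect_lt(abs(frac - 0.2), 3 * sqrt(0.2 * 0.8 / n2))

  # occupancy intervals partition the session exactly
  occ <- s$occupancy
  expect_equal(sum(occ$end - occ$start), 20000)
  expect_equal(occ$start[-1], occ$end[-nrow(occ)])
  expect_error(generate_cpp_session(1.2), "bias_paired")
})
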