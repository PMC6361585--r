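# Independent oracles used to cross-check package implementations.

# Brute-force burst enumeration, structurally different from the package's
# left-to-right scan: split the train into segments at intervals > `cont`;
# within each segment a burst runs from the first sub-`open` pair to the
# segment's end.
burst_oracle <- function(times, open = 0.080, cont = 0.160) {
  n <- length(times)
  if (n < 2) return(data.frame(start = numeric(), end = numeric(),
                               n_spikes = integer()))
  isi <- diff(times)
  seg_id <- cumsum(c(1, as.integer(isi > cont)))
  out <- list()
  for (s in unique(seg_id)) {
    idx <- which(seg_id == s)
    if (length(idx) < 2) next
    sub_isi <- diff(times[idx])
    k <- which(sub_isi < open)
    if (!length(k)) next
    first <- idx[k[1]]
    last <- idx[length(idx)]
    out[[length(out) + 1]] <- data.frame(start = times[first],
                                         end = times[last],
                                         n_spikes = last - first + 1L)
  }
  if (!length(out)) return(data.frame(start = numeric(), end = numeric(),
                                      n_spikes = integer()))
  do.call(rbind, out)
}

# Binomial-resampling oracle for the 2 x 2 proportion contrast: resample
# both groups from the pooled proportion under the null and recompute the
# chi-square statistic.
resample_proportions_p <- function(counts, B = 2000) {
  stat <- function(tab) {
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    sum((tab - e)^2 / e)
  }
  obs <- stat(counts)
  n <- rowSums(counts)
  phat <- sum(counts[, 1]) / sum(counts)
  hits <- 0
  for (b in seq_len(B)) {
    a <- stats::rbinom(1, n[1], phat)
    d <- stats::rbinom(1, n[2], phat)
    tab <- rbind(c(a, n[1] - a), c(d, n[2] - d))
    if (any(colSums(tab) == 0)) next
    if (stat(tab) >= obs - 1e-12) hits <- hits + 1
  }
  hits / B
}

# central 99% band of Binomial(n, p), as a proportion
binom_band <- function(n, p = 0.05) {
  stats::qbinom(c(0.005, 0.995), n, p) / n
}

# quick homogeneous-Poisson train with a 1 ms dead time (matches the
# generator's clean-unit structure) for oracle fuzzing
random_train <- function(rate, length_s, seed) {
  cfg <- unit_gen_config("u", rate)
  sched <- event_schedule("reward_cue", 0, 0)
  generate_spike_train(cfg, sched, length_s, seed = seed)
}

# cluster-process train for burst-positive fuzzing
random_burst_train <- function(seed, rate = 5, length_s = 30) {
  cfg <- unit_gen_config("u", rate,
                         burst = list(cluster_rate = 0.5,
                                      spikes_per_cluster = 4,
                                      within_isi = 0.02))
  sched <- event_schedule("reward_cue", 0, 0)
  generate_spike_train(cfg, sched, length_s, seed = seed)
}
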