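#' Align spikes to events and bin
#'
#' Builds the trials-by-bins spike-count matrix for one stimulus: every
#' event of `label` contributes one row, spike times are taken relative to
#' event onset, and counted in half-open bins `[edge, edge + bin_width)`.
#' Time intervals blanked on the train (see [blank_shock_artifact()]) are
#' recorded as reduced effective bin durations, so downstream rates are
#' computed over effective time.
#'
#' The phasic convention is 50 ms bins over a window from -1 s (the 1 s
#' baseline) to the response period; the sustained convention reuses the
#' same operation with 5 min bins and a 15 min baseline.
#'
#' @param train a [spike_train()].
#' @param schedule an [event_schedule()].
#' @param label stimulus label to align to; at least one event required.
#' @param window numeric length-2 `(pre, post)` in seconds relative to
#'   onset, `pre < post` (e.g. `c(-1, 0.5)`).
#' @param bin_width bin width in seconds; must divide the window length.
#' @return An object of class `trial_matrix`: list with `unit_id`,
#'   `stimulus`, `bin_edges` (left edges plus final right edge), `counts`
#'   (trials x bins), `eff_width` (effective bin durations after
#'   blanking), `excluded_mask` (bins partially or fully blanked), and
#'   `bin_width`.
#' @export
align_and_bin <- function(train, schedule, label, window, bin_width) {
  stopifnot(length(window) == 2, window[1] < window[2], bin_width > 0)
  nb <- (window[2] - window[1]) / bin_width
  if (abs(nb - round(nb)) > 1e-8)
    stop("bin_width must divide the window length")
  nb <- as.integer(round(nb))
  ev <- schedule_events(schedule, label)
  if (!nrow(ev))
    stop("no events with label '", label, "' in schedule")
  edges <- window[1] + bin_width * (0:nb)
  nt <- nrow(ev)
  counts <- matrix(0L, nt, nb)
  eff <- matrix(bin_width, nt, nb)
  blk <- train$blanked
  times <- train$times
  for (t in seq_len(nt)) {
    on <- ev$onset[t]
    # binary search keeps per-trial cost logarithmic in train length
    lo <- findInterval(on + window[1] - 1e-12, times) + 1L
    hi <- findInterval(on + window[2] - 1e-12, times)
    rel <- if (hi >= lo) times[lo:hi] - on else numeric()
    if (length(rel)) {
      # epsilon keeps spikes landing exactly on a bin edge in the
      # right-hand (half-open) bin despite floating-point division
      idx <- floor((rel - window[1]) / bin_width + 1e-9) + 1L
      idx[idx > nb] <- nb
      counts[t, ] <- tabulate(idx, nbins = nb)
    }
    if (!is.null(blk) && nrow(blk)) {
      for (b in seq_len(nb)) {
        ov <- interval_overlap(on + edges[b], on + edges[b + 1], blk)
        if (ov > 0) eff[t, b] <- bin_width - ov
      }
    }
  }
  structure(list(unit_id = train$unit_id, stimulus = label,
                 bin_edges = edges, counts = counts, eff_width = eff,
                 excluded_mask = eff < bin_width, bin_width = bin_width,
                 window = window),
            class = "trial_matrix")
}

#' @export
print.trial_matrix <- function(x, ...) {
  cat(sprintf("<trial_matrix %s/%s: %d trials x %d bins of %g s>\n",
              x$unit_id, x$stimulus, nrow(x$counts), ncol(x$counts),
              x$bin_width))
  invisible(x)
}

#' Baseline-normalized PSTH
#'
#' Collapses a [align_and_bin()] matrix to a trial-averaged peri-stimulus
#' rate trace and normalizes it to the pre-stimulus baseline.  The default
#' dialect is a z-score: each bin's trial-mean rate minus the mean of the
#' baseline-bin rates, divided by their SD (floored at `sd_floor`).  A
#' fold-change dialect (`rate / baseline_mean`) is also provided.
#'
#' @param matrix a `trial_matrix`.
#' @param baseline_window numeric length-2 `(pre, 0)` within the matrix
#'   window; bins fully inside it form the baseline (default: everything
#'   before onset).
#' @param method `"zscore"` (default) or `"foldchange"`.
#' @param sd_floor lower bound on the baseline SD in Hz (default 0.1),
#'   keeping low-rate units stable.
#' @return An object of class `normalized_psth`: `bin_centers`,
#'   `normalized_rate`, `rate` (raw trial-mean Hz), `baseline_mean`,
#'   `baseline_sd` (Hz), `method`, and `flags` (`"zero_baseline"` when the
#'   baseline had no spikes).
#' @export
normalize_psth <- function(matrix, baseline_window = NULL,
                           method = c("zscore", "foldchange"),
                           sd_floor = 0.1) {
  method <- match.arg(method)
  m <- matrix
  if (is.null(baseline_window)) baseline_window <- c(m$window[1], 0)
  stopifnot(baseline_window[1] >= m$window[1] - 1e-9,
            baseline_window[2] <= m$window[2] + 1e-9)
  left <- m$bin_edges[-length(m$bin_edges)]
  right <- m$bin_edges[-1]
  base_bins <- left >= baseline_window[1] - 1e-9 &
    right <= baseline_window[2] + 1e-9
  if (!any(base_bins)) stop("baseline window contains no whole bin")
  # trial-mean rate per bin over effective (unblanked) time
  rate <- colSums(m$counts) / colSums(m$eff_width)
  rate[!is.finite(rate)] <- 0
  mu <- mean(rate[base_bins])
  sdev <- stats::sd(rate[base_bins])
  flags <- character()
  if (sum(m$counts[, base_bins]) == 0) flags <- c(flags, "zero_baseline")
  norm <- if (method == "zscore") {
    (rate - mu) / max(sdev, sd_floor, na.rm = TRUE)
  } else {
    rate / max(mu, sd_floor)
  }
  structure(list(unit_id = m$unit_id, stimulus = m$stimulus,
                 bin_centers = (left + right) / 2, bin_left = left,
                 normalized_rate = norm, rate = rate,
                 baseline_mean = mu, baseline_sd = sdev,
                 normalization_method = method, flags = flags),
            class = "normalized_psth")
}

#' Latency to peak or trough
#'
#' Response latency defined as the left edge of the first bin that attains
#' the window's extreme value: the maximum for excited units, the minimum
#' for inhibited units.  Ties are broken toward the earliest bin.
#'
#' @param psth a [normalize_psth()] result.
#' @param response_window numeric length-2 window in seconds; bins whose
#'   left edge lies in `[start, end)` are searched.
#' @param direction `"excited"` (peak) or `"inhibited"` (trough).
#' @return A list with `latency` (seconds, left bin edge) and `flag`
#'   (`"flat"` when the trace is constant over the window, in which case
#'   the first bin is returned).
#' @export
latency_to_extreme <- function(psth, response_window,
                               direction = c("excited", "inhibited")) {
  direction <- match.arg(direction)
  sel <- psth$bin_left >= response_window[1] - 1e-9 &
    psth$bin_left < response_window[2] - 1e-9
  if (!any(sel)) stop("response window contains no bin")
  v <- psth$normalized_rate[sel]
  left <- psth$bin_left[sel]
  flag <- if (max(v) == min(v)) "flat" else NA_character_
  target <- if (direction == "excited") max(v) else min(v)
  list(latency = left[which(v == target)[1]], flag = flag)
}

#' Population-average PSTH
#'
#' Pointwise mean and SEM across units' normalized PSTHs, as used for
#' population time-course figures.
#'
#' @param psths list of [normalize_psth()] results with identical bin
#'   structure.
#' @return A list with `bin_centers`, `mean`, `sem` (`NA` for a single
#'   unit), and `n`.
#' @export
population_average <- function(psths) {
  stopifnot(length(psths) >= 1)
  centers <- psths[[1]]$bin_centers
  for (p in psths)
    if (!isTRUE(all.equal(p$bin_centers, centers)))
      stop("mixed bin structures")
  vals <- do.call(rbind, lapply(psths, `[[`, "normalized_rate"))
  n <- nrow(vals)
  list(bin_centers = centers, mean = colMeans(vals),
       sem = if (n > 1) apply(vals, 2, stats::sd) / sqrt(n)
       else rep(NA_real_, ncol(vals)),
       n = n)
}
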