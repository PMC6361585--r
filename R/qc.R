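#' Refractory-period violation fraction
#'
#' Fraction of spikes whose preceding interspike interval is shorter than
#' the refractory bound (1 ms).  A unit passes the refractory rule when the
#' fraction is strictly below 0.002 (0.2% of spikes).
#'
#' @param train a [spike_train()].
#' @param refractory refractory bound in seconds (default 0.001); the
#'   violating interval is half-open `[0, refractory)`.
#' @return A list with `fraction`, `n_violations`, `n_spikes`, `pass`
#'   (strict `fraction < threshold`), and `flag` (`"too_few_spikes"` when
#'   the train has fewer than 2 spikes, else `NA`).
#' @param threshold acceptance threshold on the fraction (default 0.002).
#' @export
refractory_violation_fraction <- function(train, refractory = 0.001,
                                          threshold = 0.002) {
  n <- length(train$times)
  if (n < 2)
    return(list(fraction = 0, n_violations = 0L, n_spikes = n,
                pass = TRUE, flag = "too_few_spikes"))
  isi <- diff(train$times)
  nv <- sum(isi < refractory)
  frac <- nv / n
  list(fraction = frac, n_violations = nv, n_spikes = n,
       pass = frac < threshold, flag = NA_character_)
}

#' Detect firing-rate drift
#'
#' Rank-based trend test for slow drift of the baseline firing rate across
#' a session (or across sessions): Spearman correlation of per-window
#' baseline rate against window index, two-sided.  Units with a significant
#' trend are flagged for exclusion.
#'
#' @param train a [spike_train()].
#' @param baseline_windows 2-column matrix or data frame of `(start, end)`
#'   baseline windows in seconds; at least 2 required.  An empty window
#'   contributes a rate of 0.
#' @param alpha significance level (default 0.05).
#' @return A list with `statistic` (Spearman rho), `p`, `flag`
#'   (`p < alpha`), and `rates` (the per-window rates tested).
#' @export
detect_drift <- function(train, baseline_windows, alpha = 0.05) {
  w <- as.matrix(baseline_windows)
  if (nrow(w) < 2) stop("need at least 2 baseline windows")
  rates <- vapply(seq_len(nrow(w)), function(i) {
    sum(train$times >= w[i, 1] & train$times < w[i, 2]) /
      (w[i, 2] - w[i, 1])
  }, 0)
  if (stats::var(rates) == 0)
    return(list(statistic = 0, p = 1, flag = FALSE, rates = rates))
  ct <- suppressWarnings(
    stats::cor.test(rates, seq_along(rates), method = "spearman",
                    exact = FALSE))
  list(statistic = unname(ct$estimate), p = ct$p.value,
       flag = ct$p.value < alpha, rates = rates)
}

#' Blank shock artifacts
#'
#' Removes all spikes in the first 10 ms after each footshock onset
#' (`[onset, onset + blank)`), the period contaminated by the shock
#' artifact, and records the blanked intervals on the train so downstream
#' rate estimates treat them as excluded time.  Overlapping blank windows
#' are merged; the operation is idempotent.
#'
#' @param train a [spike_train()].
#' @param shock_onsets numeric vector of shock onset times in seconds.
#' @param blank blanked duration in seconds (default 0.010).
#' @return The blanked [spike_train()] with a `blanked` interval matrix.
#' @export
blank_shock_artifact <- function(train, shock_onsets, blank = 0.010) {
  if (!length(shock_onsets)) return(train)
  if (min(shock_onsets) < train$session_span[1] ||
      max(shock_onsets) > train$session_span[2])
    stop("shock onsets outside session span")
  iv <- cbind(as.numeric(shock_onsets), as.numeric(shock_onsets) + blank)
  iv <- merge_intervals(rbind(train$blanked, iv))
  dimnames(iv) <- NULL
  keep <- rep(TRUE, length(train$times))
  for (i in seq_len(nrow(iv)))
    keep <- keep & !(train$times >= iv[i, 1] & train$times < iv[i, 2])
  spike_train(train$unit_id, train$times[keep], train$session_span,
              train$session_id, blanked = iv)
}

#' Unit quality-control report
#'
#' Applies the acceptance rules used before any response analysis: the
#' refractory rule (violation fraction strictly below 0.2%) and the
#' firing-rate drift rule (no significant rank trend in per-window baseline
#' rates).
#'
#' @param train a [spike_train()].
#' @param baseline_windows baseline windows for [detect_drift()]; when
#'   `NULL`, the session is cut into `n_windows` equal windows.
#' @param n_windows number of automatic baseline windows (default 20).
#' @param refractory_threshold,alpha rule parameters (defaults 0.002, 0.05).
#' @return A one-row data frame: `unit_id`,
#'   `refractory_violation_fraction`, `drift_statistic`, `drift_p`,
#'   `accepted`, `reasons` (comma-separated failed rules, `""` if
#'   accepted).
#' @export
qc_unit <- function(train, baseline_windows = NULL, n_windows = 20,
                    refractory_threshold = 0.002, alpha = 0.05) {
  if (is.null(baseline_windows)) {
    edges <- seq(train$session_span[1], train$session_span[2],
                 length.out = n_windows + 1)
    baseline_windows <- cbind(edges[-length(edges)], edges[-1])
  }
  rv <- refractory_violation_fraction(train,
                                      threshold = refractory_threshold)
  dr <- detect_drift(train, baseline_windows, alpha = alpha)
  reasons <- c(if (!rv$pass) "refractory", if (dr$flag) "drift")
  data.frame(unit_id = train$unit_id,
             refractory_violation_fraction = rv$fraction,
             drift_statistic = dr$statistic, drift_p = dr$p,
             accepted = rv$pass && !dr$flag,
             reasons = paste(reasons, collapse = ","),
             stringsAsFactors = FALSE)
}
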