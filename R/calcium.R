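#' Extract trial windows from a calcium trace
#'
#' Cuts a dF/F trace into fixed-length trial windows centered on stimulus
#' onsets (the acquisition convention: the camera runs for a 20 s window
#' centered at cue or shock onset).  Onsets too close to the recording
#' edges are dropped and logged.
#'
#' @param trace a [calcium_trace()].
#' @param onsets stimulus onsets in seconds; defaults to the trace's
#'   `trial_onsets`.
#' @param window total window length in seconds, centered on onset
#'   (default 20).
#' @return An object of class `trial_tensor`: list with `cell_id`,
#'   `projection_target`, `data` (trials x timepoints), `time` (seconds
#'   relative to onset), `sample_rate`, and `dropped` (onsets discarded at
#'   the edges).
#' @export
extract_trials <- function(trace, onsets = NULL, window = 20) {
  if (is.null(onsets)) onsets <- trace$trial_onsets
  stopifnot(length(onsets) >= 1, window > 0)
  half <- window / 2
  fr <- trace$sample_rate
  n_per <- as.integer(round(window * fr))
  total_s <- length(trace$dF_F) / fr
  ok <- onsets - half >= 0 & onsets + half <= total_s
  dropped <- onsets[!ok]
  onsets <- onsets[ok]
  if (!length(onsets)) stop("all onsets too close to recording edges")
  data <- t(vapply(onsets, function(on) {
    i0 <- as.integer(round((on - half) * fr))
    trace$dF_F[i0 + seq_len(n_per)]
  }, numeric(n_per)))
  structure(list(cell_id = trace$cell_id,
                 projection_target = trace$projection_target,
                 data = data,
                 time = (seq_len(n_per) - 0.5) / fr - half,
                 sample_rate = fr, dropped = dropped),
            class = "trial_tensor")
}

#' Baseline-normalize and smooth a trial tensor
#'
#' Per trial, subtracts the mean of the pre-onset baseline segment, then
#' applies a centered moving average of the given width (0.6 s = 3 samples
#' at 5 Hz); the averaging window shrinks at the trial edges.
#'
#' @param tensor a [extract_trials()] tensor.
#' @param smooth_s moving-average width in seconds (default 0.6).
#' @param baseline_window length-2 window in seconds relative to onset
#'   defining the baseline segment (default: the whole pre-onset half).
#' @return The tensor with normalized, smoothed `data`.
#' @export
normalize_and_smooth <- function(tensor, smooth_s = 0.6,
                                 baseline_window = NULL) {
  if (is.null(baseline_window))
    baseline_window <- c(min(tensor$time), 0)
  base_idx <- tensor$time >= baseline_window[1] &
    tensor$time < baseline_window[2]
  if (!any(base_idx)) stop("baseline window contains no sample")
  x <- tensor$data - rowMeans(tensor$data[, base_idx, drop = FALSE])
  w <- max(1L, as.integer(round(smooth_s * tensor$sample_rate)))
  half <- (w - 1L) %/% 2L
  n <- ncol(x)
  sm <- x
  if (w > 1) {
    cs <- cbind(0, t(apply(x, 1, cumsum)))
    for (j in seq_len(n)) {
      a <- max(1L, j - half)
      b <- min(n, j + half)
      sm[, j] <- (cs[, b + 1] - cs[, a]) / (b - a + 1)
    }
  }
  tensor$data <- sm
  tensor$baseline_window <- baseline_window
  tensor
}

#' Per-cell trial response test
#'
#' Paired t-test of per-trial mean dF/F in the response window against the
#' per-trial baseline-window mean, two-sided; the cell is called
#' responsive at `p < alpha` with direction given by the sign of the mean
#' difference.
#'
#' @param tensor a trial tensor (normalized or raw); at least 5 trials.
#' @param response_window length-2 window in seconds post-onset (default
#'   0-2 s, the cue duration).
#' @param baseline_window baseline window (default: pre-onset half).
#' @param alpha significance level (default 0.05).
#' @return A list with `cell_id`, `direction`, `p`, `magnitude` (mean
#'   paired difference in dF/F), and `flag` (`"degenerate"` when the
#'   paired differences have zero variance, in which case `p` is `NA` and
#'   direction is taken from the sign alone).
#' @export
cell_response_test <- function(tensor, response_window = c(0, 2),
                               baseline_window = NULL, alpha = 0.05) {
  if (nrow(tensor$data) < 5) stop("need at least 5 trials")
  if (is.null(baseline_window))
    baseline_window <- c(min(tensor$time), 0)
  win_mean <- function(w) {
    idx <- tensor$time >= w[1] & tensor$time < w[2]
    if (!any(idx)) stop("window contains no sample")
    rowMeans(tensor$data[, idx, drop = FALSE])
  }
  d <- win_mean(response_window) - win_mean(baseline_window)
  if (all(d == 0))
    return(list(cell_id = tensor$cell_id, direction = "none", p = 1,
                magnitude = 0, flag = NA_character_))
  if (stats::var(d) == 0) {
    dirn <- if (mean(d) > 0) "excited" else if (mean(d) < 0) "inhibited"
    else "none"
    return(list(cell_id = tensor$cell_id, direction = dirn, p = NA_real_,
                magnitude = mean(d), flag = "degenerate"))
  }
  p <- stats::t.test(d)$p.value
  dirn <- "none"
  if (p < alpha && mean(d) != 0)
    dirn <- if (mean(d) > 0) "excited" else "inhibited"
  list(cell_id = tensor$cell_id, direction = dirn, p = p,
       magnitude = mean(d), flag = NA_character_)
}

#' Projection-target contrast
#'
#' Compares projection-defined populations (e.g. VTA- vs DRN-projecting
#' cells): per-group Pearson correlation between reward-cue and footshock
#' response magnitudes, and a chi-square contrast of the
#' reward-cue-inhibited proportions.
#'
#' @param group_a,group_b data frames with one row per cell and columns
#'   `reward_magnitude`, `shock_magnitude`, `reward_direction`; both
#'   non-empty.
#' @param labels length-2 character labels for the groups.
#' @return A list with `correlations` (per-group [correlate_responses()]
#'   results) and `proportions` (a [compare_proportions()] result on the
#'   inhibited / not-inhibited table).
#' @export
projection_contrast <- function(group_a, group_b,
                                labels = c("VTA", "DRN")) {
  stopifnot(nrow(group_a) > 0, nrow(group_b) > 0)
  cors <- lapply(list(group_a, group_b), function(g)
    correlate_responses(g$reward_magnitude, g$shock_magnitude))
  names(cors) <- labels
  counts <- rbind(
    c(sum(group_a$reward_direction == "inhibited"),
      sum(group_a$reward_direction != "inhibited")),
    c(sum(group_b$reward_direction == "inhibited"),
      sum(group_b$reward_direction != "inhibited")))
  dimnames(counts) <- list(labels, c("inhibited", "not_inhibited"))
  list(correlations = cors, proportions = compare_proportions(counts))
}
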