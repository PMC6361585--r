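#' Detect bursts by the interspike-interval rule
#'
#' Scans interspike intervals left to right: a burst opens at the first
#' spike of any pair separated by less than 80 ms; subsequent spikes join
#' the burst while the next interval does not exceed 160 ms; the burst
#' closes when the following spike is more than 160 ms away (or the train
#' ends).  Scanning resumes after the closing spike, so bursts are
#' non-overlapping maximal runs.  Thresholds are strict at 80 ms (an
#' interval of exactly 80 ms does not open a burst) and inclusive at
#' 160 ms (exactly 160 ms continues a burst).
#'
#' @param train a [spike_train()].
#' @param open_isi opening interval bound in seconds (default 0.080).
#' @param continue_isi continuation bound in seconds (default 0.160).
#' @return An object of class `burst_stats`: list with `unit_id`, `bursts`
#'   (data frame `start`, `end`, `n_spikes`), `pct_spikes_in_bursts`
#'   (percentage of all spikes inside bursts, 0-100), and `n_spikes`.
#' @examples
#' st <- spike_train("u1", c(0, 0.05, 0.10, 0.50), c(0, 1))
#' detect_bursts(st)  # one burst of 3 spikes, 75% of spikes in bursts
#' @export
detect_bursts <- function(train, open_isi = 0.080, continue_isi = 0.160) {
  t <- train$times
  n <- length(t)
  empty <- data.frame(start = numeric(), end = numeric(),
                      n_spikes = integer())
  if (n < 2)
    return(structure(list(unit_id = train$unit_id, bursts = empty,
                          pct_spikes_in_bursts = 0, n_spikes = n),
                     class = "burst_stats"))
  isi <- diff(t)
  starts <- integer(); ends <- integer()
  i <- 1L
  while (i < n) {
    if (isi[i] < open_isi) {
      j <- i + 1L
      while (j < n && isi[j] <= continue_isi) j <- j + 1L
      starts <- c(starts, i); ends <- c(ends, j)
      i <- j + 1L
    } else i <- i + 1L
  }
  bursts <- if (length(starts))
    data.frame(start = t[starts], end = t[ends],
               n_spikes = ends - starts + 1L)
  else empty
  structure(list(unit_id = train$unit_id, bursts = bursts,
                 pct_spikes_in_bursts = 100 * sum(bursts$n_spikes) / n,
                 n_spikes = n),
            class = "burst_stats")
}

#' @export
print.burst_stats <- function(x, ...) {
  cat(sprintf("<burst_stats %s: %d bursts, %.1f%% of %d spikes in bursts>\n",
              x$unit_id, nrow(x$bursts), x$pct_spikes_in_bursts,
              x$n_spikes))
  invisible(x)
}

#' Baseline firing rate
#'
#' Spike count over effective duration within a window; blanked intervals
#' on the train are subtracted from the duration.
#'
#' @param train a [spike_train()].
#' @param window numeric length-2 `(start, end)` in seconds, within the
#'   session span.
#' @return Rate in Hz.
#' @export
baseline_rate <- function(train, window) {
  stopifnot(length(window) == 2, window[1] < window[2])
  if (window[1] < train$session_span[1] - 1e-9 ||
      window[2] > train$session_span[2] + 1e-9)
    stop("window outside session span")
  eff <- (window[2] - window[1]) -
    interval_overlap(window[1], window[2], train$blanked)
  if (eff <= 0) stop("window has zero effective (unblanked) duration")
  sum(train$times >= window[1] & train$times < window[2]) / eff
}
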