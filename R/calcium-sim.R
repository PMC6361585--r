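#' Calcium trace object
#'
#' An extracted dF/F time series for one cell, uniformly sampled, with its
#' projection-target label and trial onsets.
#'
#' @param cell_id cell identifier.
#' @param dF_F numeric dF/F series.
#' @param sample_rate sampling rate in Hz.
#' @param projection_target `"VTA"`, `"DRN"`, or `"unknown"`.
#' @param trial_onsets stimulus onsets in seconds.
#' @return An object of class `calcium_trace`.
#' @export
calcium_trace <- function(cell_id, dF_F, sample_rate,
                          projection_target = "unknown",
                          trial_onsets = numeric()) {
  stopifnot(sample_rate > 0, all(is.finite(dF_F)))
  structure(list(cell_id = as.character(cell_id), dF_F = as.numeric(dF_F),
                 sample_rate = sample_rate,
                 projection_target = projection_target,
                 trial_onsets = as.numeric(trial_onsets)),
            class = "calcium_trace")
}

#' @export
print.calcium_trace <- function(x, ...) {
  cat(sprintf("<calcium_trace %s (%s): %d samples @ %g Hz, %d trials>\n",
              x$cell_id, x$projection_target, length(x$dF_F),
              x$sample_rate, length(x$trial_onsets)))
  invisible(x)
}

# difference-of-exponentials calcium impulse response, peak-normalized
calcium_kernel <- function(sample_rate, rise = 0.1, decay = 0.8,
                           length_s = 5) {
  t <- seq(0, length_s, by = 1 / sample_rate)
  h <- exp(-t / decay) - exp(-t / rise)
  h / max(h)
}

#' Convolve spike times into a noiseless dF/F trace
#'
#' Bins spike times into frames and convolves with the peak-normalized
#' difference-of-exponentials indicator kernel
#' `exp(-t/decay) - exp(-t/rise)`.
#'
#' @param times spike times in seconds.
#' @param session_length recording length in seconds.
#' @param frame_rate sampling rate in Hz.
#' @param rise,decay kernel time constants in seconds.
#' @return Numeric dF/F vector of length `floor(session_length *
#'   frame_rate)`.
#' @export
spikes_to_calcium <- function(times, session_length, frame_rate = 20,
                              rise = 0.1, decay = 0.8) {
  n_frames <- floor(session_length * frame_rate)
  counts <- tabulate(pmin(n_frames, floor(times * frame_rate) + 1L),
                     nbins = n_frames)
  kern <- calcium_kernel(frame_rate, rise, decay)
  stats::convolve(counts, rev(kern), type = "open")[seq_len(n_frames)]
}

#' Generate synthetic calcium traces
#'
#' Simulates spike trains for a population spec, convolves each with a
#' difference-of-exponentials indicator kernel, samples at `frame_rate`,
#' and adds Gaussian noise.  Ground truth is retained so classification on
#' the traces can be validated.
#'
#' @param pop_spec population spec as in [generate_population()].
#' @param schedule an [event_schedule()].
#' @param session_length session length in seconds.
#' @param frame_rate sampling rate in Hz, `> 0` (nominal 20, typically
#'   downsampled to 5 afterwards with [downsample_trace()]).
#' @param noise_sd Gaussian noise SD in dF/F units, `>= 0`.
#' @param seed integer master seed.
#' @param rise,decay indicator kernel rise/decay time constants in seconds
#'   (defaults 0.1 and 0.8, a fast-indicator-like shape).
#' @param projection_target projection label attached to every generated
#'   cell.
#' @return A list with `traces` (list of [calcium_trace()]) and `truth`
#'   as in [generate_population()].
#' @export
generate_calcium_traces <- function(pop_spec, schedule, session_length,
                                    frame_rate = 20, noise_sd = 0.05, seed = 1,
                                    rise = 0.1, decay = 0.8,
                                    projection_target = "unknown") {
  if (frame_rate <= 0) stop("frame_rate must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  pop <- generate_population(pop_spec, schedule, session_length, seed,
                             id_prefix = "c")
  n_frames <- floor(session_length * frame_rate)
  noise_seeds <- derive_seeds(seed + 1L, length(pop$trains))
  traces <- lapply(seq_along(pop$trains), function(i) {
    st <- pop$trains[[i]]
    conv <- spikes_to_calcium(st$times, session_length, frame_rate,
                              rise, decay)
    noise <- if (noise_sd > 0)
      with_seed(noise_seeds[i], stats::rnorm(n_frames, 0, noise_sd))
    else 0
    calcium_trace(st$unit_id, conv + noise, frame_rate, projection_target,
                  trial_onsets = schedule$onset)
  })
  list(traces = traces, truth = pop$truth)
}

#' Temporally downsample a calcium trace
#'
#' Averages consecutive blocks of `factor` samples, emulating the usual
#' acquisition-then-downsample sequence (e.g. 20 Hz acquisition down to
#' 5 Hz analysis).
#'
#' @param trace a [calcium_trace()].
#' @param factor integer downsampling factor.
#' @return A [calcium_trace()] at `sample_rate / factor`.
#' @export
downsample_trace <- function(trace, factor = 4L) {
  factor <- as.integer(factor)
  stopifnot(factor >= 1)
  n <- floor(length(trace$dF_F) / factor)
  x <- matrix(trace$dF_F[seq_len(n * factor)], nrow = factor)
  calcium_trace(trace$cell_id, colMeans(x), trace$sample_rate / factor,
                trace$projection_target, trace$trial_onsets)
}
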