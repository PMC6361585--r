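#' Conditioned-place-test session object
#'
#' Chamber occupancy intervals, derived entry counts, and photobeam counts
#' for one pre- or post-conditioning free-exploration session in a
#' three-chamber apparatus (stimulus-paired, unpaired, center).  Occupancy
#' intervals must partition the session, consecutive intervals must differ
#' in chamber, and transitions between the two side chambers must pass
#' through the center.
#'
#' @param occupancy data frame with columns `chamber` (one of `"paired"`,
#'   `"unpaired"`, `"center"`), `start`, `end` (seconds).
#' @param phase `"pre"` or `"post"`.
#' @param photobeam_count non-negative integer count of photobeam breaks.
#' @param animal_id,group optional metadata.
#' @return An object of class `cpp_session`.
#' @export
cpp_session <- function(occupancy, phase = c("pre", "post"),
                        photobeam_count = 0L, animal_id = "a1",
                        group = "sham") {
  phase <- match.arg(phase)
  occ <- as.data.frame(occupancy)
  stopifnot(all(c("chamber", "start", "end") %in% names(occ)),
            photobeam_count >= 0)
  bad <- which(!occ$chamber %in% c("paired", "unpaired", "center"))
  if (length(bad))
    stop("invalid chamber in occupancy row ", bad[1])
  bad <- which(occ$end <= occ$start)
  if (length(bad))
    stop("non-positive occupancy interval at row ", bad[1])
  if (nrow(occ) > 1) {
    gap <- which(abs(occ$start[-1] - occ$end[-nrow(occ)]) > 1e-9)
    if (length(gap))
      stop("occupancy intervals do not partition the session at row ",
           gap[1] + 1)
    same <- which(occ$chamber[-1] == occ$chamber[-nrow(occ)])
    if (length(same))
      stop("consecutive intervals share a chamber at row ", same[1] + 1)
    side <- occ$chamber != "center"
    jump <- which(side[-1] & side[-nrow(occ)])
    if (length(jump))
      stop("side-to-side transition without center passage at row ",
           jump[1] + 1)
  }
  structure(list(occupancy = occ, phase = phase,
                 photobeam_count = as.integer(photobeam_count),
                 animal_id = animal_id, group = group),
            class = "cpp_session")
}

#' @export
print.cpp_session <- function(x, ...) {
  tot <- sum(x$occupancy$end - x$occupancy$start)
  cat(sprintf("<cpp_session %s/%s (%s): %d intervals over %.0f s, %d beam breaks>\n",
              x$animal_id, x$group, x$phase, nrow(x$occupancy), tot,
              x$photobeam_count))
  invisible(x)
}

#' Generate a synthetic place-test session
#'
#' Markov chamber-transition model of three-chamber exploration: the animal
#' alternates between the center and a side chamber, with exponential dwell
#' times; at each center departure the paired side is chosen with
#' probability `bias_paired`.  Photobeam counts are two breaks per chamber
#' transition plus Poisson background activity, so they track locomotion.
#'
#' @param bias_paired probability of entering the paired chamber at each
#'   center departure, in `(0, 1)`.
#' @param mean_dwell mean chamber dwell time in seconds.
#' @param session_length session length in seconds (default 900, a 15 min
#'   exploration).
#' @param seed integer seed.
#' @param phase,animal_id,group metadata passed to [cpp_session()].
#' @param center_dwell_frac center dwells are `mean_dwell *
#'   center_dwell_frac` on average (traversals are brief; default 0.25).
#' @param beam_background_rate rate (Hz) of within-chamber photobeam breaks
#'   (default 0.05).
#' @return A [cpp_session()] whose occupancy intervals sum exactly to
#'   `session_length`.
#' @export
generate_cpp_session <- function(bias_paired, mean_dwell = 20,
                                 session_length = 900, seed = 1,
                                 phase = "pre", animal_id = "a1",
                                 group = "sham", center_dwell_frac = 0.25,
                                 beam_background_rate = 0.05) {
  if (!is.numeric(bias_paired) || bias_paired <= 0 || bias_paired >= 1)
    stop("bias_paired must be in (0, 1)")
  stopifnot(mean_dwell > 0, session_length > 0)
  with_seed(seed, {
    chambers <- character()
    dwells <- numeric()
    t <- 0
    cur <- "center"
    while (t < session_length) {
      mu <- if (cur == "center") mean_dwell * center_dwell_frac else mean_dwell
      d <- stats::rexp(1, 1 / mu)
      d <- min(d, session_length - t)
      chambers <- c(chambers, cur)
      dwells <- c(dwells, d)
      t <- t + d
      cur <- if (cur == "center") {
        if (stats::runif(1) < bias_paired) "paired" else "unpaired"
      } else "center"
    }
    ends <- cumsum(dwells)
    occ <- data.frame(chamber = chambers,
                      start = c(0, ends[-length(ends)]), end = ends)
    n_trans <- nrow(occ) - 1
    beams <- 2L * n_trans +
      stats::rpois(1, beam_background_rate * session_length)
    cpp_session(occ, phase = phase, photobeam_count = beams,
                animal_id = animal_id, group = group)
  })
}
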