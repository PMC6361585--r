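#' Spike train object
#'
#' One unit's sorted spike times plus session metadata; the atomic
#' electrophysiology record.
#'
#' @param unit_id unit identifier.
#' @param times numeric vector of spike times in seconds, strictly
#'   increasing.
#' @param session_span numeric length-2, session start/end in seconds.
#' @param session_id session identifier.
#' @param blanked optional 2-column matrix of excluded (blanked) time
#'   intervals; see [blank_shock_artifact()].
#' @return An object of class `spike_train`.
#' @export
spike_train <- function(unit_id, times, session_span, session_id = "s1",
                        blanked = NULL) {
  times <- as.numeric(times)
  if (is.unsorted(times, strictly = TRUE))
    stop("spike times must be strictly increasing")
  if (length(times) && (times[1] < session_span[1] ||
                        times[length(times)] > session_span[2]))
    stop("spike times outside session span")
  structure(list(unit_id = as.character(unit_id), times = times,
                 session_id = session_id,
                 session_span = as.numeric(session_span),
                 blanked = blanked),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train %s: %d spikes over %.1f s (%.2f Hz)>\n",
              x$unit_id, length(x$times), diff(x$session_span),
              length(x$times) / diff(x$session_span)))
  invisible(x)
}

# kernel phases matched to schedule events -> matrix (on, off, gain)
kernel_phases <- function(kernels, schedule, session_length) {
  rows <- list()
  for (k in kernels) {
    ev <- schedule$onset[schedule$label == k$stimulus]
    if (!length(ev)) next
    phases <- list(list(k$latency, k$duration, k$gain))
    if (!is.null(k$second))
      phases <- c(phases, list(list(k$second$latency, k$second$duration,
                                    k$second$gain)))
    for (ph in phases) {
      on <- pmax(0, ev + ph[[1]])
      off <- pmin(session_length, ev + ph[[1]] + ph[[2]])
      keep <- off > on
      if (any(keep))
        rows[[length(rows) + 1]] <- cbind(on[keep], off[keep],
                                          ph[[3]])
    }
  }
  if (!length(rows)) return(matrix(numeric(), ncol = 3))
  do.call(rbind, rows)
}

#' Generate a synthetic spike train
#'
#' Simulates an inhomogeneous Poisson spike train by per-segment thinning.
#' The rate function is `baseline_rate(t)` times the product of all active
#' kernel gains; it is decomposed into segments at kernel-phase boundaries,
#' candidate spikes are drawn at each segment's maximum rate, and thinned by
#' the ratio `rate(t) / max`.  This is exact for the piecewise-constant
#' (no-drift) case and for linear baseline drift.  Optional burst clusters
#' (a Neyman-Scott process) and quality defects are then added per the
#' config.
#'
#' Clean units carry an absolute refractory dead time (default 1 ms): any
#' spike closer than `dead_time` to its predecessor is deleted, and the
#' driving intensity is compensated (`r / (1 - r * dead_time)`) so the
#' realized rate still equals the configured rate function.  Injected
#' refractory violations and artifact spikes are added after this step,
#' so only configured defects produce sub-millisecond intervals.
#'
#' @param config a [unit_gen_config()].
#' @param schedule an [event_schedule()]; all events must fall within the
#'   session.
#' @param session_length session length in seconds, `> 0`.
#' @param seed integer seed; identical inputs reproduce identical trains.
#' @param dead_time absolute refractory period in seconds (default 0.001);
#'   requires `rate * dead_time < 0.5` everywhere.
#' @return A [spike_train()].
#' @examples
#' cfg <- archetype_config("pda")
#' sched <- phasic_schedule(n_reward = 10, n_per_stimulus = 0, iti = 5)
#' st <- generate_spike_train(cfg, sched, 120, seed = 1)
#' @export
generate_spike_train <- function(config, schedule, session_length, seed,
                                 dead_time = 0.001) {
  stopifnot(inherits(config, "unit_gen_config"),
            inherits(schedule, "event_schedule"))
  if (!is.numeric(session_length) || session_length <= 0)
    stop("session_length must be > 0")
  if (nrow(schedule) && (min(schedule$onset) < 0 ||
                         max(schedule$onset) > session_length))
    stop("schedule events must lie within [0, session_length]")

  drift <- 0
  if (!is.null(config$defects$drift_slope))
    drift <- config$defects$drift_slope / 60  # Hz per second
  base_rate <- function(t) pmax(0, config$baseline_rate + drift * t)
  # dead-time compensation keeps the realized post-deletion rate at the
  # configured value: r' / (1 + r' * tau) = r  when  r' = r / (1 - r tau)
  compensate <- function(r) {
    if (dead_time <= 0) return(r)
    if (any(r * dead_time >= 0.5))
      stop("rate * dead_time must stay below 0.5")
    r / (1 - r * dead_time)
  }

  phases <- kernel_phases(config$kernels, schedule, session_length)
  breaks <- sort(unique(c(0, session_length, phases[, 1], phases[, 2])))
  times <- with_seed(seed, {
    out <- vector("list", length(breaks) - 1)
    for (i in seq_len(length(breaks) - 1)) {
      a <- breaks[i]; b <- breaks[i + 1]
      mid <- (a + b) / 2
      gain <- 1
      if (nrow(phases))
        gain <- prod(phases[phases[, 1] <= mid & phases[, 2] > mid, 3])
      rmax <- compensate(max(base_rate(a), base_rate(b)) * gain)
      if (rmax <= 0) next
      n <- stats::rpois(1, rmax * (b - a))
      if (n == 0) next
      cand <- stats::runif(n, a, b)
      keep <- stats::runif(n) < compensate(base_rate(cand) * gain) / rmax
      out[[i]] <- cand[keep]
    }
    spikes <- unlist(out, use.names = FALSE)

    if (!is.null(config$burst) && config$burst$cluster_rate > 0) {
      bc <- config$burst
      ncl <- stats::rpois(1, bc$cluster_rate * session_length)
      if (ncl > 0) {
        centers <- stats::runif(ncl, 0, session_length)
        nsp <- 1 + stats::rpois(ncl, max(0, bc$spikes_per_cluster - 1))
        extra <- unlist(lapply(seq_len(ncl), function(j) {
          centers[j] + cumsum(c(0, stats::rexp(nsp[j] - 1,
                                               1 / bc$within_isi)))
        }))
        spikes <- c(spikes, extra[extra < session_length & extra >= 0])
      }
    }

    spikes <- sort(spikes)
    if (dead_time > 0 && length(spikes) > 1) {
      repeat {
        bad <- which(diff(spikes) < dead_time)
        if (!length(bad)) break
        spikes <- spikes[-(bad + 1L)]
      }
    }

    rf <- config$defects$refractory_fraction
    if (!is.null(rf) && rf > 0 && length(spikes)) {
      k <- round(rf * length(spikes))
      if (k > 0) {
        dup <- sample(spikes, k)
        spikes <- c(spikes, dup + 5e-4)
      }
    }
    art <- config$defects$artifact_labels
    if (!is.null(art)) {
      ons <- schedule$onset[schedule$label %in% art]
      spikes <- c(spikes, ons + 1e-3)
    }
    spikes
  })
  times <- sort(times[times >= 0 & times <= session_length])
  times <- unique(times)
  spike_train(config$unit_id, times, c(0, session_length))
}

#' Generate a synthetic population with ground truth
#'
#' Expands a population specification into spike trains plus a planted
#' ground-truth table, so that downstream classifiers can be validated
#' against known labels.
#'
#' @param pop_spec list of entries; each entry is either
#'   `list(archetype = <name>, count = <n>, ...)` (extra arguments passed to
#'   [archetype_config()]) or `list(config = <unit_gen_config>, count = <n>)`.
#'   Counts must be `>= 1`.
#' @param schedule an [event_schedule()].
#' @param session_length session length in seconds.
#' @param seed integer master seed; one child seed is derived per unit.
#' @param id_prefix prefix for generated unit ids.
#' @return A list with `trains` (list of [spike_train()]) and `truth`, a
#'   list with `units` (data frame: `unit_id`, `archetype`,
#'   `valence_encoding`) and `categories` (data frame: `unit_id`,
#'   `stimulus`, planted `category`).
#' @export
generate_population <- function(pop_spec, schedule, session_length, seed,
                                id_prefix = "u") {
  counts <- vapply(pop_spec, function(e) as.integer(e$count), 1L)
  if (any(counts < 1)) stop("counts must be >= 1")
  total <- sum(counts)
  ids <- sprintf("%s%03d", id_prefix, seq_len(total))
  seeds <- derive_seeds(seed, total)

  trains <- vector("list", total)
  units <- data.frame(unit_id = ids,
                      archetype = rep(NA_character_, total),
                      valence_encoding = rep(FALSE, total),
                      stringsAsFactors = FALSE)
  cats <- list()
  i <- 0
  for (entry in pop_spec) {
    for (j in seq_len(entry$count)) {
      i <- i + 1
      if (!is.null(entry$config)) {
        cfg <- entry$config
        cfg$unit_id <- ids[i]
      } else {
        extra <- entry[setdiff(names(entry), c("archetype", "count"))]
        cfg <- do.call(archetype_config,
                       c(list(archetype = entry$archetype,
                              unit_id = ids[i]), extra))
      }
      trains[[i]] <- generate_spike_train(cfg, schedule, session_length,
                                          seed = seeds[i])
      kt <- kernel_truth(cfg)
      units$archetype[i] <- cfg$archetype
      units$valence_encoding[i] <-
        any(kt$stimulus == "reward_cue" & kt$category == "inhibited") &&
        any(kt$stimulus == "footshock" & kt$category == "excited")
      if (nrow(kt))
        cats[[length(cats) + 1]] <- cbind(unit_id = ids[i], kt)
    }
  }
  if (anyDuplicated(ids)) stop("duplicate unit ids")
  categories <- if (length(cats)) do.call(rbind, cats) else
    data.frame(unit_id = character(), stimulus = character(),
               category = character())
  list(trains = trains,
       truth = list(units = units, categories = categories))
}
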