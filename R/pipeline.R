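#' Build an analysis configuration
#'
#' Collects everything the end-to-end pipeline needs: the population to
#' synthesize (or spike/schedule CSV paths to load), session layout,
#' analysis windows, significance levels, and the normalization dialect.
#' Defaults are the standard analysis commitments: 50 ms bins, 1 s
#' baseline, reward window 200-400 ms, aversive window 0-100 ms, pDA
#' typing windows 0-200 / 200-2000 ms, inhibition window 100-500 ms,
#' alpha 0.05, z-score normalization with a 0.1 Hz SD floor.
#'
#' @param population population spec as in [generate_population()]
#'   (ignored when `spike_csv` is given).
#' @param spike_csv,schedule_csv optional paths to a spike table and event
#'   schedule to analyze instead of synthesizing.
#' @param n_reward,n_per_stimulus,iti phasic session layout passed to
#'   [phasic_schedule()] (defaults 50, 30, 30 s).
#' @param seed integer master seed.
#' @param alpha per-neuron significance level.
#' @param windows analysis windows, see [default_windows()].
#' @param method,sd_floor normalization dialect, see [normalize_psth()].
#' @param vta_typing logical; when `TRUE` units are additionally typed as
#'   pDA / ramping / reward-inhibited and pDA aversive responses
#'   subtyped.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(population = list(list(archetype = "none",
                                                   count = 10)),
                            spike_csv = NULL, schedule_csv = NULL,
                            n_reward = 50, n_per_stimulus = 30, iti = 30,
                            seed = 1, alpha = 0.05,
                            windows = default_windows(),
                            method = "zscore", sd_floor = 0.1,
                            vta_typing = FALSE) {
  stopifnot(alpha > 0, alpha < 1)
  need <- c("reward_cue", "aversive", "pda", "ramping", "pda_inhibition")
  missing <- setdiff(need, names(windows))
  if (length(missing))
    stop("windows must define: ", paste(missing, collapse = ", "))
  structure(list(population = population, spike_csv = spike_csv,
                 schedule_csv = schedule_csv, n_reward = n_reward,
                 n_per_stimulus = n_per_stimulus, iti = iti, seed = seed,
                 alpha = alpha, windows = windows, method = method,
                 sd_floor = sd_floor, vta_typing = vta_typing),
            class = "analysis_config")
}

# binning window per stimulus: long enough for every analysis window used
bin_window_for <- function(label, vta_typing) {
  if (label == "reward_cue" && vta_typing) c(-1, 2)
  else if (label == "reward_cue") c(-1, 0.5)
  else c(-1, 0.5)
}

#' Run the end-to-end analysis pipeline
#'
#' Synthesizes (or loads) a phasic-session population, applies unit QC
#' (shock-artifact blanking, refractory and drift screening), computes
#' per-stimulus response profiles, classifies units (valence encoding;
#' optionally pDA / ramping typing and aversive-inhibition subtyping),
#' and assembles population summaries: per-stimulus direction proportion
#' tables and cross-stimulus magnitude correlations among shock-excited
#' units.  The run is deterministic given the config seed.
#'
#' @param config an [analysis_config()].
#' @return A report: list with `provenance` (config echo, package
#'   version, windows), `qc` (per-unit QC table), `profiles` (per
#'   unit-stimulus response table), `classification` (per-unit labels),
#'   `proportions` (per-stimulus direction counts), `correlations`
#'   (footshock-vs-other magnitude correlations), and `truth` (planted
#'   ground truth when data were synthesized).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  if (!is.null(config$spike_csv)) {
    schedule <- read_event_schedule(config$schedule_csv)
    trains <- read_spike_table(config$spike_csv)
    session_length <- max(c(schedule$onset + config$iti,
                            vapply(trains, function(st)
                              st$session_span[2], 0)))
    trains <- lapply(trains, function(st) {
      st$session_span <- c(0, session_length); st
    })
    truth <- NULL
  } else {
    schedule <- phasic_schedule(config$n_reward, config$n_per_stimulus,
                                iti = config$iti)
    session_length <- max(schedule$onset) + config$iti
    pop <- generate_population(config$population, schedule,
                               session_length, seed = config$seed)
    trains <- pop$trains
    truth <- pop$truth
  }
  shock_onsets <- schedule$onset[schedule$label == "footshock"]
  trains <- lapply(trains, function(st)
    if (length(shock_onsets)) blank_shock_artifact(st, shock_onsets)
    else st)

  qc <- do.call(rbind, lapply(trains, qc_unit))
  accepted <- trains[qc$accepted]

  stimuli <- unique(schedule$label)
  win <- config$windows
  resp_window <- function(lb) {
    if (lb == "reward_cue") win$reward_cue else win$aversive
  }
  profiles <- list()
  classification <- list()
  for (st in accepted) {
    mats <- lapply(stimuli, function(lb)
      align_and_bin(st, schedule, lb,
                    bin_window_for(lb, config$vta_typing), 0.05))
    names(mats) <- stimuli
    profs <- lapply(stimuli, function(lb)
      window_response_test(mats[[lb]], resp_window(lb),
                           alpha = config$alpha,
                           sd_floor = config$sd_floor,
                           method = config$method))
    names(profs) <- stimuli
    profiles[[st$unit_id]] <- do.call(rbind, profs)
    rmtg <- classify_rmtg_profile(profs)
    row <- data.frame(unit_id = st$unit_id,
                      valence_encoding = rmtg$valence_encoding,
                      cell_type = NA_character_,
                      footshock_response_type = NA_character_,
                      stringsAsFactors = FALSE)
    if (config$vta_typing && "reward_cue" %in% stimuli) {
      ct <- classify_vta_cell_type(mats$reward_cue, alpha = config$alpha,
                                   windows = win)
      row$cell_type <- ct$label
      if (ct$label == "pda" && "footshock" %in% stimuli) {
        row$footshock_response_type <-
          classify_aversive_inhibition_type(
            mats$footshock, alpha = config$alpha,
            early_window = win$pda_early,
            inhibition_window = win$pda_inhibition)$type
      }
    }
    classification[[st$unit_id]] <- row
  }
  profiles <- do.call(rbind, c(profiles, list(make.row.names = FALSE)))
  classification <- do.call(rbind, c(classification,
                                     list(make.row.names = FALSE)))

  proportions <- lapply(stimuli, function(lb) {
    sub <- profiles[profiles$stimulus == lb, ]
    table(factor(sub$direction,
                 levels = c("excited", "inhibited", "none")))
  })
  names(proportions) <- stimuli

  correlations <- list()
  if (all(c("footshock", "siren") %in% stimuli) ||
      all(c("footshock", "bright_light") %in% stimuli)) {
    shock <- profiles[profiles$stimulus == "footshock", ]
    shock_exc <- shock$unit_id[shock$direction == "excited"]
    for (other in intersect(c("siren", "bright_light"), stimuli)) {
      o <- profiles[profiles$stimulus == other, ]
      ids <- intersect(shock_exc, o$unit_id)
      if (length(ids) >= 3) {
        xm <- shock$magnitude[match(ids, shock$unit_id)]
        ym <- o$magnitude[match(ids, o$unit_id)]
        correlations[[paste0("footshock_vs_", other)]] <-
          tryCatch(correlate_responses(xm, ym), error = function(e) NULL)
      }
    }
  }

  list(provenance = list(
         package = "valencephys",
         version = as.character(utils::packageVersion("valencephys")),
         seed = config$seed, alpha = config$alpha,
         windows = config$windows, method = config$method,
         sd_floor = config$sd_floor,
         n_units = length(trains), n_accepted = length(accepted)),
       qc = qc, profiles = profiles, classification = classification,
       proportions = proportions, correlations = correlations,
       truth = truth)
}

#' Validate a pipeline report against the bundled schema
#'
#' Checks the report's structure against the JSON schema shipped in
#' `inst/extdata/report-schema.json`: required top-level components,
#' required columns of the tabular components, and required provenance
#' fields.
#'
#' @param report a [run_pipeline()] report.
#' @return `TRUE` invisibly; otherwise an error naming the first missing
#'   element.
#' @export
validate_report <- function(report) {
  schema <- jsonlite::read_json(
    system.file("extdata", "report-schema.json", package = "valencephys"),
    simplifyVector = TRUE)
  missing <- setdiff(schema$required, names(report))
  if (length(missing))
    stop("report missing component: ", missing[1])
  for (comp in names(schema$columns)) {
    miss <- setdiff(schema$columns[[comp]], names(report[[comp]]))
    if (length(miss))
      stop("report component '", comp, "' missing column: ", miss[1])
  }
  miss <- setdiff(schema$provenance, names(report$provenance))
  if (length(miss)) stop("provenance missing field: ", miss[1])
  invisible(TRUE)
}

#' Write a pipeline report to disk
#'
#' Tabular components as CSV, provenance and proportion tables as JSON.
#'
#' @param report a [run_pipeline()] report.
#' @param dir output directory (created if needed).
#' @return `dir` invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$qc, file.path(dir, "qc.csv"),
                   row.names = FALSE)
  utils::write.csv(report$profiles, file.path(dir, "profiles.csv"),
                   row.names = FALSE)
  utils::write.csv(report$classification,
                   file.path(dir, "classification.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(provenance = report$provenance,
         proportions = lapply(report$proportions, as.list),
         correlations = report$correlations),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(dir)
}
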