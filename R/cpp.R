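# per-chamber seconds and entries for one session
session_summary <- function(session, debounce = 1) {
  occ <- session$occupancy
  dur <- occ$end - occ$start
  seconds <- vapply(c("paired", "unpaired", "center"), function(ch)
    sum(dur[occ$chamber == ch]), 0)
  # an entry is a transition into a chamber; brief center traversals
  # (dwell < debounce) are not counted as center entries
  entries <- c(paired = 0L, unpaired = 0L, center = 0L)
  if (nrow(occ) > 1) for (i in 2:nrow(occ)) {
    ch <- occ$chamber[i]
    if (ch == "center" && dur[i] < debounce) next
    entries[ch] <- entries[ch] + 1L
  }
  list(seconds = seconds, entries = entries,
       n_transitions = nrow(occ) - 1L)
}

#' Place-preference score
#'
#' Preference for the stimulus-paired chamber: seconds spent in (mode
#' `"time"`) or entries into (mode `"entries"`) the paired chamber minus
#' the unpaired chamber.  The center chamber contributes to neither.
#'
#' @param session a [cpp_session()].
#' @param mode `"time"` or `"entries"`.
#' @param debounce center-entry debounce in seconds (default 1); see
#'   [locomotor_summary()].
#' @return Numeric score (seconds or entry count difference); negative
#'   values indicate avoidance of the paired chamber.
#' @export
preference_score <- function(session, mode = c("time", "entries"),
                             debounce = 1) {
  mode <- match.arg(mode)
  s <- session_summary(session, debounce)
  out <- if (mode == "time")
    s$seconds[["paired"]] - s$seconds[["unpaired"]]
  else
    as.numeric(s$entries[["paired"]] - s$entries[["unpaired"]])
  structure(out, mode = mode)
}

#' Place-preference shift
#'
#' Conditioning effect for one animal: the post-training preference score
#' minus the pre-training preference score, in the same mode.
#'
#' @param pre,post preference scores from [preference_score()] (pre- and
#'   post-conditioning sessions of the same animal, same mode).
#' @return `post - pre`.
#' @export
preference_shift <- function(pre, post) {
  mp <- attr(pre, "mode"); mq <- attr(post, "mode")
  if (!is.null(mp) && !is.null(mq) && !identical(mp, mq))
    stop("pre and post scores use different modes")
  as.numeric(post) - as.numeric(pre)
}

#' Locomotor summary of a place-test session
#'
#' Overall activity measures: the photobeam-break count recorded for the
#' session and the total number of chamber entries (every transition into
#' a side chamber, plus center entries with dwell of at least the
#' debounce).
#'
#' @param session a [cpp_session()].
#' @param debounce center-entry debounce in seconds (default 1).
#' @return A list with `photobeam_count` and `total_entries`.
#' @export
locomotor_summary <- function(session, debounce = 1) {
  s <- session_summary(session, debounce)
  list(photobeam_count = session$photobeam_count,
       total_entries = as.integer(sum(s$entries)))
}

#' Group contrast of preference shifts
#'
#' Two-way ANOVA (lesion group x stimulus) on per-animal preference
#' shifts, with Bonferroni-adjusted per-stimulus group contrasts, plus a
#' one-sample test of each group-by-stimulus cell's shifts against zero.
#'
#' @param shifts data frame with columns `animal`, `group` (2+ levels),
#'   `stimulus`, `shift`; at least 2 animals per group-by-stimulus cell.
#' @return A list with `anova` (data frame of effects: `term`, `F`, `p`),
#'   `per_stimulus` (data frame: `stimulus`, `p_raw`, `p_bonferroni` for
#'   the group contrast within each stimulus), and `vs_zero` (data frame:
#'   `group`, `stimulus`, `mean_shift`, `p` from a one-sample t-test).
#' @export
group_contrast <- function(shifts) {
  stopifnot(all(c("group", "stimulus", "shift") %in% names(shifts)))
  shifts$group <- factor(shifts$group)
  shifts$stimulus <- factor(shifts$stimulus)
  cell_n <- table(shifts$group, shifts$stimulus)
  if (any(cell_n < 2)) stop("need at least 2 animals per cell")
  multi_stim <- nlevels(shifts$stimulus) > 1
  form <- if (multi_stim) shift ~ group * stimulus else shift ~ group
  fit <- stats::aov(form, data = shifts)
  tab <- summary(fit)[[1]]
  terms <- trimws(rownames(tab))
  keep <- terms != "Residuals"
  anova_df <- data.frame(term = terms[keep], F = tab[keep, "F value"],
                         p = tab[keep, "Pr(>F)"],
                         stringsAsFactors = FALSE)
  stims <- levels(shifts$stimulus)
  p_raw <- vapply(stims, function(sm) {
    sub <- shifts[shifts$stimulus == sm, ]
    stats::t.test(shift ~ group, data = sub)$p.value
  }, 0)
  per_stim <- data.frame(stimulus = stims, p_raw = unname(p_raw),
                         p_bonferroni = pmin(1, unname(p_raw) *
                                               length(stims)),
                         stringsAsFactors = FALSE)
  cells <- unique(shifts[, c("group", "stimulus")])
  vs_zero <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sub <- shifts$shift[shifts$group == cells$group[i] &
                          shifts$stimulus == cells$stimulus[i]]
    data.frame(group = as.character(cells$group[i]),
               stimulus = as.character(cells$stimulus[i]),
               mean_shift = mean(sub),
               p = if (stats::var(sub) == 0) NA_real_ else
                 stats::t.test(sub)$p.value,
               stringsAsFactors = FALSE)
  }))
  list(anova = anova_df, per_stimulus = per_stim, vs_zero = vs_zero)
}
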