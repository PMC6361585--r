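#' Correlate per-unit response magnitudes
#'
#' Pearson correlation between two sets of per-unit response magnitudes
#' (e.g. footshock vs siren window-mean normalized rates), with the
#' least-squares line, as used for cross-stimulus magnitude scatterplots.
#' An optional subset restricts the analysis, e.g. to units significantly
#' excited by one stimulus.
#'
#' @param x,y numeric vectors of paired per-unit magnitudes.
#' @param subset optional logical vector selecting units.
#' @return A list with `n`, `r_squared`, `p` (two-sided), `slope`,
#'   `intercept`, and `r`.
#' @export
correlate_responses <- function(x, y, subset = NULL) {
  if (!is.null(subset)) {
    x <- x[subset]; y <- y[subset]
  }
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 paired magnitudes")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("zero variance in magnitudes")
  ct <- stats::cor.test(x, y, method = "pearson")
  fit <- stats::lm.fit(cbind(1, x), y)
  list(n = length(x), r = unname(ct$estimate),
       r_squared = unname(ct$estimate)^2, p = ct$p.value,
       slope = unname(fit$coefficients[2]),
       intercept = unname(fit$coefficients[1]))
}

#' Chi-square contrast of category proportions
#'
#' Chi-square test of independence, without continuity correction, on a
#' groups-by-categories count table (e.g. inhibited / excited / none by
#' sham vs lesion).
#'
#' @param counts matrix of non-negative counts, at least 2 x 2.
#' @return A list with `counts`, `expected`, `statistic`, `df`, and `p`.
#' @export
compare_proportions <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2 || ncol(counts) < 2)
    stop("need at least 2 groups and 2 categories")
  if (any(counts < 0)) stop("counts must be non-negative")
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  if (any(expected == 0))
    stop("expected count of zero; drop empty rows/columns")
  ch <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(counts = counts, expected = expected,
       statistic = unname(ch$statistic), df = unname(ch$parameter),
       p = ch$p.value)
}

#' Repeated-measures time-course test
#'
#' Group-level test of a multi-phase time course: each unit contributes one
#' mean value per time window plus a baseline; a repeated-measures one-way
#' ANOVA tests for any window effect, followed by Holm-Sidak-adjusted
#' paired contrasts of each window against baseline.
#'
#' @param values numeric matrix or data frame, units x windows, with one
#'   column named `baseline_col`.
#' @param baseline_col name of the baseline column (default
#'   `"baseline"`).
#' @return A list with `F`, `p` (omnibus), `n`, and `contrasts` (data
#'   frame `window`, `p_raw`, `p_adj`).
#' @export
group_time_course_test <- function(values, baseline_col = "baseline") {
  values <- as.matrix(values)
  if (ncol(values) < 2) stop("need at least 2 windows")
  if (!baseline_col %in% colnames(values))
    stop("no '", baseline_col, "' column")
  n <- nrow(values)
  long <- data.frame(
    y = as.vector(values),
    window = factor(rep(colnames(values), each = n),
                    levels = colnames(values)),
    unit = factor(rep(seq_len(n), ncol(values))))
  if (all(apply(values, 1, function(r) max(r) == min(r)))) {
    Fv <- 0; p <- 1
  } else {
    fit <- stats::aov(y ~ window + Error(unit), data = long)
    tab <- summary(fit)[["Error: Within"]][[1]]
    Fv <- tab["window", "F value"]
    p <- tab["window", "Pr(>F)"]
  }
  others <- setdiff(colnames(values), baseline_col)
  p_raw <- vapply(others, function(w) {
    d <- values[, w] - values[, baseline_col]
    if (all(d == 0)) 1 else stats::t.test(d)$p.value
  }, 0)
  list(F = Fv, p = p, n = n,
       contrasts = data.frame(window = others, p_raw = unname(p_raw),
                              p_adj = holm_sidak(unname(p_raw)),
                              stringsAsFactors = FALSE))
}

#' D'Agostino-Pearson omnibus normality test
#'
#' The K-squared omnibus test combining the transformed sample skewness
#' (D'Agostino) and kurtosis (Anscombe-Glynn) statistics;
#' `K2 = Z1^2 + Z2^2` is referred to a chi-square distribution with 2
#' degrees of freedom.  Requires `n >= 8`.
#'
#' @param x numeric sample.
#' @return A list with `statistic` (K2), `z_skew`, `z_kurt`, and `p`.
#' @export
dagostino_pearson_test <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8) stop("need n >= 8")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) stop("zero variance sample")
  b1 <- mean((x - m)^3) / m2^1.5
  b2 <- mean((x - m)^4) / m2^2

  # skewness: D'Agostino (1970)
  Y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(W2)))
  a <- sqrt(2 / (W2 - 1))
  Z1 <- delta * log(Y / a + sqrt((Y / a)^2 + 1))

  # kurtosis: Anscombe & Glynn (1983)
  Eb2 <- 3 * (n - 1) / (n + 1)
  Vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - Eb2) / sqrt(Vb2)
  sb <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / sb * (2 / sb + sqrt(1 + 4 / sb^2))
  Z2 <- ((1 - 2 / (9 * A)) -
           ((1 - 2 / A) / (1 + xk * sqrt(2 / (A - 4))))^(1/3)) /
    sqrt(2 / (9 * A))

  K2 <- Z1^2 + Z2^2
  list(statistic = K2, z_skew = Z1, z_kurt = Z2,
       p = stats::pchisq(K2, df = 2, lower.tail = FALSE))
}

#' Normality gate before parametric testing
#'
#' Applies the D'Agostino-Pearson omnibus test; when normality is rejected
#' at `alpha`, the sample is replaced by its mid-ranks before parametric
#' testing (rank transformation), as is common for electrophysiology data
#' that fail normality.  Samples below the test minimum (`n < 8`) pass
#' through unchanged with a flag.
#'
#' @param x numeric sample.
#' @param alpha significance level of the gate (default 0.05).
#' @return A list with `values` (original or mid-ranks), `transformed`
#'   (logical), `p` (normality p, `NA` when skipped), and `flag`
#'   (`"too_few"` when skipped, else `NA`).
#' @export
normality_gate <- function(x, alpha = 0.05) {
  if (length(x) < 8)
    return(list(values = x, transformed = FALSE, p = NA_real_,
                flag = "too_few"))
  dp <- dagostino_pearson_test(x)
  if (dp$p < alpha)
    list(values = rank(x, ties.method = "average"), transformed = TRUE,
         p = dp$p, flag = NA_character_)
  else
    list(values = x, transformed = FALSE, p = dp$p, flag = NA_character_)
}
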