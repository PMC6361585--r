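# internal helpers shared across modules

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Derive a stream of child seeds from one master seed; keeps every derived
# seed inside 32-bit integer range.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Holm-Sidak step-down adjustment
#'
#' Step-down Sidak-corrected p-values for a family of comparisons, as used
#' after repeated-measures one-way ANOVA.
#'
#' @param p numeric vector of raw p-values.
#' @return Adjusted p-values in the input order, monotone and capped at 1.
#' @export
holm_sidak <- function(p) {
  stopifnot(is.numeric(p), all(p >= 0 & p <= 1, na.rm = TRUE))
  m <- length(p)
  o <- order(p)
  adj <- 1 - (1 - p[o])^(m - seq_len(m) + 1)
  adj <- pmin(cummax(adj), 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# merge possibly-overlapping intervals given as a 2-column matrix
merge_intervals <- function(iv) {
  if (is.null(iv) || nrow(iv) == 0) return(iv)
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  out <- iv[1, , drop = FALSE]
  if (nrow(iv) > 1) for (i in 2:nrow(iv)) {
    k <- nrow(out)
    if (iv[i, 1] <= out[k, 2]) {
      out[k, 2] <- max(out[k, 2], iv[i, 2])
    } else out <- rbind(out, iv[i, , drop = FALSE])
  }
  out
}

# total overlap of [a, b) with a set of merged intervals
interval_overlap <- function(a, b, iv) {
  if (is.null(iv) || nrow(iv) == 0) return(0)
  sum(pmax(0, pmin(b, iv[, 2]) - pmax(a, iv[, 1])))
}
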