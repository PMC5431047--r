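#' Fisher exact test for pair-order count tables, batched
#'
#' Adds a `p_raw` column to a table of per-pair ordering counts: the
#' exact p-value of Fisher's test for the 2x2 table
#' `[[n1, n2], [m1, m2]]` (rows = phenotypes, columns = the two
#' orderings). The two-sided p-value is the fixed-margin sum of the
#' probabilities of all tables no more probable than the observed one
#' (with the conventional `1 + 1e-7` relative guard against floating-
#' point ties), so it matches `stats::fisher.test()` exactly -- but the
#' computation is batched: tables are grouped by their margins, and each
#' distinct margin triple is enumerated once, which makes genome-scale
#' pair counts (tens of millions of tables sharing a handful of margins)
#' feasible.
#'
#' Rows in which one phenotype has no informative samples
#' (`n1 + n2 == 0` or `m1 + m2 == 0`, i.e. all ties) cannot be tested;
#' they receive `p_raw = NA` and are counted in a message.
#'
#' @param counts Data frame with integer columns `n1`, `n2`, `m1`, `m2`
#'   (e.g. from [compute_pair_counts()]).
#' @param alternative `"two.sided"` (default), `"greater"` (case group
#'   shifted toward the `G_i > G_j` ordering) or `"less"`.
#' @return `counts` with a `p_raw` column appended.
#' @examples
#' fisher_pair_test(data.frame(n1 = 10, n2 = 0, m1 = 0, m2 = 10))
#' @export
fisher_pair_test <- function(counts,
                             alternative = c("two.sided", "greater",
                                             "less")) {
  alternative <- match.arg(alternative)
  need <- c("n1", "n2", "m1", "m2")
  if (!all(need %in% names(counts))) {
    abort("`counts` must have columns n1, n2, m1, m2.")
  }
  for (cn in need) {
    v <- counts[[cn]]
    if (!is.numeric(v) || anyNA(v) || any(v < 0)) {
      abort(paste0("Column ", cn, " must be nonnegative counts."))
    }
  }
  p <- fisher_batch(counts$n1, counts$n2, counts$m1, counts$m2,
                    alternative)
  n_skip <- sum(is.na(p))
  if (n_skip > 0) {
    inform(sprintf(
      "%d pair(s) with all ties in one phenotype skipped (p_raw = NA).",
      n_skip
    ))
  }
  dplyr::mutate(as_tibble(counts), p_raw = p)
}

# Vectorized Fisher exact p-values for many 2x2 tables.
# Tables are grouped by (row1 total, row2 total, col1 total); for each
# group the hypergeometric support is enumerated once and every member
# table's p-value is read off the sorted cumulative mass.
fisher_batch <- function(n1, n2, m1, m2, alternative = "two.sided") {
  r1 <- n1 + n2; r2 <- m1 + m2; c1 <- n1 + m1
  p <- rep(NA_real_, length(n1))
  ok <- r1 > 0 & r2 > 0
  if (!any(ok)) return(p)

  key <- paste(r1, r2, c1, sep = "_")
  idx_ok <- which(ok)
  groups <- split(idx_ok, key[idx_ok])
  relerr <- 1 + 1e-7

  for (idx in groups) {
    R1 <- r1[idx[1]]; R2 <- r2[idx[1]]; C1 <- c1[idx[1]]
    lo <- max(0L, C1 - R2); hi <- min(C1, R1)
    supp <- lo:hi
    d <- dhyper(supp, R1, R2, C1)
    obs <- n1[idx] - lo + 1L
    if (alternative == "two.sided") {
      o <- order(d)
      cs <- cumsum(d[o])
      # rank of the largest sorted mass still <= observed mass * relerr
      r <- findInterval(d[obs] * relerr, d[o])
      p[idx] <- pmin(cs[r], 1)
    } else if (alternative == "greater") {
      cs <- rev(cumsum(rev(d)))
      p[idx] <- pmin(cs[obs], 1)
    } else {
      cs <- cumsum(d)
      p[idx] <- pmin(cs[obs], 1)
    }
  }
  p
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a vector of p-values
#' (`stats::p.adjust(method = "BH")` with input validation). Adjusted
#' values are order-aligned with the input and capped at 1.
#'
#' @param p_values Numeric vector of probabilities in `[0, 1]`.
#' @return Numeric vector of the same length.
#' @examples
#' bh_adjust(c(0.005, 0.03, 0.04))   # 0.015 0.040 0.040
#' @export
bh_adjust <- function(p_values) {
  if (!is.numeric(p_values) || anyNA(p_values) ||
      any(p_values < 0 | p_values > 1)) {
    abort("p-values must all lie in [0, 1].")
  }
  p.adjust(p_values, method = "BH")
}
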