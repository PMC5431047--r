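#' Overlap and concordance counts of two DR pair tables
#'
#' A pair is *overlapped* if the same unordered gene pair is significant
#' in both tables with an unambiguous reversal direction in each;
#' it is *concordant* if the direction (Pattern1/Pattern2) agrees.
#' Both tables must use the canonical pair key (`gene_i < gene_j` in
#' sorted id order), which [detect_dr_pairs()] guarantees, and are
#' assumed to have been computed with case/control in the same semantic
#' orientation -- flipping the labels of one analysis flips its patterns
#' and would silently invert the concordance.
#'
#' @param table_a,table_b DR pair tables ([detect_dr_pairs()] output or
#'   data frames with `gene_i`, `gene_j`, `pattern`).
#' @return Tibble with one row: `M` (overlapped pairs) and `M1`
#'   (concordant pairs).
#' @export
overlap_and_count <- function(table_a, table_b) {
  a <- unambiguous_pairs(table_a)
  b <- unambiguous_pairs(table_b)
  j <- dplyr::inner_join(a, b, by = c("gene_i", "gene_j"),
                         suffix = c("_a", "_b"))
  tibble(M = nrow(j), M1 = sum(j$pattern_a == j$pattern_b))
}

unambiguous_pairs <- function(tb) {
  need <- c("gene_i", "gene_j", "pattern")
  if (!all(need %in% names(tb))) {
    abort("DR pair tables need columns gene_i, gene_j, pattern.")
  }
  tb <- as_tibble(tb)[, need]
  if (any(tb$gene_i >= tb$gene_j)) {
    abort("Pair keys must be canonical: gene_i < gene_j in sorted order.")
  }
  tb[tb$pattern %in% c("Pattern1", "Pattern2"), ]
}

#' Exact binomial reproducibility probability
#'
#' The probability of observing at least `M1` concordant pairs among `M`
#' overlapped pairs when each pair is independently concordant with
#' probability `p0`:
#' `P = sum_{i=M1}^{M} choose(M, i) p0^i (1-p0)^(M-i)`.
#' With two mutually exclusive reversal directions, a random pair is
#' concordant by chance with `p0 = 0.5`. Computed through the exact
#' binomial survival function (`stats::pbinom`), numerically stable for
#' `M` well beyond 1e7 -- no normal approximation.
#'
#' @param M Number of overlapped pairs (nonnegative integer).
#' @param M1 Number of concordant pairs, `0 <= M1 <= M`.
#' @param p0 Null concordance probability (default 0.5).
#' @return Upper-tail probability in `[0, 1]` (1 when `M = 0`).
#' @examples
#' binomial_concordance_p(10, 10)    # 0.5^10
#' binomial_concordance_p(4, 3)      # 5/16
#' @export
binomial_concordance_p <- function(M, M1, p0 = 0.5) {
  if (M1 > M) abort("`M1` cannot exceed `M`.")
  if (M < 0 || M1 < 0) abort("`M` and `M1` must be nonnegative.")
  if (p0 < 0 || p0 > 1) abort("`p0` must be in [0, 1].")
  pbinom(M1 - 1, M, p0, lower.tail = FALSE)
}

#' Reproducibility report for two DR pair tables
#'
#' Assembles the overlapped-pair count `M`, the concordant count `M1`,
#' the concordance ratio `M1/M`, and the exact binomial probability of
#' at least `M1` concordant pairs by chance
#' ([binomial_concordance_p()]). The two lists are flagged significantly
#' reproducible when that probability is below `alpha`.
#'
#' @param table_a,table_b DR pair tables (same orientation of
#'   case/control in both analyses).
#' @param p0 Null concordance probability (default 0.5).
#' @param alpha Significance level for the reproducibility call
#'   (default 0.05).
#' @return An object of class `reo_concordance` (see [tidy()] /
#'   [glance()] methods): list with `count_a`, `count_b`, `M`, `M1`,
#'   `ratio` (`NA` when `M = 0`), `p0`, `p_binomial`, `significant`.
#' @export
concordance_report <- function(table_a, table_b, p0 = 0.5,
                               alpha = 0.05) {
  cnt <- overlap_and_count(table_a, table_b)
  M <- cnt$M; M1 <- cnt$M1
  p <- binomial_concordance_p(M, M1, p0)
  structure(
    list(
      count_a = nrow(table_a),
      count_b = nrow(table_b),
      M = M,
      M1 = M1,
      ratio = if (M > 0) M1 / M else NA_real_,
      p0 = p0,
      p_binomial = p,
      significant = M > 0 && p < alpha
    ),
    class = "reo_concordance"
  )
}

#' @export
print.reo_concordance <- function(x, ...) {
  cat("<reo_concordance>\n")
  cat(sprintf("  DR pairs: %d vs %d; overlapped M = %d, concordant M1 = %d\n",
              x$count_a, x$count_b, x$M, x$M1))
  if (x$M > 0) {
    cat(sprintf("  concordance ratio M1/M = %.4f\n", x$ratio))
    cat(sprintf("  P(>= M1 concordant | p0 = %g) = %.4g%s\n",
                x$p0, x$p_binomial,
                if (x$significant) "  (significantly reproducible)" else ""))
  } else {
    cat("  no overlapped pairs; ratio undefined\n")
  }
  invisible(x)
}

#' @rdname concordance_report
#' @param x A `reo_concordance`.
#' @param ... Unused.
#' @method tidy reo_concordance
#' @export
tidy.reo_concordance <- function(x, ...) {
  tibble(
    count_a = x$count_a, count_b = x$count_b, M = x$M, M1 = x$M1,
    ratio = x$ratio, p0 = x$p0, p_binomial = x$p_binomial,
    significant = x$significant
  )
}

#' @rdname concordance_report
#' @method glance reo_concordance
#' @export
glance.reo_concordance <- function(x, ...) tidy(x)
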