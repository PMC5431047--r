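#' Background gene pairs of one pathway
#'
#' The number of unordered gene pairs formed by a pathway's background
#' genes: `g(g-1)/2` with `g` the size of the pathway's intersection
#' with the background gene set. A pathway of 24 background genes, for
#' instance, forms 276 pairs.
#'
#' @param pathway_genes Character vector of the pathway's gene ids.
#' @param background Character vector of background gene ids.
#' @return Number of pairs (double, since counts can exceed
#'   `.Machine$integer.max` at genome scale).
#' @examples
#' count_pathway_pairs(letters[1:5], letters[2:10])  # 4 genes -> 6 pairs
#' @export
count_pathway_pairs <- function(pathway_genes, background) {
  g <- length(intersect(unique(pathway_genes), background))
  g * (g - 1) / 2
}

#' Cumulative hypergeometric enrichment probability
#'
#' The probability of observing at least `x` DR pairs in a pathway with
#' `m` background pairs, when `k` of the `n` background pairs are DR:
#' `P = 1 - sum_{i=0}^{x-1} C(m,i) C(n-m,k-i) / C(n,k)`.
#' Computed via the hypergeometric survival function
#' (`stats::phyper(lower.tail = FALSE)`), stable for `n` up to tens of
#' millions of pairs. All arguments are vectorized.
#'
#' @param x Observed DR pairs in the pathway, `0 <= x <= min(m, k)`.
#' @param m Background pairs in the pathway.
#' @param k Total DR pairs.
#' @param n Total background pairs.
#' @return Probability in `[0, 1]` (1 when `x = 0`).
#' @examples
#' enrichment_p(3, 3, 5, 10)   # 1/12
#' @export
enrichment_p <- function(x, m, k, n) {
  if (any(m > n) || any(k > n)) abort("Need m <= n and k <= n.")
  if (any(x > pmin(m, k))) abort("Need x <= min(m, k).")
  if (any(x < 0 | m < 0 | k < 0 | n < 0)) {
    abort("Counts must be nonnegative.")
  }
  if (any(k - x > n - m)) {
    abort("Infeasible counts: k - x exceeds the out-of-pathway pairs.")
  }
  phyper(x - 1, m, n - m, k, lower.tail = FALSE)
}

#' Pathway enrichment of DR gene pairs
#'
#' For each pathway with at least two background genes, counts the DR
#' pairs whose *both* genes lie in the pathway (`x`), computes the
#' cumulative hypergeometric probability of at least `x` such pairs
#' among the pathway's `m = g(g-1)/2` background pairs
#' ([enrichment_p()]), adjusts across all tested pathways
#' (Benjamini-Hochberg, one family -- pathways with `x = 0` included),
#' and flags pathways with adjusted p below `fdr`.
#'
#' @param dr_table A [detect_dr_pairs()] table (its genes must all lie
#'   in the collection's background).
#' @param collection A [reo_collection][read_gmt()] with
#'   `background_genes` derived ([define_background()]).
#' @param fdr Adjusted-p significance threshold (default 0.05).
#' @return A `reo_enrichment`: tibble with columns `pathway`, `g`
#'   (background genes in pathway), `m`, `x`, `k`, `n`, `p_raw`,
#'   `p_adjusted`, `significant`, sorted by `(p_adjusted, pathway)`.
#'   Attributes also hold
#'   `N` (background genes), `n` (background pairs, `N(N-1)/2`), `k`
#'   (total DR pairs) and `fdr`; see [glance.reo_enrichment()].
#' @export
enrich_all <- function(dr_table, collection, fdr = 0.05) {
  stopifnot(inherits(collection, "reo_collection"))
  if (is.null(collection$background_genes)) {
    abort("Collection has no derived background; call define_background().")
  }
  bg <- collection$background_genes
  dr <- as_tibble(dr_table)
  outside <- setdiff(unique(c(dr$gene_i, dr$gene_j)), bg)
  if (length(outside)) {
    abort(paste0(
      "DR table references gene(s) outside the collection background ",
      "(dataset/collection mismatch): ",
      paste(head(outside, 5), collapse = ", ")
    ))
  }

  N <- length(bg)
  n <- N * (N - 1) / 2
  k <- nrow(dr)

  eff <- lapply(collection$sets, function(s) intersect(unique(s), bg))
  g <- lengths(eff)
  keep <- g >= 2L
  if (!any(keep)) {
    abort("No pathway has >= 2 background genes; nothing to test.")
  }
  eff <- eff[keep]
  res <- tibble(
    pathway = names(eff),
    g = as.integer(g[keep]),
    m = g[keep] * (g[keep] - 1) / 2,
    x = vapply(eff, function(s)
      sum(dr$gene_i %in% s & dr$gene_j %in% s), numeric(1)),
    k = k,
    n = n
  )
  res$p_raw <- enrichment_p(res$x, res$m, k, n)
  res$p_adjusted <- bh_adjust(res$p_raw)
  res$significant <- res$p_adjusted < fdr
  res <- dplyr::arrange(res, .data$p_adjusted, .data$pathway)

  for (nm in c("N", "n", "k", "fdr")) {
    attr(res, nm) <- switch(nm, N = N, n = n, k = k, fdr = fdr)
  }
  class(res) <- c("reo_enrichment", class(res))
  res
}

#' @export
print.reo_enrichment <- function(x, ...) {
  cat(sprintf(
    "<reo_enrichment> %d pathway(s) tested, %d significant (FDR < %s); N = %d background genes, k = %s DR pairs\n",
    nrow(x), sum(x$significant), format(attr(x, "fdr") %||% NA),
    attr(x, "N") %||% NA, format(attr(x, "k") %||% NA, big.mark = ",")
  ))
  NextMethod()
}

#' Tidy an enrichment table
#' @param x A `reo_enrichment`.
#' @param ... Unused.
#' @return Plain tibble.
#' @method tidy reo_enrichment
#' @export
tidy.reo_enrichment <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "reo_enrichment")
  for (nm in c("N", "n", "k", "fdr")) attr(out, nm) <- NULL
  out
}

#' One-row summary of an enrichment run
#' @param x A `reo_enrichment`.
#' @param ... Unused.
#' @return Tibble with one row: background size `N`, background pairs
#'   `n`, DR pairs `k`, pathways tested and significant, threshold.
#' @method glance reo_enrichment
#' @export
glance.reo_enrichment <- function(x, ...) {
  tibble(
    N = attr(x, "N"),
    n = attr(x, "n"),
    k = attr(x, "k"),
    n_pathways_tested = nrow(x),
    n_significant = sum(x$significant),
    fdr = attr(x, "fdr")
  )
}

#' Write an enrichment table as TSV
#' @param x A `reo_enrichment`.
#' @param path Output path.
#' @param params,input_paths Passed to [write_result_tsv()].
#' @return `x`, invisibly.
#' @export
write_enrichment <- function(x, path, params = list(),
                             input_paths = character()) {
  cols <- c("pathway", "g", "m", "x", "k", "n", "p_raw", "p_adjusted",
            "significant")
  write_result_tsv(as_tibble(x)[, cols], path, params, input_paths)
  invisible(x)
}
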