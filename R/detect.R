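#' Classify the direction of a differential ordering
#'
#' A pair whose case-group odds of the `G_i > G_j` ordering exceed the
#' control-group odds (`n1/n2 > m1/m2`) is "Pattern1"; the reverse is
#' "Pattern2". The comparison is made by cross-products
#' (`n1*m2` vs `n2*m1`) so zero denominators need no special casing;
#' exact equality of the cross-products is "ambiguous" (no reversal
#' direction).
#'
#' @param counts Data frame with columns `n1`, `n2`, `m1`, `m2`.
#' @return `counts` with a `pattern` column
#'   (`"Pattern1"`/`"Pattern2"`/`"ambiguous"`) appended.
#' @examples
#' assign_pattern(data.frame(n1 = 9, n2 = 1, m1 = 2, m2 = 8))  # Pattern1
#' @export
assign_pattern <- function(counts) {
  need <- c("n1", "n2", "m1", "m2")
  if (!all(need %in% names(counts))) {
    abort("`counts` must have columns n1, n2, m1, m2.")
  }
  cp1 <- as.numeric(counts$n1) * as.numeric(counts$m2)
  cp2 <- as.numeric(counts$n2) * as.numeric(counts$m1)
  dplyr::mutate(
    as_tibble(counts),
    pattern = dplyr::case_when(
      cp1 > cp2 ~ "Pattern1",
      cp1 < cp2 ~ "Pattern2",
      TRUE ~ "ambiguous"
    )
  )
}

#' Detect differentially ranked (DR) gene pairs
#'
#' The core case/control comparison: for every unordered pair of
#' background genes the per-phenotype ordering counts are tested for
#' association with phenotype (Fisher exact test), p-values are
#' Benjamini-Hochberg adjusted across *all* tested pairs, and pairs with
#' adjusted p below `fdr` are reported with their reversal direction
#' (Pattern1/Pattern2). Pairs with all ties in one phenotype are skipped
#' before adjustment (their count is recorded).
#'
#' When a collection is supplied the analysis is restricted to its
#' background genes (measured genes annotated in at least one set),
#' taken in sorted id order -- the canonical pair ordering, so tables
#' from different runs align without remapping.
#'
#' @param dataset A [reo_dataset()] with >= 2 samples per phenotype.
#' @param collection Optional [reo_collection][read_gmt()]; if its
#'   background is not yet derived, [define_background()] is applied.
#'   `NULL` analyses all genes of the dataset.
#' @param fdr Adjusted-p threshold for calling a pair DR (default 0.05).
#' @param block_size Passed to [compute_pair_counts()].
#' @param alternative Sidedness of the Fisher test (two-sided default).
#' @return A `dr_pair_table`: tibble with columns `gene_i`, `gene_j`,
#'   `n1`, `n2`, `m1`, `m2`, `p_raw`, `p_adjusted`, `pattern`, holding
#'   only significant pairs, sorted by `(p_adjusted, gene_i, gene_j)`.
#'   Attributes record the numbers of genes, tested/skipped pairs, the
#'   sample sizes and the threshold; see [glance.dr_pair_table()].
#' @examples
#' sim <- simulate_two_phenotype(simulation_spec(
#'   n_genes = 40, n_case = 15, n_control = 15, n_planted = 3, seed = 1
#' ))
#' detect_dr_pairs(sim$dataset)
#' @export
detect_dr_pairs <- function(dataset, collection = NULL, fdr = 0.05,
                            block_size = 1024L,
                            alternative = c("two.sided", "greater",
                                            "less")) {
  alternative <- match.arg(alternative)
  stopifnot(inherits(dataset, "reo_dataset"))
  if (!is.numeric(fdr) || length(fdr) != 1 || fdr < 0 || fdr > 1) {
    abort("`fdr` must be a single value in [0, 1].")
  }
  check_min_samples(dataset)

  if (!is.null(collection)) {
    if (is.null(collection$background_genes)) {
      collection <- define_background(dataset, collection)
    }
    genes <- collection$background_genes  # already sorted
    if (length(setdiff(genes, rownames(dataset$values)))) {
      abort("Collection background contains genes not in the dataset.")
    }
  } else {
    genes <- sort(rownames(dataset$values))
  }

  counts <- compute_pair_counts(dataset, genes, block_size)
  testable <- counts$n1 + counts$n2 > 0 & counts$m1 + counts$m2 > 0
  n_skipped <- sum(!testable)
  tested <- counts[testable, ]
  tested$p_raw <- fisher_batch(tested$n1, tested$n2, tested$m1,
                               tested$m2, alternative)
  tested$p_adjusted <- bh_adjust(tested$p_raw)

  sig <- tested[tested$p_adjusted < fdr, , drop = FALSE]
  sig <- assign_pattern(sig)
  sig <- dplyr::arrange(sig, .data$p_adjusted, .data$gene_i, .data$gene_j)

  new_dr_pair_table(
    sig,
    n_genes = length(genes),
    n_pairs_tested = nrow(tested),
    n_pairs_skipped = n_skipped,
    n_case = length(phenotype_samples(dataset, "case")),
    n_control = length(phenotype_samples(dataset, "control")),
    fdr = fdr,
    alternative = alternative
  )
}

new_dr_pair_table <- function(df, ...) {
  meta <- list(...)
  out <- as_tibble(df)
  for (nm in names(meta)) attr(out, nm) <- meta[[nm]]
  class(out) <- c("dr_pair_table", class(out))
  out
}

#' @export
print.dr_pair_table <- function(x, ...) {
  cat(sprintf(
    "<dr_pair_table> %d DR pair(s) of %s tested (FDR < %s, %s)\n",
    nrow(x), format(attr(x, "n_pairs_tested") %||% NA, big.mark = ","),
    format(attr(x, "fdr") %||% NA),
    attr(x, "alternative") %||% "two.sided"
  ))
  NextMethod()
}

#' Tidy a DR pair table
#' @param x A `dr_pair_table`.
#' @param ... Unused.
#' @return Plain tibble of the significant pairs.
#' @method tidy dr_pair_table
#' @export
tidy.dr_pair_table <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "dr_pair_table")
  for (nm in c("n_genes", "n_pairs_tested", "n_pairs_skipped", "n_case",
               "n_control", "fdr", "alternative")) {
    attr(out, nm) <- NULL
  }
  out
}

#' One-row summary of a DR pair detection run
#' @param x A `dr_pair_table`.
#' @param ... Unused.
#' @return Tibble with one row: gene/pair counts, sample sizes,
#'   threshold, and the Pattern1/Pattern2 split.
#' @method glance dr_pair_table
#' @export
glance.dr_pair_table <- function(x, ...) {
  tibble(
    n_genes = attr(x, "n_genes"),
    n_pairs_tested = attr(x, "n_pairs_tested"),
    n_pairs_skipped = attr(x, "n_pairs_skipped"),
    n_dr_pairs = nrow(x),
    n_pattern1 = sum(x$pattern == "Pattern1"),
    n_pattern2 = sum(x$pattern == "Pattern2"),
    n_case = attr(x, "n_case"),
    n_control = attr(x, "n_control"),
    fdr = attr(x, "fdr"),
    alternative = attr(x, "alternative")
  )
}

#' Write / read a DR pair table as TSV
#'
#' Columns, in order: gene_i, gene_j, n1, n2, m1, m2, p_raw, p_adjusted,
#' pattern. [write_dr_pairs()] prepends the provenance comment line of
#' [write_result_tsv()].
#'
#' @param x A `dr_pair_table` (or compatible data frame).
#' @param path Output/input TSV path.
#' @param params,input_paths Passed to [write_result_tsv()].
#' @return The table, invisibly (write) or as a tibble (read).
#' @export
write_dr_pairs <- function(x, path, params = list(),
                           input_paths = character()) {
  cols <- c("gene_i", "gene_j", "n1", "n2", "m1", "m2", "p_raw",
            "p_adjusted", "pattern")
  write_result_tsv(as_tibble(x)[, cols], path, params, input_paths)
  invisible(x)
}

#' @rdname write_dr_pairs
#' @export
read_dr_pairs <- function(path) {
  tb <- read_result_tsv(path)
  need <- c("gene_i", "gene_j", "pattern")
  if (!all(need %in% names(tb))) {
    abort(paste0(path, " is not a DR pair table (missing ",
                 paste(setdiff(need, names(tb)), collapse = ", "), ")."))
  }
  new_dr_pair_table(tb)
}
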