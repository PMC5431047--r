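#' Relative expression ordering of one gene pair in one sample
#'
#' The within-sample ordering of a gene pair is `"greater"` if the first
#' gene's value exceeds the second's, `"less"` if it is below it, and
#' `"tie"` on exact equality. Tied pairs are excluded from the
#' phenotype counts (they contribute to neither frequency). Equality is
#' exact: no epsilon is applied.
#'
#' @param values_i,values_j Finite numeric vectors (recycled to common
#'   length): the two genes' values in one or more samples.
#' @return Character vector in `{"greater", "less", "tie"}`.
#' @examples
#' reo_of_sample(5, 3)           # "greater"
#' reo_of_sample(2, 2)           # "tie" -- excluded from counts
#' @export
reo_of_sample <- function(values_i, values_j) {
  if (!is.numeric(values_i) || !is.numeric(values_j) ||
      any(!is.finite(values_i)) || any(!is.finite(values_j))) {
    abort("Expression values must be finite numbers.")
  }
  out <- rep("tie", length.out = max(length(values_i), length(values_j)))
  out[values_i > values_j] <- "greater"
  out[values_i < values_j] <- "less"
  out
}

#' Per-pair ordering counts in the two phenotypes
#'
#' For every unordered gene pair (i, j), i before j in `genes` order,
#' counts the samples of each phenotype in which gene i's value exceeds
#' gene j's (`n1` cases, `m1` controls) and in which it is below it
#' (`n2`, `m2`). Samples where the two values are exactly equal are
#' excluded from that pair's counts, so `n1 + n2 <= n_case` and
#' `m1 + m2 <= n_control`.
#'
#' Pairs are produced in blocks of `block_size` genes so peak memory is
#' proportional to `block_size^2 + block_size * n_samples`, never to the
#' total pair count; the result is identical for any `block_size`.
#'
#' @param dataset A [reo_dataset()].
#' @param genes Ordered character vector of gene ids to analyse
#'   (default: all genes of the dataset in sorted id order, the canonical
#'   pair ordering). Must have >= 2 entries, all present in the dataset.
#' @param block_size Genes per block (default 1024).
#' @return Tibble with columns `gene_i`, `gene_j`, `n1`, `n2`, `m1`,
#'   `m2`; one row per pair, `choose(length(genes), 2)` rows in total,
#'   ordered by position of `gene_i` then `gene_j` in `genes`.
#' @examples
#' m <- matrix(c(2, 1, 3, 5, 1, 2, 0, 4), nrow = 2,
#'             dimnames = list(c("A", "B"), paste0("s", 1:4)))
#' ds <- reo_dataset(m, c(s1 = "case", s2 = "case",
#'                        s3 = "control", s4 = "control"))
#' compute_pair_counts(ds)   # n1=1, n2=1, m1=0, m2=2
#' @export
compute_pair_counts <- function(dataset, genes = NULL, block_size = 1024L) {
  stopifnot(inherits(dataset, "reo_dataset"))
  if (is.null(genes)) genes <- sort(rownames(dataset$values))
  genes <- as.character(genes)
  if (length(genes) < 2) abort("Need at least 2 genes to form pairs.")
  if (anyDuplicated(genes)) abort("`genes` must not contain duplicates.")
  missing_g <- setdiff(genes, rownames(dataset$values))
  if (length(missing_g)) {
    abort(paste0("Genes absent from the dataset: ",
                 paste(head(missing_g, 5), collapse = ", ")))
  }
  block_size <- as.integer(block_size)
  if (is.na(block_size) || block_size < 1L) {
    abort("`block_size` must be a positive integer.")
  }

  x_case <- dataset$values[genes,
                           phenotype_samples(dataset, "case"),
                           drop = FALSE]
  x_ctrl <- dataset$values[genes,
                           phenotype_samples(dataset, "control"),
                           drop = FALSE]

  g <- length(genes)
  starts <- seq.int(1L, g, by = block_size)
  blocks <- lapply(starts, function(s) s:min(s + block_size - 1L, g))

  out <- vector("list", length(blocks) * (length(blocks) + 1L) / 2L)
  pos <- 0L
  for (bi in seq_along(blocks)) {
    for (bj in bi:length(blocks)) {
      pos <- pos + 1L
      out[[pos]] <- block_pair_counts(
        x_case, x_ctrl, blocks[[bi]], blocks[[bj]], genes
      )
    }
  }
  res <- dplyr::bind_rows(out)
  res[order(match(res$gene_i, genes), match(res$gene_j, genes)), ]
}

# Counts for all pairs (i, j) with i in rows `I`, j in rows `J`, i < j.
block_pair_counts <- function(x_case, x_ctrl, I, J, genes) {
  li <- length(I); lj <- length(J)
  gt_case <- matrix(0L, li, lj); eq_case <- matrix(0L, li, lj)
  gt_ctrl <- matrix(0L, li, lj); eq_ctrl <- matrix(0L, li, lj)
  for (s in seq_len(ncol(x_case))) {
    xi <- x_case[I, s]; xj <- x_case[J, s]
    gt_case <- gt_case + outer(xi, xj, ">")
    eq_case <- eq_case + outer(xi, xj, "==")
  }
  for (s in seq_len(ncol(x_ctrl))) {
    xi <- x_ctrl[I, s]; xj <- x_ctrl[J, s]
    gt_ctrl <- gt_ctrl + outer(xi, xj, ">")
    eq_ctrl <- eq_ctrl + outer(xi, xj, "==")
  }
  if (I[1] == J[1]) {
    sel <- which(upper.tri(gt_case), arr.ind = TRUE)
  } else {
    sel <- as.matrix(expand.grid(row = seq_len(li), col = seq_len(lj)))
  }
  ii <- I[sel[, 1]]; jj <- J[sel[, 2]]
  n  <- ncol(x_case); m <- ncol(x_ctrl)
  n1 <- gt_case[sel]; m1 <- gt_ctrl[sel]
  tibble(
    gene_i = genes[ii], gene_j = genes[jj],
    n1 = as.integer(n1),
    n2 = as.integer(n - n1 - eq_case[sel]),
    m1 = as.integer(m1),
    m2 = as.integer(m - m1 - eq_ctrl[sel])
  )
}
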