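#' Construct a two-phenotype expression dataset
#'
#' Bundles a gene-by-sample expression matrix with a case/control phenotype
#' assignment. Only within-sample relative orderings of the values are ever
#' used downstream, so the matrix may be on any scale (raw, log, RMA,
#' TPM, ...) and needs no between-sample normalization.
#'
#' @param values Numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids). No missing values.
#' @param phenotype Data frame with columns `sample_id` and `phenotype`
#'   (values `"case"` or `"control"`), or a named character vector
#'   `sample_id -> label`. Every column of `values` must be assigned
#'   exactly one label.
#'
#' @return An object of class `reo_dataset`: a list with elements
#'   `values` (the matrix) and `phenotype` (a tibble with columns
#'   `sample_id`, `phenotype`).
#'
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(c("g1", "g2", "g3"), paste0("s", 1:4)))
#' ds <- reo_dataset(m, c(s1 = "case", s2 = "case",
#'                        s3 = "control", s4 = "control"))
#' ds
#' @export
reo_dataset <- function(values, phenotype) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix (genes x samples).")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("`values` must have rownames (gene ids) and colnames (sample ids).")
  }
  if (anyDuplicated(colnames(values))) {
    abort("Sample ids (colnames) must be unique.")
  }
  if (anyDuplicated(rownames(values))) {
    abort(paste0(
      "Gene ids (rownames) must be unique; ",
      "use read_expression() to collapse duplicates."
    ))
  }
  if (anyNA(values) || any(!is.finite(values))) {
    abort("`values` must contain only finite numbers (no NA/NaN/Inf).")
  }

  if (is.data.frame(phenotype)) {
    pheno <- as_tibble(phenotype[, c("sample_id", "phenotype")])
  } else if (!is.null(names(phenotype))) {
    pheno <- tibble(sample_id = names(phenotype),
                    phenotype = unname(as.character(phenotype)))
  } else {
    abort("`phenotype` must be a data frame or a named character vector.")
  }
  pheno$phenotype <- as.character(pheno$phenotype)
  bad <- setdiff(unique(pheno$phenotype), c("case", "control"))
  if (length(bad)) {
    abort(paste0("Phenotype labels must be 'case' or 'control'; found: ",
                 paste(bad, collapse = ", ")))
  }
  if (anyDuplicated(pheno$sample_id)) {
    abort("Each sample may appear only once in the phenotype assignment.")
  }
  missing_ph <- setdiff(colnames(values), pheno$sample_id)
  if (length(missing_ph)) {
    abort(paste0("Samples without a phenotype label: ",
                 paste(head(missing_ph, 5), collapse = ", ")))
  }
  extra <- setdiff(pheno$sample_id, colnames(values))
  if (length(extra)) {
    abort(paste0("Phenotype file lists samples absent from the matrix: ",
                 paste(head(extra, 5), collapse = ", ")))
  }
  pheno <- pheno[match(colnames(values), pheno$sample_id), ]

  structure(list(values = values, phenotype = pheno),
            class = "reo_dataset")
}

#' @export
print.reo_dataset <- function(x, ...) {
  nc <- sum(x$phenotype$phenotype == "case")
  nm <- sum(x$phenotype$phenotype == "control")
  cat(sprintf(
    "<reo_dataset> %d genes x %d samples (%d case, %d control)\n",
    nrow(x$values), ncol(x$values), nc, nm
  ))
  invisible(x)
}

#' @export
dim.reo_dataset <- function(x) dim(x$values)

#' Sample ids of one phenotype
#' @param dataset A [reo_dataset()].
#' @param phenotype `"case"` or `"control"`.
#' @return Character vector of sample ids.
#' @export
phenotype_samples <- function(dataset, phenotype = c("case", "control")) {
  phenotype <- match.arg(phenotype)
  dataset$phenotype$sample_id[dataset$phenotype$phenotype == phenotype]
}

check_min_samples <- function(dataset, n_min = 2L) {
  nc <- length(phenotype_samples(dataset, "case"))
  nm <- length(phenotype_samples(dataset, "control"))
  if (nc < n_min || nm < n_min) {
    abort(sprintf(
      "Need at least %d case and %d control samples (have %d case, %d control).",
      n_min, n_min, nc, nm
    ))
  }
  invisible(dataset)
}

#' Merge case samples with controls from another experiment
#'
#' Combines two datasets column-wise on their shared gene ids — the
#' one-sided integration use case, where a disease-only matrix borrows
#' normal controls measured by an independent study. Because downstream
#' analysis uses only within-sample orderings, the two matrices may be on
#' entirely different scales.
#'
#' @param a,b Two [reo_dataset()] objects. Sample ids must not collide.
#' @param min_shared_genes Hard floor on the gene-id intersection; fewer
#'   shared genes suggests an identifier-space mismatch and raises an
#'   error. Default 1000.
#' @return A [reo_dataset()] restricted to the shared genes (in sorted
#'   id order), containing all samples of both inputs.
#' @export
merge_datasets <- function(a, b, min_shared_genes = 1000L) {
  stopifnot(inherits(a, "reo_dataset"), inherits(b, "reo_dataset"))
  shared <- sort(intersect(rownames(a$values), rownames(b$values)))
  if (length(shared) < min_shared_genes) {
    abort(sprintf(
      "Only %d gene ids shared between the two matrices (floor: %d).",
      length(shared), min_shared_genes
    ))
  }
  dup <- intersect(colnames(a$values), colnames(b$values))
  if (length(dup)) {
    abort(paste0("Sample ids present in both datasets: ",
                 paste(head(dup, 5), collapse = ", ")))
  }
  values <- cbind(a$values[shared, , drop = FALSE],
                  b$values[shared, , drop = FALSE])
  pheno <- dplyr::bind_rows(a$phenotype, b$phenotype)
  reo_dataset(values, pheno)
}
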