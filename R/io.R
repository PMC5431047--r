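#' Read an expression matrix and phenotype file
#'
#' Reads a tab-separated gene-by-sample expression table (first column
#' gene id, header row of sample ids) together with a two-column
#' phenotype file (`sample_id<TAB>label`, label `case` or `control`).
#' Duplicated gene ids are collapsed by keeping, per id, the row with the
#' largest mean expression across all samples (the usual probe-collapse
#' convention); rows containing missing values are dropped. Both actions
#' emit a warning. Samples present in the matrix but absent from the
#' phenotype file are dropped with a warning; a phenotype entry naming a
#' sample not in the matrix is an error.
#'
#' @param path Expression TSV ('.' decimal separator, UTF-8).
#' @param phenotype_path Phenotype TSV. A header line is tolerated (it is
#'   recognised by its second field not being `case`/`control`).
#' @param require_both If `TRUE` (default) it is an error for either
#'   phenotype to have fewer than 2 samples; set `FALSE` when reading a
#'   one-phenotype matrix that will be merged with controls from
#'   another file ([merge_datasets()]).
#' @return A [reo_dataset()]. Row order follows the file (after duplicate
#'   collapse, which keeps each id's first surviving position).
#' @export
read_expression <- function(path, phenotype_path, require_both = TRUE) {
  if (!file.exists(path)) abort(paste0("Expression file not found: ", path))
  # cells are parsed with as.numeric (strtod), which is correctly
  # rounded, so written doubles survive a round trip bit-exactly
  tb <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  )
  if (ncol(tb) < 2) {
    abort(paste0("Malformed expression file (need gene id + >=1 sample): ",
                 path))
  }
  gene_ids <- tb[[1]]
  values <- matrix(NA_real_, nrow(tb), ncol(tb) - 1L,
                   dimnames = list(gene_ids, colnames(tb)[-1]))
  for (j in 2:ncol(tb)) {
    cell <- tb[[j]]
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(is.na(num) & !is.na(cell) & cell != "" &
                   toupper(cell) != "NA")
    if (length(bad)) {
      abort(sprintf("Non-numeric cell in %s at line %d, column %d.",
                    path, bad[1] + 1L, j))
    }
    values[, j - 1L] <- num
  }

  n_miss <- sum(!stats::complete.cases(values))
  if (n_miss > 0) {
    warn(sprintf("Dropping %d row(s) with missing values from %s.",
                 n_miss, path))
    values <- values[stats::complete.cases(values), , drop = FALSE]
  }

  if (anyDuplicated(rownames(values))) {
    dup_ids <- unique(rownames(values)[duplicated(rownames(values))])
    warn(sprintf(
      "Collapsing %d duplicated gene id(s) (keeping the row with the largest mean): %s%s",
      length(dup_ids), paste(head(dup_ids, 3), collapse = ", "),
      if (length(dup_ids) > 3) ", ..." else ""
    ))
    keep <- order(rowMeans(values), decreasing = TRUE)
    values <- values[keep, , drop = FALSE]
    values <- values[!duplicated(rownames(values)), , drop = FALSE]
    # restore file order of the surviving rows
    values <- values[order(match(rownames(values), gene_ids)), , drop = FALSE]
  }

  pheno <- read_phenotype(phenotype_path)
  extra <- setdiff(pheno$sample_id, colnames(values))
  if (length(extra)) {
    abort(paste0("Phenotype file ", phenotype_path,
                 " lists sample(s) absent from the matrix: ",
                 paste(head(extra, 5), collapse = ", ")))
  }
  unlabeled <- setdiff(colnames(values), pheno$sample_id)
  if (length(unlabeled)) {
    warn(paste0("Dropping ", length(unlabeled),
                " sample(s) without a phenotype label: ",
                paste(head(unlabeled, 5), collapse = ", ")))
    values <- values[, setdiff(colnames(values), unlabeled), drop = FALSE]
  }

  pheno <- pheno[pheno$sample_id %in% colnames(values), ]
  ds <- reo_dataset(values, pheno)
  if (require_both) check_min_samples(ds)
  ds
}

#' Read a two-column phenotype file
#' @param path TSV with columns sample_id, label (`case`/`control`).
#' @return Tibble with columns `sample_id`, `phenotype`.
#' @export
read_phenotype <- function(path) {
  if (!file.exists(path)) abort(paste0("Phenotype file not found: ", path))
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) abort(paste0("Empty phenotype file: ", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 2)) {
    abort(sprintf("Phenotype file %s line %d has fewer than 2 fields.",
                  path, which(nf < 2)[1]))
  }
  sample_id <- vapply(fields, `[[`, character(1), 1L)
  label <- trimws(vapply(fields, `[[`, character(1), 2L))
  if (length(label) > 1 && !label[1] %in% c("case", "control")) {
    sample_id <- sample_id[-1]  # header line
    label <- label[-1]
  }
  bad <- which(!label %in% c("case", "control"))
  if (length(bad)) {
    abort(sprintf(
      "Phenotype file %s: label '%s' (sample '%s') is not case/control.",
      path, label[bad[1]], sample_id[bad[1]]
    ))
  }
  tibble(sample_id = sample_id, phenotype = label)
}

#' Write an expression dataset as TSV (with companion phenotype file)
#'
#' Values are written with 17 significant digits so that a write/read
#' round trip reproduces every double bit-exactly.
#'
#' @param dataset A [reo_dataset()].
#' @param path Output expression TSV.
#' @param phenotype_path Optional output phenotype TSV.
#' @return `dataset`, invisibly.
#' @export
write_expression <- function(dataset, path, phenotype_path = NULL) {
  stopifnot(inherits(dataset, "reo_dataset"))
  v <- dataset$values
  body <- vapply(seq_len(nrow(v)), function(i) {
    paste(c(rownames(v)[i], sprintf("%.17g", v[i, ])), collapse = "\t")
  }, character(1))
  readr::write_lines(
    c(paste(c("gene_id", colnames(v)), collapse = "\t"), body), path
  )
  if (!is.null(phenotype_path)) {
    readr::write_lines(
      paste(dataset$phenotype$sample_id, dataset$phenotype$phenotype,
            sep = "\t"),
      phenotype_path
    )
  }
  invisible(dataset)
}

#' Read a GMT gene-set file
#'
#' Standard tab-separated GMT dialect: each line is
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. Duplicate genes within a
#' line are deduplicated; a duplicated set name is an error; a line with
#' fewer than three fields is an error (reported with its line number).
#'
#' @param path GMT file.
#' @param source_label Free-text label stored on the collection
#'   (defaults to the file name).
#' @return An object of class `reo_collection`: list with `sets` (named
#'   list of character vectors), `background_genes` (`NULL` until
#'   [define_background()] is called) and `source_label`.
#' @export
read_gmt <- function(path, source_label = basename(path)) {
  if (!file.exists(path)) abort(paste0("GMT file not found: ", path))
  lines <- readr::read_lines(path, progress = FALSE)
  keep <- nzchar(trimws(lines))
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    abort(sprintf("GMT file %s line %d has fewer than 3 fields.",
                  path, lineno[which(nf < 3)[1]]))
  }
  nm <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(nm)) {
    abort(paste0("Duplicate pathway name(s) in ", path, ": ",
                 paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nm
  new_collection(sets, source_label = source_label)
}

new_collection <- function(sets, background_genes = NULL,
                           source_label = "") {
  structure(
    list(sets = sets, background_genes = background_genes,
         source_label = source_label),
    class = "reo_collection"
  )
}

#' @export
print.reo_collection <- function(x, ...) {
  cat(sprintf("<reo_collection> %d gene sets (%s)\n",
              length(x$sets), x$source_label))
  if (is.null(x$background_genes)) {
    cat("  background: not derived (call define_background())\n")
  } else {
    n <- length(x$background_genes)
    cat(sprintf("  background: %d genes, %d gene pairs\n",
                n, n * (n - 1) / 2))
  }
  invisible(x)
}

#' Derive the analysis background of a collection
#'
#' The background genes are the measured genes annotated in at least one
#' set of the collection: `intersect(rownames(dataset), union(sets))`.
#' All pair counting and enrichment is performed on this background; the
#' total background pair count is `N(N-1)/2` for `N` background genes.
#'
#' @param dataset A [reo_dataset()] (defines the measured genes).
#' @param collection A [read_gmt()] collection.
#' @return The collection with `background_genes` filled in (sorted).
#' @export
define_background <- function(dataset, collection) {
  stopifnot(inherits(dataset, "reo_dataset"),
            inherits(collection, "reo_collection"))
  annotated <- unique(unlist(collection$sets, use.names = FALSE))
  bg <- sort(intersect(rownames(dataset$values), annotated))
  if (!length(bg)) {
    abort(paste0(
      "No overlap between measured gene ids and pathway gene ids; ",
      "the two id spaces appear to be different."
    ))
  }
  collection$background_genes <- bg
  collection
}

#' Write a GMT file
#' @param collection A `reo_collection`.
#' @param path Output path.
#' @return `collection`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "reo_collection"))
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, "na", collection$sets[[nm]]), collapse = "\t")
  }, character(1))
  readr::write_lines(lines, path)
  invisible(collection)
}

#' Write a result table as TSV with a provenance line
#'
#' The first line is a `#`-prefixed comment carrying the tool version,
#' the run parameters and md5 hashes of the inputs; the second line is
#' the header. No timestamp is written, so identical runs produce
#' byte-identical files.
#'
#' @param df Data frame to write.
#' @param path Output path.
#' @param params Named list echoed into the provenance line.
#' @param input_paths Files to hash into the provenance line.
#' @return `df`, invisibly.
#' @export
write_result_tsv <- function(df, path, params = list(),
                             input_paths = character()) {
  ver <- as.character(utils::packageVersion("reopairs"))
  ptxt <- if (length(params)) {
    paste(names(params), vapply(params, function(x)
      paste(format(x), collapse = ","), character(1)),
      sep = "=", collapse = " ")
  } else ""
  htxt <- if (length(input_paths)) {
    h <- tools::md5sum(input_paths)
    paste(basename(names(h)), unname(h), sep = ":", collapse = " ")
  } else ""
  readr::write_lines(
    sprintf("# reopairs %s | %s | %s", ver, ptxt, htxt), path
  )
  readr::write_tsv(df, path, append = TRUE, col_names = TRUE,
                   progress = FALSE)
  invisible(df)
}

#' Read a result table written by [write_result_tsv()]
#' @param path TSV path (leading `#` comment lines are skipped).
#' @return Tibble.
#' @export
read_result_tsv <- function(path) {
  readr::read_tsv(path, comment = "#", progress = FALSE,
                  show_col_types = FALSE)
}
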