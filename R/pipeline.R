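#' Run the full detection + enrichment pipeline
#'
#' Wires the stages end to end: read the expression matrix and
#' phenotype file (optionally merging a second, control-only matrix on
#' shared gene ids -- the one-sided integration use case), derive the
#' pathway background, detect DR gene pairs, test pathway enrichment,
#' and write `dr_pairs.tsv`, `enrichment.tsv` and `report.json` to
#' `out_dir`. Outputs carry a provenance line (version, parameters,
#' input hashes) and are byte-identical across repeated runs on the
#' same inputs.
#'
#' @param expr Expression TSV (genes x samples).
#' @param pheno Phenotype TSV for the samples of `expr` (and of
#'   `control_expr` if given -- a single phenotype file covers all
#'   samples).
#' @param gmt GMT gene-set file.
#' @param out_dir Output directory (created if missing).
#' @param control_expr Optional second expression TSV whose samples are
#'   merged with `expr` on shared gene ids before analysis.
#' @param fdr_pairs,fdr_pathways Significance thresholds (defaults
#'   0.05).
#' @param alternative Fisher-test sidedness.
#' @param block_size Passed to [compute_pair_counts()].
#' @param min_shared_genes Floor on the gene-id intersection when
#'   merging two matrices (default 1000).
#' @return Invisibly, a list with `dr_pairs` (the
#'   [dr_pair_table][detect_dr_pairs()]), `enrichment` (the
#'   [reo_enrichment][enrich_all()] table) and `report` (the list
#'   written to `report.json`).
#' @export
run_pipeline <- function(expr, pheno, gmt, out_dir,
                         control_expr = NULL,
                         fdr_pairs = 0.05, fdr_pathways = 0.05,
                         alternative = "two.sided",
                         block_size = 1024L,
                         min_shared_genes = 1000L) {
  for (thr in c(fdr_pairs, fdr_pathways)) {
    if (!is.numeric(thr) || thr <= 0 || thr > 1) {
      abort("FDR thresholds must lie in (0, 1].")
    }
  }
  inputs <- c(expr, pheno, gmt, control_expr)
  missing_f <- inputs[!file.exists(inputs)]
  if (length(missing_f)) {
    abort(paste0("Input file(s) not found: ",
                 paste(missing_f, collapse = ", ")))
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  full_pheno <- read_phenotype(pheno)
  dataset <- if (is.null(control_expr)) {
    read_expression(expr, pheno)
  } else {
    ds_a <- read_expression_subset(expr, full_pheno)
    ds_b <- read_expression_subset(control_expr, full_pheno)
    merge_datasets(ds_a, ds_b, min_shared_genes)
  }
  check_min_samples(dataset)

  collection <- define_background(dataset, read_gmt(gmt))
  dr <- detect_dr_pairs(dataset, collection, fdr = fdr_pairs,
                        block_size = block_size,
                        alternative = alternative)
  enr <- enrich_all(dr, collection, fdr = fdr_pathways)

  params <- list(fdr_pairs = fdr_pairs, fdr_pathways = fdr_pathways,
                 alternative = alternative, block_size = block_size)
  write_dr_pairs(dr, file.path(out_dir, "dr_pairs.tsv"),
                 params, inputs)
  write_enrichment(enr, file.path(out_dir, "enrichment.tsv"),
                   params, inputs)

  report <- c(
    list(
      tool = "reopairs",
      version = as.character(utils::packageVersion("reopairs")),
      inputs = as.list(setNames(unname(tools::md5sum(inputs)),
                                basename(inputs)))
    ),
    params,
    list(min_shared_genes = min_shared_genes),
    as.list(glance(dr)),
    list(
      n_background_genes = attr(enr, "N"),
      n_background_pairs = attr(enr, "n"),
      n_pathways_tested = nrow(enr),
      n_pathways_significant = sum(enr$significant)
    )
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(dr_pairs = dr, enrichment = enr, report = report))
}

# Read an expression TSV keeping only its samples that appear in the
# (already loaded) phenotype table; used when case and control matrices
# come from different files but share one phenotype file.
read_expression_subset <- function(path, pheno_tb) {
  hdr <- strsplit(readr::read_lines(path, n_max = 1), "\t",
                  fixed = TRUE)[[1]][-1]
  keep <- pheno_tb[pheno_tb$sample_id %in% hdr, ]
  if (!nrow(keep)) {
    abort(paste0("No sample of ", path,
                 " appears in the phenotype file."))
  }
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  readr::write_lines(
    paste(keep$sample_id, keep$phenotype, sep = "\t"), tmp
  )
  suppressWarnings(read_expression(path, tmp, require_both = FALSE))
}

#' Label-permutation null harness
#'
#' Repeats detection + enrichment with phenotype labels randomly
#' reassigned to the pooled samples (group sizes preserved) and
#' summarises how many pathways reach significance under each shuffle.
#' On data with a genuine phenotype signal the permuted runs should
#' yield far fewer significant pathways than the unpermuted analysis;
#' on null data both should be near zero.
#'
#' @param dataset A [reo_dataset()] with >= 4 samples pooled.
#' @param collection A collection (background derived or derivable).
#' @param n_permutations Number of label shuffles (>= 1).
#' @param seed Integer seed for the shuffles.
#' @param fdr_pairs,fdr_pathways Thresholds as in [run_pipeline()].
#' @param block_size Passed to [compute_pair_counts()].
#' @return Tibble with one row per permutation (`permutation`,
#'   `n_dr_pairs`, `n_significant_pathways`), with a `summary`
#'   attribute (one-row tibble of mean and 0/25/50/75/100% quantiles of
#'   the significant-pathway count).
#' @export
permute_labels_run <- function(dataset, collection, n_permutations,
                               seed = 1L, fdr_pairs = 0.05,
                               fdr_pathways = 0.05,
                               block_size = 1024L) {
  stopifnot(inherits(dataset, "reo_dataset"))
  if (n_permutations < 1) abort("`n_permutations` must be >= 1.")
  if (ncol(dataset$values) < 4) {
    abort("Need at least 4 pooled samples to permute.")
  }
  if (is.null(collection$background_genes)) {
    collection <- define_background(dataset, collection)
  }
  labels <- dataset$phenotype$phenotype
  res <- withr::with_seed(seed, {
    purrr::map_dfr(seq_len(n_permutations), function(b) {
      ds_b <- dataset
      ds_b$phenotype$phenotype <- sample(labels)
      dr <- suppressMessages(detect_dr_pairs(
        ds_b, collection, fdr = fdr_pairs, block_size = block_size
      ))
      enr <- enrich_all(dr, collection, fdr = fdr_pathways)
      tibble(permutation = b, n_dr_pairs = nrow(dr),
             n_significant_pathways = sum(enr$significant))
    })
  })
  q <- quantile(res$n_significant_pathways, c(0, .25, .5, .75, 1))
  attr(res, "summary") <- tibble(
    n_permutations = n_permutations,
    mean_significant_pathways = mean(res$n_significant_pathways),
    q0 = q[[1]], q25 = q[[2]], q50 = q[[3]], q75 = q[[4]], q100 = q[[5]]
  )
  res
}
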