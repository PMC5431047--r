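#' Specification of a two-phenotype simulation
#'
#' Describes a synthetic case/control expression experiment with a
#' planted set of gene pairs whose mean ordering reverses in the case
#' group. Control samples are the per-gene baseline means plus i.i.d.
#' Gaussian noise on a log-like scale; case samples are identical
#' except that, for every planted pair, the two baseline means are
#' swapped and pushed apart to `effect_size` times their original gap.
#' All other genes are untouched, so non-planted pairs between
#' untouched genes are exact nulls.
#'
#' Defaults emulate a moderately sized microarray-like study:
#' log2-scale baselines spread evenly over 4..12, per-sample noise
#' standard deviation 0.5, 30 samples per group, and an effect size
#' of 2. Planted pairs, unless supplied explicitly, are drawn disjoint
#' in genes among pairs whose baselines differ by at least `min_gap`
#' (default one log2 unit, i.e. a two-fold baseline separation):
#' a reversal between genes of near-identical baseline is not a
#' resolvable ordering signal at this noise level and would not be a
#' meaningful planted truth.
#'
#' @param n_genes Number of genes.
#' @param n_case,n_control Samples per phenotype (defaults 30/30).
#' @param baseline_means Optional per-gene baseline vector (default:
#'   evenly spaced over `[4, 12]`, shuffled across gene ids so baseline
#'   is unrelated to id order).
#' @param noise_sd Gaussian noise SD (log scale), default 0.5.
#' @param planted_pairs Optional two-column matrix/data frame of gene
#'   indices (i, j) to reverse; genes must be disjoint across pairs.
#' @param n_planted If `planted_pairs` is `NULL`, how many pairs to
#'   draw (default 0).
#' @param effect_size Mean-separation multiplier in cases (> 0),
#'   default 2.
#' @param min_gap Minimum baseline gap for drawn planted pairs.
#' @param seed Integer seed; the simulation is a pure function of the
#'   spec.
#' @return A `simulation_spec` list.
#' @export
simulation_spec <- function(n_genes, n_case = 30L, n_control = 30L,
                            baseline_means = NULL, noise_sd = 0.5,
                            planted_pairs = NULL, n_planted = 0L,
                            effect_size = 2, min_gap = 1, seed = 1L) {
  if (n_genes < 2) abort("`n_genes` must be >= 2.")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  if (effect_size <= 0) abort("`effect_size` must be > 0.")
  if (!is.null(baseline_means) && length(baseline_means) != n_genes) {
    abort("`baseline_means` must have length `n_genes`.")
  }
  spec <- list(
    n_genes = as.integer(n_genes),
    n_case = as.integer(n_case), n_control = as.integer(n_control),
    baseline_means = baseline_means, noise_sd = noise_sd,
    planted_pairs = planted_pairs, n_planted = as.integer(n_planted),
    effect_size = effect_size, min_gap = min_gap,
    seed = as.integer(seed)
  )
  structure(spec, class = "simulation_spec")
}

sim_gene_ids <- function(n_genes) {
  sprintf("g%0*d", nchar(as.character(n_genes)), seq_len(n_genes))
}

# Disjoint random pairs with baseline gap >= min_gap.
draw_planted_pairs <- function(n_pairs, baselines, min_gap) {
  n_genes <- length(baselines)
  if (2 * n_pairs > n_genes) {
    abort("More planted genes than genes available.")
  }
  avail <- seq_len(n_genes)
  out <- matrix(NA_integer_, n_pairs, 2)
  for (p in seq_len(n_pairs)) {
    ij <- NULL
    for (attempt in 1:10000) {
      cand <- sample(avail, 2)
      if (abs(baselines[cand[1]] - baselines[cand[2]]) >= min_gap) {
        ij <- cand
        break
      }
    }
    if (is.null(ij)) {
      abort("Could not find enough planted pairs with the required gap.")
    }
    out[p, ] <- ij
    avail <- setdiff(avail, ij)
  }
  out
}

#' Simulate a two-phenotype expression dataset with planted reversals
#'
#' @param spec A [simulation_spec()].
#' @return List with elements `dataset` (a [reo_dataset()]),
#'   `planted`: a tibble of the ground truth with canonical pair keys
#'   (`gene_i < gene_j`) and `pattern_expected`, the Pattern label
#'   [detect_dr_pairs()] should assign (`"Pattern1"` when the case
#'   group favours the `gene_i > gene_j` ordering); and `spec_frozen`:
#'   the input spec with the drawn baselines and planted pairs made
#'   explicit, so that changing only its `seed` yields an independent
#'   replicate of the *same* generative model (new noise, same truth).
#'   Deterministic given `spec$seed`.
#' @examples
#' sim <- simulate_two_phenotype(
#'   simulation_spec(n_genes = 50, n_planted = 5, seed = 7)
#' )
#' sim$dataset
#' sim$planted
#' @export
simulate_two_phenotype <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  withr::with_seed(spec$seed, {
    ng <- spec$n_genes
    ids <- sim_gene_ids(ng)
    base <- spec$baseline_means %||% sample(seq(4, 12, length.out = ng))

    pp <- spec$planted_pairs
    if (is.null(pp) && spec$n_planted > 0) {
      pp <- draw_planted_pairs(spec$n_planted, base, spec$min_gap)
    }
    if (!is.null(pp)) {
      pp <- as.matrix(pp)[, 1:2, drop = FALSE]
      storage.mode(pp) <- "integer"
      if (anyDuplicated(as.vector(pp))) {
        abort("Planted pairs must be disjoint in genes.")
      }
      if (any(pp < 1 | pp > ng)) {
        abort("Planted pair indices out of range.")
      }
    } else {
      pp <- matrix(integer(0), 0, 2)
    }

    case_means <- base
    for (p in seq_len(nrow(pp))) {
      i <- pp[p, 1]; j <- pp[p, 2]
      mid <- (base[i] + base[j]) / 2
      half <- spec$effect_size * abs(base[i] - base[j]) / 2
      s <- sign(base[i] - base[j])
      case_means[i] <- mid - s * half   # reversed ordering in cases
      case_means[j] <- mid + s * half
    }

    n <- spec$n_case; m <- spec$n_control
    values <- cbind(
      matrix(case_means, ng, n) +
        matrix(rnorm(ng * n, sd = spec$noise_sd), ng, n),
      matrix(base, ng, m) +
        matrix(rnorm(ng * m, sd = spec$noise_sd), ng, m)
    )
    rownames(values) <- ids
    colnames(values) <- c(sprintf("case_%02d", seq_len(n)),
                          sprintf("ctrl_%02d", seq_len(m)))
    pheno <- tibble(
      sample_id = colnames(values),
      phenotype = rep(c("case", "control"), c(n, m))
    )

    planted <- if (nrow(pp)) {
      gi <- ids[pp[, 1]]; gj <- ids[pp[, 2]]
      swap <- gi > gj
      tmp <- gi[swap]; gi[swap] <- gj[swap]; gj[swap] <- tmp
      # after canonicalization, gene_i is the pair member with the
      # smaller id; cases favour gene_i > gene_j iff gene_i's case
      # mean exceeds gene_j's
      tibble(
        gene_i = gi, gene_j = gj,
        pattern_expected = ifelse(
          case_means[match(gi, ids)] > case_means[match(gj, ids)],
          "Pattern1", "Pattern2"
        )
      )
    } else {
      tibble(gene_i = character(), gene_j = character(),
             pattern_expected = character())
    }
    planted <- dplyr::arrange(planted, .data$gene_i, .data$gene_j)

    frozen <- spec
    frozen$baseline_means <- base
    frozen$planted_pairs <- pp

    list(dataset = reo_dataset(values, pheno), planted = planted,
         spec_frozen = frozen)
  })
}

#' Gene-set collection matched to a simulation's planted pairs
#'
#' Builds a collection whose first set (`"signal_pathway"`) contains
#' every gene of every planted pair plus random fillers up to
#' `pathway_size`; the remaining `n_pathways - 1` sets are random draws
#' of `pathway_size` genes. This gives pathway enrichment a known
#' answer: the signal pathway should be the top, significant hit.
#'
#' @param planted_pairs Tibble with `gene_i`, `gene_j` (as returned by
#'   [simulate_two_phenotype()]).
#' @param n_genes Total genes in the simulated universe (ids are
#'   regenerated with the simulator's naming).
#' @param pathway_size Genes per set (>= 2; must be >= the number of
#'   distinct planted genes).
#' @param n_pathways Total sets (>= 1).
#' @param seed Integer seed.
#' @return A [reo_collection][read_gmt()] (background not yet derived).
#' @export
make_matched_collection <- function(planted_pairs, n_genes,
                                    pathway_size = 20L,
                                    n_pathways = 50L, seed = 1L) {
  if (pathway_size < 2) abort("`pathway_size` must be >= 2.")
  if (n_pathways < 1) abort("`n_pathways` must be >= 1.")
  ids <- sim_gene_ids(n_genes)
  planted_genes <- unique(c(planted_pairs$gene_i, planted_pairs$gene_j))
  if (length(setdiff(planted_genes, ids))) {
    abort("Planted genes do not match the simulated gene universe.")
  }
  if (pathway_size < length(planted_genes)) {
    abort("`pathway_size` smaller than the number of planted genes.")
  }
  withr::with_seed(seed, {
    fillers <- sample(setdiff(ids, planted_genes),
                      pathway_size - length(planted_genes))
    sets <- list(signal_pathway = sort(c(planted_genes, fillers)))
    for (p in seq_len(n_pathways - 1L)) {
      sets[[sprintf("random_pathway_%03d", p)]] <-
        sort(sample(ids, pathway_size))
    }
    new_collection(sets, source_label = "simulated")
  })
}
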