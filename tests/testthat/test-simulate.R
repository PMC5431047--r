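test_that("simulation is deterministic and respects its spec", {
  spec <- simulation_spec(n_genes = 50, n_case = 8, n_control = 9,
                          n_planted = 4, seed = 21)
  s1 <- simulate_two_phenotype(spec)
  s2 <- simulate_two_phenotype(spec)
  expect_identical(s1$dataset$values, s2$dataset$values)
  expect_identical(s1$planted, s2$planted)
  expect_identical(dim(s1$dataset), c(50L, 17L))
  expect_equal(length(phenotype_samples(s1$dataset, "case")), 8)
  expect_equal(length(phenotype_samples(s1$dataset, "control")), 9)
  # planted pairs disjoint in genes, canonical keys
  genes <- c(s1$planted$gene_i, s1$planted$gene_j)
  expect_false(anyDuplicated(genes) > 0)
  expect_true(all(s1$planted$gene_i < s1$planted$gene_j))
  # a different seed gives different data
  s3 <- simulate_two_phenotype(simulation_spec(
    n_genes = 50, n_case = 8, n_control = 9, n_planted = 4, seed = 22
  ))
  expect_false(identical(s1$dataset$values, s3$dataset$values))
})

test_that("frozen spec replicates the generative model with new noise", {
  s1 <- simulate_two_phenotype(simulation_spec(
    n_genes = 40, n_planted = 3, seed = 55
  ))
  sp2 <- s1$spec_frozen
  sp2$seed <- 56L
  s2 <- simulate_two_phenotype(sp2)
  expect_identical(s1$planted, s2$planted)
  expect_false(identical(s1$dataset$values, s2$dataset$values))
})

test_that("noiseless planted pairs are perfectly reversed; null spec has no signal", {
  s <- simulate_two_phenotype(simulation_spec(
    n_genes = 30, n_case = 6, n_control = 6, noise_sd = 0,
    n_planted = 3, seed = 3
  ))
  pc <- compute_pair_counts(s$dataset)
  planted <- dplyr::inner_join(s$planted, pc,
                               by = c("gene_i", "gene_j"))
  expect_equal(nrow(planted), 3)
  # ordering identical in every sample within a phenotype, reversed
  # between phenotypes
  expect_true(all((planted$n1 == 6 & planted$m1 == 0) |
                    (planted$n2 == 6 & planted$m2 == 0)))

  null_s <- simulate_two_phenotype(simulation_spec(
    n_genes = 30, n_case = 6, n_control = 6, n_planted = 0, seed = 3
  ))
  expect_equal(nrow(null_s$planted), 0)
  expect_equal(nrow(detect_dr_pairs(null_s$dataset)), 0)
})

test_that("simulation spec validation", {
  expect_error(simulation_spec(n_genes = 1), ">= 2")
  expect_error(simulation_spec(10, noise_sd = -1), ">= 0")
  expect_error(simulation_spec(10, effect_size = 0), "> 0")
  expect_error(
    simulate_two_phenotype(simulation_spec(10, n_planted = 6, seed = 1)),
    "planted"
  )
  expect_error(
    simulate_two_phenotype(simulation_spec(
      10, planted_pairs = rbind(c(1, 2), c(2, 3)), seed = 1
    )),
    "disjoint"
  )
})

test_that("matched collections contain the planted genes and are reproducible", {
  sim <- simulate_two_phenotype(simulation_spec(
    n_genes = 100, n_planted = 5, seed = 19
  ))
  col <- make_matched_collection(sim$planted, 100, pathway_size = 20,
                                 n_pathways = 10, seed = 20)
  expect_equal(length(col$sets), 10)
  planted_genes <- unique(c(sim$planted$gene_i, sim$planted$gene_j))
  expect_length(planted_genes, 10)
  expect_true(all(planted_genes %in% col$sets$signal_pathway))
  expect_length(col$sets$signal_pathway, 20)
  col2 <- make_matched_collection(sim$planted, 100, pathway_size = 20,
                                  n_pathways = 10, seed = 20)
  expect_identical(col$sets, col2$sets)

  # degenerate: only the signal pathway
  only <- make_matched_collection(sim$planted, 100, pathway_size = 15,
                                  n_pathways = 1, seed = 1)
  expect_identical(names(only$sets), "signal_pathway")
  # pathway too small for the planted genes
  expect_error(
    make_matched_collection(sim$planted, 100, pathway_size = 5,
                            n_pathways = 3, seed = 1),
    "smaller"
  )
})
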