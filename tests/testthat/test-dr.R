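test_that("Fisher p-values match hand-derived tables and are symmetric", {
  p <- function(n1, n2, m1, m2) {
    fisher_pair_test(data.frame(n1 = n1, n2 = n2,
                                m1 = m1, m2 = m2))$p_raw
  }
  expect_equal(p(10, 0, 0, 10), 2 / 184756, tolerance = 1e-12)
  expect_equal(p(5, 5, 5, 5), 1)
  expect_equal(p(3, 0, 0, 3), 0.1, tolerance = 1e-12)
  # invariance under swapping rows, and under swapping both columns
  expect_equal(p(9, 1, 2, 8), p(2, 8, 9, 1))
  expect_equal(p(9, 1, 2, 8), p(1, 9, 8, 2))
  # all-tie phenotype -> NA with a message, not an error
  expect_message(res <- fisher_pair_test(
    data.frame(n1 = 0, n2 = 0, m1 = 3, m2 = 2)
  ), "skipped")
  expect_true(is.na(res$p_raw))
  expect_error(fisher_pair_test(data.frame(n1 = -1, n2 = 1,
                                           m1 = 1, m2 = 1)),
               "nonnegative")
})

test_that("batched Fisher equals brute-force enumeration and fisher.test on random tables", {
  withr::local_seed(2024)
  tabs <- data.frame(
    n1 = sample(0:30, 250, TRUE), n2 = sample(0:30, 250, TRUE),
    m1 = sample(0:30, 250, TRUE), m2 = sample(0:30, 250, TRUE)
  )
  tabs <- tabs[tabs$n1 + tabs$n2 > 0 & tabs$m1 + tabs$m2 > 0, ][1:200, ]
  got <- fisher_pair_test(tabs)$p_raw
  oracle <- mapply(fisher_oracle, tabs$n1, tabs$n2, tabs$m1, tabs$m2)
  expect_equal(got, oracle, tolerance = 1e-12)
  # independent second route: stats::fisher.test on a subsample
  sub <- seq(1, 200, by = 10)
  ft <- vapply(sub, function(i) {
    stats::fisher.test(matrix(as.numeric(tabs[i, ]), 2,
                              byrow = TRUE))$p.value
  }, numeric(1))
  expect_equal(got[sub], ft, tolerance = 1e-12)
})

test_that("one-sided alternatives are hypergeometric tails", {
  tab <- data.frame(n1 = 8, n2 = 2, m1 = 3, m2 = 7)
  g <- fisher_pair_test(tab, alternative = "greater")$p_raw
  l <- fisher_pair_test(tab, alternative = "less")$p_raw
  expect_equal(g, stats::fisher.test(matrix(c(8, 2, 3, 7), 2,
                                            byrow = TRUE),
                                     alternative = "greater")$p.value,
               tolerance = 1e-12)
  expect_equal(l, stats::fisher.test(matrix(c(8, 2, 3, 7), 2,
                                            byrow = TRUE),
                                     alternative = "less")$p.value,
               tolerance = 1e-12)
})

test_that("BH adjustment: worked example, caps, monotonicity, validation", {
  expect_equal(bh_adjust(c(0.005, 0.03, 0.04)),
               c(0.015, 0.04, 0.04))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.012), 0.012)
  withr::local_seed(3)
  p <- runif(50)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p - 1e-15))
  expect_true(all(adj <= 1))
  # adjusted values preserve the ranking of the raw values
  expect_true(all(diff(adj[order(p)]) > -1e-15))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("pattern assignment follows the cross-product rule", {
  pat <- function(...) assign_pattern(data.frame(...))$pattern
  expect_identical(pat(n1 = 9, n2 = 1, m1 = 2, m2 = 8), "Pattern1")
  expect_identical(pat(n1 = 10, n2 = 0, m1 = 0, m2 = 10), "Pattern1")
  expect_identical(pat(n1 = 0, n2 = 10, m1 = 10, m2 = 0), "Pattern2")
  expect_identical(pat(n1 = 5, n2 = 5, m1 = 5, m2 = 5), "ambiguous")
  expect_identical(pat(n1 = 0, n2 = 0, m1 = 0, m2 = 0), "ambiguous")
})

test_that("detection recovers planted reversals and is empty on null data", {
  sim <- simulate_two_phenotype(simulation_spec(
    n_genes = 120, n_case = 20, n_control = 20, n_planted = 10,
    seed = 77
  ))
  dr <- detect_dr_pairs(sim$dataset)
  found <- dplyr::inner_join(sim$planted, tidy(dr),
                             by = c("gene_i", "gene_j"))
  expect_equal(nrow(found), 10)
  expect_identical(found$pattern_expected, found$pattern)

  # case/control drawn from the same null population -> (near-)empty
  null_sim <- simulate_two_phenotype(simulation_spec(
    n_genes = 120, n_case = 20, n_control = 20, n_planted = 0,
    seed = 78
  ))
  dr0 <- detect_dr_pairs(null_sim$dataset)
  expect_lte(nrow(dr0), 2)

  # degenerate threshold
  expect_equal(nrow(detect_dr_pairs(sim$dataset, fdr = 0)), 0)
})

test_that("swapping case/control labels maps Pattern1 to Pattern2 with identical p", {
  sim <- simulate_two_phenotype(simulation_spec(
    n_genes = 60, n_case = 12, n_control = 15, n_planted = 5, seed = 8
  ))
  dr <- detect_dr_pairs(sim$dataset)
  flipped <- sim$dataset
  flipped$phenotype$phenotype <-
    ifelse(flipped$phenotype$phenotype == "case", "control", "case")
  dr_f <- detect_dr_pairs(flipped)
  a <- dplyr::arrange(tidy(dr), gene_i, gene_j)
  b <- dplyr::arrange(tidy(dr_f), gene_i, gene_j)
  expect_identical(a[, c("gene_i", "gene_j")],
                   b[, c("gene_i", "gene_j")])
  expect_equal(a$p_raw, b$p_raw, tolerance = 1e-14)
  expect_identical(
    a$pattern,
    dplyr::recode(b$pattern, Pattern1 = "Pattern2",
                  Pattern2 = "Pattern1")
  )
})

test_that("detection output is deterministic and its summary is coherent", {
  sim <- simulate_two_phenotype(simulation_spec(
    n_genes = 50, n_case = 10, n_control = 10, n_planted = 4, seed = 4
  ))
  d1 <- detect_dr_pairs(sim$dataset)
  d2 <- detect_dr_pairs(sim$dataset)
  expect_identical(tidy(d1), tidy(d2))
  g <- glance(d1)
  expect_equal(g$n_pairs_tested + g$n_pairs_skipped, choose(50, 2))
  expect_equal(g$n_dr_pairs, nrow(d1))
  expect_true(all(d1$p_adjusted < g$fdr))
  expect_true(all(d1$p_adjusted >= d1$p_raw - 1e-15))
  # table is sorted by adjusted p
  expect_true(all(diff(d1$p_adjusted) >= 0))
})

test_that("DR tables round-trip through their TSV format", {
  sim <- simulate_two_phenotype(simulation_spec(
    n_genes = 40, n_case = 10, n_control = 10, n_planted = 3, seed = 6
  ))
  dr <- detect_dr_pairs(sim$dataset)
  dir <- withr::local_tempdir()
  write_dr_pairs(dr, file.path(dir, "dr.tsv"),
                 params = list(fdr = 0.05))
  back <- read_dr_pairs(file.path(dir, "dr.tsv"))
  expect_equal(as.data.frame(back), as.data.frame(tidy(dr)),
               tolerance = 1e-12)
})
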