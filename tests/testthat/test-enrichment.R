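test_that("pathway pair counting is g(g-1)/2 on the background intersection", {
  bg <- paste0("g", 1:100)
  expect_equal(count_pathway_pairs(paste0("g", 1:24), bg), 276)
  expect_equal(count_pathway_pairs(c("g1", "g2"), bg), 1)
  expect_equal(count_pathway_pairs("g1", bg), 0)
  # genes outside the background do not count
  expect_equal(count_pathway_pairs(c("g1", "g2", "zz"), bg), 1)
  # duplicates within the pathway do not inflate g
  expect_equal(count_pathway_pairs(c("g1", "g1", "g2"), bg), 1)
})

test_that("hypergeometric tail: worked values, degenerate cases, validation", {
  expect_equal(enrichment_p(3, 3, 5, 10), 1 / 12, tolerance = 1e-12)
  expect_equal(enrichment_p(0, 3, 5, 10), 1)
  expect_equal(enrichment_p(4, 4, 4, 4), 1)   # certain event
  expect_error(enrichment_p(6, 5, 10, 20), "min")
  expect_error(enrichment_p(1, 30, 5, 20), "<= n")
  expect_error(enrichment_p(0, 2, 5, 6), "Infeasible")
})

test_that("hypergeometric tail equals direct summation over feasible configurations", {
  # exhaustive at small n, sampled at n = 200
  for (n in c(6, 10, 21)) {
    for (m in 0:n) {
      for (k in 0:n) {
        for (x in 0:min(m, k)) {
          if (k - x > n - m) next
          expect_equal(enrichment_p(x, m, k, n),
                       hyper_oracle(x, m, k, n), tolerance = 1e-10)
        }
      }
    }
  }
  withr::local_seed(99)
  for (rep in 1:300) {
    n <- 200
    m <- pick_one(0:n)
    k <- pick_one(0:n)
    x <- pick_one(max(0, k - (n - m)):min(m, k))
    expect_equal(enrichment_p(x, m, k, n), hyper_oracle(x, m, k, n),
                 tolerance = 1e-10)
  }
})

test_that("hypergeometric tail is monotone and the mass normalizes", {
  # nonincreasing in x
  p_x <- enrichment_p(0:10, 20, 30, 100)
  expect_true(all(diff(p_x) <= 1e-15))
  # nondecreasing in m (x, k, n fixed)
  p_m <- vapply(10:60, function(m) enrichment_p(5, m, 30, 100),
                numeric(1))
  expect_true(all(diff(p_m) >= -1e-15))
  # sum rule of the underlying distribution
  mass <- dhyper(0:20, 20, 80, 30)
  expect_equal(sum(mass), 1, tolerance = 1e-12)
})

test_that("enrich_all finds the planted signal pathway and validates inputs", {
  sim <- simulate_two_phenotype(simulation_spec(
    n_genes = 200, n_case = 25, n_control = 25, n_planted = 5,
    seed = 13
  ))
  col <- make_matched_collection(sim$planted, 200, pathway_size = 20,
                                 n_pathways = 30, seed = 14)
  col <- define_background(sim$dataset, col)
  dr <- detect_dr_pairs(sim$dataset, col)
  enr <- enrich_all(dr, col)

  expect_identical(enr$pathway[1], "signal_pathway")
  expect_true(enr$significant[1])
  g <- glance(enr)
  # background = measured genes annotated in >= 1 pathway
  N_expect <- length(intersect(
    rownames(sim$dataset$values),
    unique(unlist(col$sets, use.names = FALSE))
  ))
  expect_equal(g$N, N_expect)
  expect_equal(g$n, N_expect * (N_expect - 1) / 2)
  expect_equal(g$k, nrow(dr))
  expect_true(all(enr$n == g$n))
  expect_true(all(enr$x <= pmin(enr$m, enr$k)))
  expect_true(all(enr$m == enr$g * (enr$g - 1) / 2))

  # empty DR table -> all P = 1, nothing significant
  empty <- tidy(dr)[0, ]
  enr0 <- enrich_all(empty, col)
  expect_true(all(enr0$p_raw == 1))
  expect_false(any(enr0$significant))

  # identical (g, x) configurations get identical p
  same <- enr[enr$g == enr$g[2] & enr$x == enr$x[2], ]
  if (nrow(same) > 1) expect_equal(var(same$p_raw), 0)

  # DR genes outside the background -> error
  rogue <- tidy(dr)
  rogue$gene_i[1] <- "not_a_gene"
  expect_error(enrich_all(rogue, col), "outside")

  # pathways with < 2 background genes are excluded
  bg2 <- col$background_genes[1:2]
  col2 <- col
  col2$sets$tiny <- c(bg2, "zzz")       # 2 background genes -> tested
  col2$sets$excluded <- bg2[1]          # 1 background gene -> dropped
  col2 <- define_background(sim$dataset, col2)
  enr2 <- enrich_all(dr, col2)
  expect_false("excluded" %in% enr2$pathway)
  expect_true("tiny" %in% enr2$pathway)
})
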