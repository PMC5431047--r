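# Independent oracles and small fixture builders.
# Everything here is deliberately naive: enumeration and direct
# summation, never the code paths under test.

# Two-sided Fisher exact p by brute-force enumeration of all tables
# with the observed margins: sum the point probabilities (computed from
# choose()) of every table no more probable than the observed one
# (1 + 1e-7 relative guard, the conventional tie rule).
fisher_oracle <- function(n1, n2, m1, m2) {
  r1 <- n1 + n2; r2 <- m1 + m2; c1 <- n1 + m1
  N <- r1 + r2
  lo <- max(0, c1 - r2); hi <- min(c1, r1)
  prob <- function(a) {
    choose(r1, a) * choose(r2, c1 - a) / choose(N, c1)
  }
  d <- vapply(lo:hi, prob, numeric(1))
  sum(d[d <= prob(n1) * (1 + 1e-7)])
}

# Upper-tail binomial probability by direct term summation.
binom_oracle <- function(M, M1, p0 = 0.5) {
  if (M1 > M) stop("M1 > M")
  if (M == 0) return(1)
  sum(vapply(M1:M, function(i) {
    choose(M, i) * p0^i * (1 - p0)^(M - i)
  }, numeric(1)))
}

# Eq-style cumulative hypergeometric by direct term summation
# (log-scale terms, summed upper tail).
hyper_oracle <- function(x, m, k, n) {
  if (x == 0) return(1)
  upper <- x:min(m, k)
  terms <- exp(lchoose(m, upper) + lchoose(n - m, k - upper) -
                 lchoose(n, k))
  min(1, sum(terms))
}

# sample() treats a length-1 vector as 1:n; this never does.
pick_one <- function(v) v[sample.int(length(v), 1)]

# Per-pair ordering counts by the obvious per-sample loop.
pair_counts_oracle <- function(dataset, genes) {
  case_s <- reopairs::phenotype_samples(dataset, "case")
  ctrl_s <- reopairs::phenotype_samples(dataset, "control")
  rows <- list()
  for (i in seq_along(genes)) {
    for (j in seq_along(genes)) {
      if (i >= j) next
      vi <- dataset$values[genes[i], ]
      vj <- dataset$values[genes[j], ]
      rows[[length(rows) + 1]] <- data.frame(
        gene_i = genes[i], gene_j = genes[j],
        n1 = sum(vi[case_s] > vj[case_s]),
        n2 = sum(vi[case_s] < vj[case_s]),
        m1 = sum(vi[ctrl_s] > vj[ctrl_s]),
        m2 = sum(vi[ctrl_s] < vj[ctrl_s])
      )
    }
  }
  do.call(rbind, rows)
}

make_tiny_dataset <- function() {
  m <- matrix(
    c(2, 1, 3,
      3, 5, 1,
      1, 2, 4,
      0, 4, 2),
    nrow = 3,
    dimnames = list(c("A", "B", "C"), c("s1", "s2", "s3", "s4"))
  )
  reopairs::reo_dataset(m, c(s1 = "case", s2 = "case",
                             s3 = "control", s4 = "control"))
}

write_tiny_files <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  ds <- make_tiny_dataset()
  expr <- file.path(dir, "expr.tsv")
  pheno <- file.path(dir, "pheno.tsv")
  reopairs::write_expression(ds, expr, pheno)
  gmt <- file.path(dir, "sets.gmt")
  writeLines(c("P1\tdesc\tA\tB\tE", "P2\tdesc\tC\tF"), gmt)
  list(expr = expr, pheno = pheno, gmt = gmt, dataset = ds)
}
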