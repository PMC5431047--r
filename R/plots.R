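#' Plot a DR pair table
#'
#' Volcano-style view of the significant pairs: the log2 odds ratio of
#' the `G_i > G_j` ordering between phenotypes (Haldane-corrected)
#' against `-log10` adjusted p, coloured by reversal direction.
#'
#' @param object A [dr_pair_table][detect_dr_pairs()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot dr_pair_table
#' @export
autoplot.dr_pair_table <- function(object, ...) {
  df <- as_tibble(object)
  if (!nrow(df)) {
    return(ggplot2::ggplot() +
             ggplot2::annotate("text", x = 0, y = 0,
                               label = "no DR pairs") +
             ggplot2::theme_void())
  }
  df$log2_or <- log2(((df$n1 + 0.5) * (df$m2 + 0.5)) /
                       ((df$n2 + 0.5) * (df$m1 + 0.5)))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$log2_or, y = -log10(.data$p_adjusted),
    colour = .data$pattern
  )) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::labs(
      x = "log2 odds ratio of the G_i > G_j ordering (case vs control)",
      y = "-log10 adjusted p",
      colour = NULL,
      title = "Differentially ranked gene pairs"
    ) +
    ggplot2::theme_minimal()
}

#' Plot an enrichment table
#'
#' Horizontal bars of `-log10` adjusted p for the top pathways,
#' significant pathways filled.
#'
#' @param object A [reo_enrichment][enrich_all()].
#' @param top Number of pathways shown (default 20).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot reo_enrichment
#' @export
autoplot.reo_enrichment <- function(object, top = 20, ...) {
  df <- head(as_tibble(object), top)
  df$pathway <- factor(df$pathway, levels = rev(df$pathway))
  ggplot2::ggplot(df, ggplot2::aes(
    x = -log10(pmax(.data$p_adjusted, 1e-300)), y = .data$pathway,
    fill = .data$significant
  )) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = "-log10 adjusted p", y = NULL, fill = "FDR significant",
      title = "Pathways enriched with DR gene pairs"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a concordance report
#'
#' Concordant vs discordant counts among the overlapped pairs of two
#' DR lists, annotated with the concordance ratio.
#'
#' @param object A [reo_concordance][concordance_report()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot reo_concordance
#' @export
autoplot.reo_concordance <- function(object, ...) {
  df <- tibble(
    outcome = c("concordant", "discordant"),
    pairs = c(object$M1, object$M - object$M1)
  )
  lab <- if (object$M > 0) {
    sprintf("M1/M = %.4f, P = %.3g", object$ratio, object$p_binomial)
  } else "no overlapped pairs"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$outcome,
                                   y = .data$pairs)) +
    ggplot2::geom_col(width = 0.6) +
    ggplot2::labs(x = NULL, y = "overlapped DR pairs",
                  title = "Cross-dataset concordance", subtitle = lab) +
    ggplot2::theme_minimal()
}

#' Ordering of one gene pair across samples
#'
#' Per-sample expression of two genes, lines joining the pair within
#' each sample, faceted by phenotype -- a direct view of a rank
#' reversal.
#'
#' @param dataset A [reo_dataset()].
#' @param gene_i,gene_j Gene ids.
#' @return A ggplot.
#' @export
plot_pair_reo <- function(dataset, gene_i, gene_j) {
  stopifnot(inherits(dataset, "reo_dataset"))
  for (g in c(gene_i, gene_j)) {
    if (!g %in% rownames(dataset$values)) {
      abort(paste0("Gene not in dataset: ", g))
    }
  }
  df <- tibble(
    sample_id = rep(colnames(dataset$values), 2),
    phenotype = rep(dataset$phenotype$phenotype, 2),
    gene = rep(c(gene_i, gene_j), each = ncol(dataset$values)),
    expression = c(dataset$values[gene_i, ], dataset$values[gene_j, ])
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gene,
                                   y = .data$expression,
                                   group = .data$sample_id)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::facet_wrap(~phenotype) +
    ggplot2::labs(title = sprintf("Within-sample ordering: %s vs %s",
                                  gene_i, gene_j)) +
    ggplot2::theme_minimal()
}
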