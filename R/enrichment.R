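#' Count network edges within a gene set
#'
#' Number of network edges whose both endpoints lie in `genes`. Genes absent
#' from the network are dropped with a warning.
#'
#' @param genes Character vector of genes.
#' @param net A [gene_network][as_gene_network].
#' @return Integer edge count.
#' @export
count_edges_within <- function(genes, net) {
  stopifnot(inherits(net, "gene_network"))
  genes <- unique(as.character(genes))
  missing <- setdiff(genes, net$nodes$gene)
  if (length(missing) > 0) {
    warn(sprintf("%d gene(s) absent from the network were dropped.",
                 length(missing)))
    genes <- setdiff(genes, missing)
  }
  sum(net$edges$gene_a %in% genes & net$edges$gene_b %in% genes)
}

#' Edge-count permutation enrichment test
#'
#' Tests whether a candidate gene set is more interconnected than random
#' gene sets of the same size: a useful preflight before network-assisted
#' association, since the model only gains power when top genes cluster on
#' the network. Random sets are drawn uniformly without replacement from the
#' pool (all network nodes by default; optionally a restricted pool such as
#' the genes with DNV data), the null distribution of within-set edge counts
#' is tabulated, and the empirical p-value uses the add-one estimator
#' `p = (1 + #{null >= observed}) / (1 + n_perm)`, so it is never zero. The
#' 95th percentile of the null is reported as a baseline.
#'
#' @param genes Candidate gene set.
#' @param net A [gene_network][as_gene_network].
#' @param n_perm Number of permutations (`>= 100`; the reference analysis
#'   used 10,000).
#' @param pool Optional character vector to sample random sets from; defaults
#'   to all network nodes.
#' @return An `edge_enrichment` object: `observed`, `null_samples`,
#'   `p_value`, `percentile_95`, `n_perm`, `k`.
#' @export
edge_enrichment_test <- function(genes, net, n_perm = 10000L, pool = NULL) {
  stopifnot(inherits(net, "gene_network"))
  if (n_perm < 100) abort("`n_perm` must be at least 100.")
  if (is.null(pool)) pool <- net$nodes$gene
  pool <- unique(as.character(pool))
  observed <- count_edges_within(genes, net)
  k <- length(intersect(unique(as.character(genes)), net$nodes$gene))
  if (k > length(pool)) abort("Gene set is larger than the sampling pool.")
  null_samples <- sample_null_edge_counts(k, net, pool, n_perm)
  structure(
    list(
      observed = observed,
      null_samples = null_samples,
      p_value = (1 + sum(null_samples >= observed)) / (1 + n_perm),
      percentile_95 = unname(quantile(null_samples, 0.95)),
      n_perm = as.integer(n_perm), k = k
    ),
    class = "edge_enrichment"
  )
}

# vectorized edge counting over permutations: membership flags per edge
sample_null_edge_counts <- function(k, net, pool, n_perm) {
  genes <- net$nodes$gene
  n <- length(genes)
  in_pool <- match(pool, genes) # NA for pool genes outside the network
  ea <- match(net$edges$gene_a, genes)
  eb <- match(net$edges$gene_b, genes)
  vapply(seq_len(n_perm), function(j) {
    idx <- in_pool[sample.int(length(in_pool), k)]
    memb <- logical(n)
    memb[idx[!is.na(idx)]] <- TRUE
    sum(memb[ea] & memb[eb])
  }, integer(1))
}

#' @export
print.edge_enrichment <- function(x, ...) {
  cat(sprintf(
    paste0("<edge_enrichment> k = %d genes: %d edges observed\n",
           "  null 95th percentile %.1f; p = %.4g (%d permutations)\n"),
    x$k, x$observed, x$percentile_95, x$p_value, x$n_perm
  ))
  invisible(x)
}

#' @describeIn edge_enrichment_test One-row summary tibble.
#' @param x An `edge_enrichment` object.
#' @param ... Unused.
#' @exportS3Method
glance.edge_enrichment <- function(x, ...) {
  tibble(
    k = x$k, observed_edges = x$observed, p_value = x$p_value,
    null_mean = mean(x$null_samples), percentile_95 = x$percentile_95,
    n_perm = x$n_perm
  )
}

#' @describeIn edge_enrichment_test Null histogram with the observed count.
#' @param object An `edge_enrichment` object.
#' @exportS3Method
autoplot.edge_enrichment <- function(object, ...) {
  df <- tibble(edges = object$null_samples)
  ggplot2::ggplot(df, ggplot2::aes(.data$edges)) +
    ggplot2::geom_histogram(binwidth = 1, boundary = -0.5) +
    ggplot2::geom_vline(xintercept = object$observed, colour = "blue") +
    ggplot2::geom_vline(xintercept = object$percentile_95, linetype = 2) +
    ggplot2::labs(x = "Edges within random gene set", y = "Permutations")
}

#' Edge enrichment along a gene ranking
#'
#' For each prefix size `k = 2, ..., k_max` of a ranked gene list, compares
#' the number of edges among the top-`k` genes with the 95th percentile of
#' the null edge-count distribution for random size-`k` sets.
#'
#' @param ranked_genes Genes ordered from most to least interesting (e.g. by
#'   adjusted p-value or local fdr).
#' @param net A [gene_network][as_gene_network].
#' @param k_max Largest prefix size (capped at the ranking length).
#' @param n_perm Permutations per prefix size.
#' @param pool Optional sampling pool, as in [edge_enrichment_test()].
#' @return A tibble of class `edge_enrichment_sweep` with `k`, `observed`,
#'   `null_q95`, `p_value`.
#' @export
edge_enrichment_sweep <- function(ranked_genes, net, k_max = 30L,
                                  n_perm = 1000L, pool = NULL) {
  ranked_genes <- as.character(ranked_genes)
  if (length(ranked_genes) == 0) abort("`ranked_genes` must be nonempty.")
  k_max <- min(k_max, length(ranked_genes))
  if (is.null(pool)) pool <- net$nodes$gene
  out <- purrr::map_dfr(2:k_max, function(k) {
    top <- ranked_genes[seq_len(k)]
    observed <- suppressWarnings(count_edges_within(top, net))
    null_samples <- sample_null_edge_counts(
      length(intersect(top, net$nodes$gene)), net, pool, n_perm
    )
    tibble(
      k = k, observed = observed,
      null_q95 = unname(quantile(null_samples, 0.95)),
      p_value = (1 + sum(null_samples >= observed)) / (1 + n_perm)
    )
  })
  class(out) <- c("edge_enrichment_sweep", class(out))
  out
}

#' @describeIn edge_enrichment_sweep Observed edges versus the null 95th
#'   percentile along the ranking.
#' @param object An `edge_enrichment_sweep` tibble.
#' @param ... Unused.
#' @exportS3Method
autoplot.edge_enrichment_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$k)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$observed, colour = "observed")) +
    ggplot2::geom_line(ggplot2::aes(y = .data$null_q95,
                                    colour = "null 95th percentile")) +
    ggplot2::labs(x = "Top-k genes", y = "Edges within set", colour = NULL)
}
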