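#' Gene interaction networks
#'
#' A `gene_network` is an undirected, simple graph over gene identifiers,
#' stored as a node table and a canonical edge table. Each node carries its
#' degree (number of distinct neighbours) and an MRF weight: `sqrt(degree)`
#' in network mode, `0` in no-network mode. Gene identifiers are opaque,
#' case-sensitive strings and node order is lexicographic everywhere, so all
#' sweep-based algorithms are deterministic.
#'
#' @param edges A data frame with columns `gene_a`, `gene_b` and optionally
#'   `score` (integer 0--1000; defaults to 1000 when absent). Self-loops are
#'   dropped and reciprocal/duplicate pairs are collapsed to a single
#'   undirected edge keeping the maximum score.
#' @param genes Optional character vector of genes to include as nodes even
#'   when isolated.
#' @param weight_mode `"sqrt_degree"` (network mode) or `"zero"`
#'   (no-network mode, all weights 0).
#' @return A `gene_network` object: a list with tibbles `nodes`
#'   (`gene`, `degree`, `weight`) and `edges` (`gene_a`, `gene_b`, `score`).
#' @examples
#' net <- as_gene_network(
#'   data.frame(gene_a = c("A", "B"), gene_b = c("B", "C"), score = 900L)
#' )
#' net$nodes
#' @export
as_gene_network <- function(edges, genes = NULL,
                            weight_mode = c("sqrt_degree", "zero")) {
  weight_mode <- match.arg(weight_mode)
  edges <- as_tibble(edges)
  if (!all(c("gene_a", "gene_b") %in% names(edges))) {
    abort("`edges` must have columns `gene_a` and `gene_b`.")
  }
  if (!"score" %in% names(edges)) edges$score <- 1000L
  edges <- clean_edges(edges)
  all_genes <- sort(unique(c(edges$gene_a, edges$gene_b, as.character(genes))))
  new_gene_network(all_genes, edges, weight_mode)
}

# canonicalize: character ids, no self-loops, gene_a < gene_b, max score per pair
clean_edges <- function(edges) {
  edges <- dplyr::mutate(edges,
    gene_a = as.character(.data$gene_a),
    gene_b = as.character(.data$gene_b),
    score = as.integer(.data$score)
  )
  edges <- dplyr::filter(edges, .data$gene_a != .data$gene_b)
  if (nrow(edges) == 0) {
    return(edges[c("gene_a", "gene_b", "score")])
  }
  flip <- edges$gene_a > edges$gene_b
  tmp <- edges$gene_a[flip]
  edges$gene_a[flip] <- edges$gene_b[flip]
  edges$gene_b[flip] <- tmp
  edges |>
    dplyr::summarise(
      score = max(.data$score),
      .by = c("gene_a", "gene_b")
    ) |>
    dplyr::arrange(.data$gene_a, .data$gene_b)
}

new_gene_network <- function(genes, edges, weight_mode) {
  degree <- integer(length(genes))
  names(degree) <- genes
  if (nrow(edges) > 0) {
    tab <- table(c(edges$gene_a, edges$gene_b))
    degree[names(tab)] <- as.integer(tab)
  }
  weight <- if (weight_mode == "sqrt_degree") sqrt(degree) else rep(0, length(genes))
  structure(
    list(
      nodes = tibble(gene = genes, degree = unname(degree), weight = unname(weight)),
      edges = edges,
      weight_mode = weight_mode
    ),
    class = "gene_network"
  )
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf(
    "<gene_network> %d genes, %d edges (weights: %s)\n",
    nrow(x$nodes), nrow(x$edges),
    if (x$weight_mode == "sqrt_degree") "sqrt(degree)" else "all zero"
  ))
  invisible(x)
}

#' @describeIn as_gene_network Node table (gene, degree, weight) as a tibble.
#' @param x A `gene_network`.
#' @param ... Unused.
#' @exportS3Method
tidy.gene_network <- function(x, ...) x$nodes

#' Read a scored edge list into a gene network
#'
#' Reads a STRING-style tab-separated edge list (`gene_a`, `gene_b`, integer
#' confidence score in 0--1000; optional header auto-detected from a
#' non-numeric third field; plain or gzip) and keeps edges at or above a
#' confidence threshold.
#'
#' @param path Path to a TSV file (optionally gzip-compressed).
#' @param score_threshold Minimum confidence score; edges with
#'   `score >= score_threshold` are kept (`>` when `strict = TRUE`). The
#'   default 400 is the STRING "medium confidence" cutoff.
#' @param strict Use a strict `>` comparison instead of `>=`.
#' @inheritParams as_gene_network
#' @return A [gene_network][as_gene_network].
#' @export
read_edge_list <- function(path, score_threshold = 400L, strict = FALSE,
                           weight_mode = c("sqrt_degree", "zero")) {
  weight_mode <- match.arg(weight_mode)
  lines <- read_text_lines(path)
  first_data <- 1L
  if (length(lines) > 0) {
    f <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
    if (length(f) >= 3 && is.na(suppressWarnings(as.numeric(f[[3]])))) {
      first_data <- 2L # header row
    }
  }
  rows <- lines[seq_along(lines) >= first_data]
  rows_n <- seq_along(lines)[seq_along(lines) >= first_data]
  keep <- nzchar(trimws(rows))
  rows <- rows[keep]
  rows_n <- rows_n[keep]
  parts <- strsplit(rows, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad) > 0) {
    abort(sprintf(
      "Malformed edge list: line %d has %d tab-separated fields (need >= 3).",
      rows_n[bad[1]], lengths(parts)[bad[1]]
    ))
  }
  ga <- vapply(parts, `[[`, character(1), 1L)
  gb <- vapply(parts, `[[`, character(1), 2L)
  sc_chr <- vapply(parts, `[[`, character(1), 3L)
  sc <- suppressWarnings(as.numeric(sc_chr))
  bad <- which(is.na(sc) | sc != round(sc))
  if (length(bad) > 0) {
    abort(sprintf(
      "Malformed edge list: line %d has non-integer score '%s'.",
      rows_n[bad[1]], sc_chr[bad[1]]
    ))
  }
  edges <- tibble(gene_a = ga, gene_b = gb, score = as.integer(sc))
  edges <- if (strict) {
    dplyr::filter(edges, .data$score > score_threshold)
  } else {
    dplyr::filter(edges, .data$score >= score_threshold)
  }
  edges <- clean_edges(edges)
  if (nrow(edges) == 0) {
    warn("No edges passed the score threshold; returning an empty network.")
  }
  genes <- sort(unique(c(edges$gene_a, edges$gene_b)))
  new_gene_network(genes, edges, weight_mode)
}

read_text_lines <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  readLines(con, warn = FALSE)
}

#' Read a gene list
#'
#' One identifier per line; blank lines and `#` comments are ignored.
#'
#' @param path Path to a text file.
#' @return Character vector of gene identifiers.
#' @export
read_gene_list <- function(path) {
  lines <- read_text_lines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines[nzchar(lines)]
}

#' Restrict a network to a gene universe
#'
#' Takes the induced subgraph on `genes`; genes absent from the network are
#' added as isolated nodes (degree 0, weight 0). Used to align a network with
#' a DNV count table before model fitting.
#'
#' @param net A [gene_network][as_gene_network].
#' @param genes Character vector of genes to keep.
#' @return A `gene_network` whose node set is exactly `sort(unique(genes))`.
#' @export
restrict_to_genes <- function(net, genes) {
  stopifnot(inherits(net, "gene_network"))
  genes <- sort(unique(as.character(genes)))
  edges <- dplyr::filter(
    net$edges,
    .data$gene_a %in% genes & .data$gene_b %in% genes
  )
  new_gene_network(genes, edges, net$weight_mode)
}

#' Build a seed-gene subnetwork
#'
#' Implements the two-step subnetwork construction used to focus a large PPI
#' database on a disease: starting from a base network, take the seed genes
#' plus their direct neighbours connected by a high-confidence edge
#' (`score > neighbor_score_threshold`), then intersect with the genes present
#' in the DNV data. By default the result is the induced subgraph of the base
#' network on the retained nodes; `high_confidence_edges_only = TRUE` instead
#' keeps only edges above the neighbour threshold.
#'
#' @param net A [gene_network][as_gene_network] built at the base threshold
#'   (its edge table must retain scores).
#' @param seeds Character vector of seed genes (known or previously implicated
#'   risk genes); at least one must be present in the network.
#' @param dnv_genes Genes with DNV data; the output node set is a subset of
#'   these.
#' @param neighbor_score_threshold Strict lower bound for seed-neighbour
#'   expansion edges (default 950, the STRING highest-confidence regime).
#' @param high_confidence_edges_only Keep only edges above the neighbour
#'   threshold in the result instead of all base-network edges.
#' @return A `gene_network` on the retained genes.
#' @export
build_seed_subnetwork <- function(net, seeds, dnv_genes,
                                  neighbor_score_threshold = 950L,
                                  high_confidence_edges_only = FALSE) {
  stopifnot(inherits(net, "gene_network"))
  seeds <- unique(as.character(seeds))
  dnv_genes <- unique(as.character(dnv_genes))
  if (length(seeds) == 0) abort("`seeds` must be nonempty.")
  seeds_in <- intersect(seeds, net$nodes$gene)
  if (length(seeds_in) == 0) abort("No seed gene is present in the network.")
  dropped <- setdiff(seeds_in, dnv_genes)
  if (length(dropped) > 0) {
    warn(sprintf(
      "%d seed gene(s) absent from `dnv_genes` were dropped from the result.",
      length(dropped)
    ))
  }
  hi <- dplyr::filter(net$edges, .data$score > neighbor_score_threshold)
  nb <- c(
    hi$gene_b[hi$gene_a %in% seeds_in],
    hi$gene_a[hi$gene_b %in% seeds_in]
  )
  keep <- intersect(union(seeds_in, nb), dnv_genes)
  edges <- if (high_confidence_edges_only) hi else net$edges
  edges <- dplyr::filter(
    edges,
    .data$gene_a %in% keep & .data$gene_b %in% keep
  )
  new_gene_network(sort(keep), edges, net$weight_mode)
}

#' Write a network as a TSV edge list, plus a node summary
#'
#' `write_edge_list()` writes the canonical `gene_a`/`gene_b`/`score` table;
#' `write_node_summary()` writes per-gene degree and MRF weight.
#'
#' @param net A [gene_network][as_gene_network].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  stopifnot(inherits(net, "gene_network"))
  readr::write_tsv(net$edges, path)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
write_node_summary <- function(net, path) {
  stopifnot(inherits(net, "gene_network"))
  readr::write_tsv(net$nodes, path)
  invisible(path)
}

# adjacency in 0-based CSR form for the C++ sweep kernels
network_csr <- function(net) {
  genes <- net$nodes$gene
  n <- length(genes)
  if (nrow(net$edges) == 0) {
    return(list(
      idx = integer(n + 1), nbr = integer(0),
      w = net$nodes$weight, genes = genes
    ))
  }
  ia <- match(net$edges$gene_a, genes)
  ib <- match(net$edges$gene_b, genes)
  from <- c(ia, ib)
  to <- c(ib, ia)
  o <- order(from, to)
  from <- from[o]
  to <- to[o]
  counts <- tabulate(from, nbins = n)
  list(
    idx = c(0L, cumsum(counts)),
    nbr = to - 1L,
    w = net$nodes$weight,
    genes = genes
  )
}

# neighbour lists (1-based), used by pure-R reference paths
network_adjacency <- function(net) {
  csr <- network_csr(net)
  n <- length(csr$genes)
  lapply(seq_len(n), function(i) {
    csr$nbr[seq_len(csr$idx[i + 1] - csr$idx[i]) + csr$idx[i]] + 1L
  })
}
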