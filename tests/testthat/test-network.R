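test_that("edge lists are deduplicated, undirected, and self-loop free", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB\t500", "B\tA\t500", "A\tA\t999"), path)
  net <- read_edge_list(path, score_threshold = 400)
  expect_setequal(net$nodes$gene, c("A", "B"))
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$nodes$degree, c(1L, 1L))
})

test_that("score threshold is >= by default and > with strict", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB\t399", "C\tD\t400"), path)
  net <- read_edge_list(path, score_threshold = 400)
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$gene_a, "C")
  expect_warning(
    net_strict <- read_edge_list(path, score_threshold = 400, strict = TRUE),
    "No edges"
  )
  expect_equal(nrow(net_strict$edges), 0L)
})

test_that("headers are auto-detected and gzip input works", {
  path <- withr::local_tempfile(fileext = ".tsv.gz")
  con <- gzfile(path, "wt")
  writeLines(c("gene_a\tgene_b\tscore", "A\tB\t700"), con)
  close(con)
  net <- read_edge_list(path)
  expect_equal(nrow(net$edges), 1L)
})

test_that("malformed edge lists fail with the offending line number", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB\t500", "C\tD"), path)
  expect_error(read_edge_list(path), "line 2")
  writeLines(c("A\tB\t500", "C\tD\thigh"), path)
  expect_error(read_edge_list(path), "line 2.*high")
})

test_that("MRF weights are sqrt(degree) in network mode, zero otherwise", {
  star <- as_gene_network(tibble::tibble(
    gene_a = "C", gene_b = c("L1", "L2", "L3", "L4")
  ))
  nodes <- tidy(star)
  expect_equal(nodes$weight[nodes$gene == "C"], 2)
  expect_equal(nodes$weight[nodes$gene == "L1"], 1)
  star0 <- as_gene_network(star$edges, weight_mode = "zero")
  expect_true(all(tidy(star0)$weight == 0))
  # handshake identity
  expect_equal(sum(nodes$degree), 2 * nrow(star$edges))
})

test_that("filtering is monotone in the threshold and round-trips", {
  set.seed(11)
  path <- withr::local_tempfile(fileext = ".tsv")
  edges <- tibble::tibble(
    gene_a = sample(LETTERS[1:8], 30, replace = TRUE),
    gene_b = sample(LETTERS[1:8], 30, replace = TRUE),
    score = sample.int(1000, 30)
  )
  readr::write_tsv(edges, path)
  key <- function(net) paste(net$edges$gene_a, net$edges$gene_b)
  prev <- NULL
  for (thr in c(0, 250, 500, 750, 1000)) {
    net <- suppressWarnings(read_edge_list(path, score_threshold = thr))
    if (!is.null(prev)) expect_true(all(key(net) %in% prev))
    prev <- key(net)
  }
  # write -> read identity on node and edge sets
  net <- read_edge_list(path, score_threshold = 400)
  out <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(net, out)
  net2 <- read_edge_list(out, score_threshold = 0)
  expect_identical(net$edges, net2$edges)
  expect_identical(net$nodes, net2$nodes)
})

test_that("restrict_to_genes induces subgraphs and adds isolated nodes", {
  net <- as_gene_network(tibble::tibble(gene_a = "A", gene_b = "B"))
  r <- restrict_to_genes(net, c("A", "B", "C"))
  expect_equal(r$nodes$gene, c("A", "B", "C"))
  expect_equal(nrow(r$edges), 1L)
  expect_equal(r$nodes$degree[r$nodes$gene == "C"], 0L)
  expect_equal(r$nodes$weight[r$nodes$gene == "C"], 0)
  r <- restrict_to_genes(net, "A")
  expect_equal(r$nodes$gene, "A")
  expect_equal(nrow(r$edges), 0L)
  r <- restrict_to_genes(net, character(0))
  expect_equal(nrow(r$nodes), 0L)
})

test_that("seed subnetwork keeps seeds plus high-confidence neighbours in the DNV universe", {
  net <- as_gene_network(tibble::tibble(
    gene_a = c("A", "A", "B"), gene_b = c("B", "C", "C"),
    score = c(960L, 900L, 960L)
  ))
  # C's seed-incident edge is below the neighbour threshold
  g2 <- build_seed_subnetwork(net, seeds = "A", dnv_genes = c("A", "B", "C"))
  expect_setequal(g2$nodes$gene, c("A", "B"))
  # intersection with DNV genes dominates
  g2 <- build_seed_subnetwork(net, seeds = "A", dnv_genes = "A")
  expect_equal(g2$nodes$gene, "A")
  expect_equal(nrow(g2$edges), 0L)
  expect_equal(g2$nodes$degree, 0L)
  # one-hop rule: neighbours of neighbours are not pulled in
  path_net <- as_gene_network(tibble::tibble(
    gene_a = c("S", "X"), gene_b = c("X", "Y"), score = 999L
  ))
  g2 <- build_seed_subnetwork(path_net, "S", dnv_genes = c("S", "X", "Y"))
  expect_setequal(g2$nodes$gene, c("S", "X"))
})

test_that("seed subnetwork errors and warnings", {
  net <- as_gene_network(tibble::tibble(gene_a = "A", gene_b = "B", score = 999L))
  expect_error(build_seed_subnetwork(net, "Z", dnv_genes = "A"), "seed")
  expect_warning(
    build_seed_subnetwork(net, "A", dnv_genes = "B"),
    "dropped"
  )
})

test_that("seed subnetwork node set is always within the DNV universe", {
  set.seed(21)
  for (rep in 1:20) {
    net <- random_network(8, p = 0.4)
    net$edges$score <- sample.int(1000, nrow(net$edges), replace = TRUE)
    net <- as_gene_network(net$edges, genes = net$nodes$gene)
    dnv <- sample(net$nodes$gene, 5)
    seeds <- sample(net$nodes$gene, 2)
    g2 <- tryCatch(
      suppressWarnings(build_seed_subnetwork(net, seeds, dnv_genes = dnv)),
      error = function(e) NULL
    )
    if (!is.null(g2)) expect_true(all(g2$nodes$gene %in% dnv))
  }
})
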