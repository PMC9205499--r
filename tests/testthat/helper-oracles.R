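# Independent oracles used across the suite. Everything here works by direct
# enumeration or brute-force summation and never calls the package's sweep
# kernels, so agreement is a genuine cross-check.

# all 2^n label configurations of an n-gene network, as rows of +/-1
all_states <- function(n) {
  as.matrix(expand.grid(rep(list(c(-1L, 1L)), n)))
}

# unnormalized log joint: MRF prior term plus optional per-gene emission
# log-likelihood difference (log f(y|+1) - log f(y|-1); the -1 part is a
# constant and cancels in every normalization)
log_joint_oracle <- function(s, net, params, led = NULL) {
  w <- setNames(net$nodes$weight, net$nodes$gene)
  names(s) <- net$nodes$gene
  val <- params$h * sum(s == 1)
  for (r in seq_len(nrow(net$edges))) {
    a <- net$edges$gene_a[r]
    b <- net$edges$gene_b[r]
    if (s[a] == -1 && s[b] == -1) val <- val + params$tau0 * (w[a] + w[b])
    if (s[a] == 1 && s[b] == 1) val <- val + params$tau1 * (w[a] + w[b])
  }
  if (!is.null(led)) val <- val + sum(led[s == 1])
  unname(val)
}

# exact P(S_i = +1 | all other coordinates) from the joint Gibbs measure
exact_conditional_oracle <- function(i, s, net, params) {
  s_plus <- s
  s_plus[i] <- 1L
  s_minus <- s
  s_minus[i] <- -1L
  lp <- log_joint_oracle(s_plus, net, params)
  lm <- log_joint_oracle(s_minus, net, params)
  1 / (1 + exp(lm - lp))
}

# exact marginals P(S_i = -1 | Y) by summing the joint over all 2^n states
exact_qneg_oracle <- function(net, params, led) {
  n <- nrow(net$nodes)
  states <- all_states(n)
  lw <- apply(states, 1, function(s) {
    log_joint_oracle(as.integer(s), net, params, led)
  })
  wts <- exp(lw - max(lw))
  wts <- wts / sum(wts)
  vapply(seq_len(n), function(i) sum(wts[states[, i] == -1L]), numeric(1))
}

# Erdos-Renyi style random network on n genes with edge probability p
random_network <- function(n, p = 0.4, weight_mode = "sqrt_degree") {
  genes <- sprintf("n%02d", seq_len(n))
  pairs <- utils::combn(genes, 2)
  keep <- runif(ncol(pairs)) < p
  edges <- tibble::tibble(
    gene_a = pairs[1, keep], gene_b = pairs[2, keep], score = 1000L
  )
  as_gene_network(edges, genes = genes, weight_mode = weight_mode)
}

random_mrf_params <- function() {
  mrf_params(h = runif(1, -4, 1), tau0 = runif(1, 0, 0.8),
             tau1 = runif(1, 0, 0.8))
}

# hyperparameters in the regime the model operates in (strongly negative
# marginal log-odds, weak-to-moderate coupling); used for MCMC accuracy
# checks, where a single Gibbs chain is only expected to mix within a mode
# structure like the fitted models produce
random_operating_params <- function() {
  mrf_params(h = runif(1, -4, -1), tau0 = runif(1, 0, 0.3),
             tau1 = runif(1, 0, 0.6))
}

# small aligned gene table for a network
random_gene_table_for <- function(net, n_trios = 2000L) {
  n <- nrow(net$nodes)
  gene_table(
    tibble::tibble(
      gene = net$nodes$gene,
      count = rpois(n, 0.5) + rbinom(n, 1, 0.2) * rpois(n, 2),
      mutability = 10^runif(n, -6.5, -5)
    ),
    n_trios = n_trios
  )
}
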