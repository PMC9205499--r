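#' Simulation settings for the network-assisted DNV study design
#'
#' Bundles the generative conditions for a synthetic study: a scale-free
#' (preferential-attachment) gene network standing in for a PPI subnetwork,
#' per-gene mutabilities drawn on the log10 scale, latent risk states sampled
#' from the MRF prior by Gibbs sweeps, and Poisson DNV counts given the
#' states. Defaults follow the reference study design: `h = -4`, `tau0 = 0`,
#' `tau1` varied around 0.1--0.9, cohort sizes 2,000--10,000 trios, and a log
#' relative risk `beta` of 3--4; the prior sampler runs 5,000 sweeps with
#' 2,000 burn-in.
#'
#' @param n_genes Number of genes (`>= 2`).
#' @param pa_m Edges attached per node in the preferential-attachment graph.
#' @param h,tau0,tau1 True MRF hyperparameters.
#' @param beta True log relative risk; `gamma = exp(beta)`.
#' @param n_trios Cohort size.
#' @param mu_log10_mean,mu_log10_sd,mu_range Mutability model:
#'   `log10(mu) ~ Normal(mean, sd)` truncated so `mu` lies in `mu_range`.
#' @param prior_n_iter,prior_n_burnin Gibbs sweeps for drawing latent states
#'   from the MRF prior.
#' @param network Optional [gene_network][as_gene_network] to use instead of
#'   a synthetic one (preserves fidelity when a real PPI network is
#'   available).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 2000L, pa_m = 1L, h = -4, tau0 = 0,
                       tau1 = 0.5, beta = 3.5, n_trios = 5000L,
                       mu_log10_mean = -5.7, mu_log10_sd = 0.6,
                       mu_range = c(1e-8, 1e-4),
                       prior_n_iter = 5000L, prior_n_burnin = 2000L,
                       network = NULL) {
  stopifnot(n_genes >= 2, n_trios >= 1, beta >= 0, mu_log10_sd >= 0,
            prior_n_iter > prior_n_burnin)
  structure(
    list(
      n_genes = as.integer(n_genes), pa_m = as.integer(pa_m),
      h = h, tau0 = tau0, tau1 = tau1, beta = beta,
      n_trios = as.integer(n_trios),
      mu_log10_mean = mu_log10_mean, mu_log10_sd = mu_log10_sd,
      mu_range = mu_range,
      prior_n_iter = as.integer(prior_n_iter),
      prior_n_burnin = as.integer(prior_n_burnin),
      network = network
    ),
    class = "sim_config"
  )
}

#' Synthetic scale-free gene network
#'
#' Preferential-attachment (Barabasi-Albert) graph over `n_genes` genes,
#' approximating the heavy-tailed degree distribution of PPI networks. All
#' edges carry the maximal confidence score.
#'
#' @inheritParams sim_config
#' @return A [gene_network][as_gene_network].
#' @export
sim_ppi_network <- function(n_genes, pa_m = 1L) {
  g <- igraph::sample_pa(n_genes, m = pa_m, directed = FALSE)
  el <- igraph::as_edgelist(g, names = FALSE)
  width <- nchar(as.character(n_genes))
  gene_id <- sprintf("g%0*d", width, seq_len(n_genes))
  as_gene_network(
    tibble(
      gene_a = gene_id[el[, 1]], gene_b = gene_id[el[, 2]], score = 1000L
    ),
    genes = gene_id
  )
}

#' Synthetic per-gene mutabilities
#'
#' Draws `log10(mu)` from a truncated normal so mutabilities stay in a
#' realistic range for damaging variant classes; at typical cohort sizes this
#' puts null expected counts on the order of 0.01--0.1.
#'
#' @param n Number of genes.
#' @inheritParams sim_config
#' @return Numeric vector of mutabilities.
#' @export
sim_mutability <- function(n, mu_log10_mean = -5.7, mu_log10_sd = 0.6,
                           mu_range = c(1e-8, 1e-4)) {
  lo <- (log10(mu_range[1]) - mu_log10_mean) / mu_log10_sd
  hi <- (log10(mu_range[2]) - mu_log10_mean) / mu_log10_sd
  u <- runif(n, stats::pnorm(lo), stats::pnorm(hi))
  10^(mu_log10_mean + mu_log10_sd * qnorm(u))
}

#' Draw latent risk states from the MRF prior
#'
#' Runs Gibbs sweeps over the prior full conditionals (no data term) and
#' returns the final post-burn-in state: one draw from the Gibbs measure.
#' Initial labels are independent Bernoulli at the isolated-gene marginal
#' `plogis(h)`.
#'
#' @inheritParams log_prior_unnorm
#' @param n_iter,n_burnin Gibbs sweeps and burn-in.
#' @return Named vector of `{-1, +1}` states over the network genes.
#' @export
sample_latent_states <- function(net, params, n_iter = 5000L,
                                 n_burnin = 2000L) {
  genes <- net$nodes$gene
  s0 <- ifelse(runif(length(genes)) < plogis(params$h), 1L, -1L)
  csr <- network_csr(net)
  res <- .gibbs_sweeps_cpp(csr$idx, csr$nbr, csr$w, params$h, params$tau0,
                           params$tau1, numeric(length(genes)), s0,
                           as.integer(n_iter), as.integer(n_burnin))
  setNames(res$state, genes)
}

#' Draw Poisson DNV counts given latent states
#'
#' @param state Vector of `{-1, +1}` latent states.
#' @param mutability Per-gene mutabilities aligned with `state`.
#' @param n_trios Cohort size.
#' @param gamma Relative risk in risk genes (`>= 1`).
#' @return Integer vector of counts.
#' @export
sample_dnv_counts <- function(state, mutability, n_trios, gamma) {
  stopifnot(length(state) == length(mutability), gamma >= 1)
  rate <- 2 * n_trios * mutability * ifelse(state == 1, gamma, 1)
  rpois(length(state), rate)
}

#' Simulate one synthetic DNV study
#'
#' Generates (or reuses) a network, draws mutabilities, latent states from
#' the MRF prior, and Poisson counts, yielding a complete synthetic dataset
#' with known truth.
#'
#' @param config A [sim_config].
#' @return A `dnv_sim` list: `network`, `gene_table`, `state_true` (named
#'   vector), and `config`.
#' @export
simulate_dnv_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  net <- if (is.null(config$network)) {
    sim_ppi_network(config$n_genes, config$pa_m)
  } else {
    config$network
  }
  genes <- net$nodes$gene
  mu <- sim_mutability(length(genes), config$mu_log10_mean,
                       config$mu_log10_sd, config$mu_range)
  s <- sample_latent_states(
    net, mrf_params(config$h, config$tau0, config$tau1),
    config$prior_n_iter, config$prior_n_burnin
  )
  y <- sample_dnv_counts(s, mu, config$n_trios, exp(config$beta))
  structure(
    list(
      network = net,
      gene_table = gene_table(
        tibble(gene = genes, count = y, mutability = mu), config$n_trios
      ),
      state_true = s,
      config = config
    ),
    class = "dnv_sim"
  )
}

#' @export
print.dnv_sim <- function(x, ...) {
  cat(sprintf(
    "<dnv_sim> %d genes, %d edges, %d true risk genes, %d DNVs total\n",
    nrow(x$gene_table), nrow(x$network$edges), sum(x$state_true == 1L),
    sum(x$gene_table$count)
  ))
  invisible(x)
}

#' Power and FDR study across simulation replicates
#'
#' For each replicate, simulates a study and applies the requested methods:
#' the network-assisted test (`"ndata"`), the same model ignoring the network
#' (`"ndata_nonet"`, all weights zero), and a per-gene Poisson upper-tail
#' test with Benjamini-Hochberg adjustment (`"poisson_bh"`). Power is the
#' fraction of true risk genes rejected; the false discovery proportion (FDP)
#' is `FP / max(1, rejections)`. Replicates where a fit fails to converge are
#' flagged, not dropped.
#'
#' @param config A [sim_config].
#' @param n_replicates Number of replicates.
#' @param methods Subset of `c("ndata", "ndata_nonet", "poisson_bh")`.
#' @param alpha FDR level for every method.
#' @param n_iter,n_burnin Posterior Gibbs settings for the model-based
#'   methods.
#' @param fit_args Extra arguments passed to [mrf_fit()].
#' @return A tibble with one row per replicate and method: `replicate`,
#'   `method`, `n_true_risk`, `n_rejected`, `power`, `fdp`, `converged`.
#' @export
run_power_study <- function(config, n_replicates = 20L,
                            methods = c("ndata", "ndata_nonet", "poisson_bh"),
                            alpha = 0.05, n_iter = 2000L, n_burnin = 1000L,
                            fit_args = list()) {
  methods <- match.arg(methods, several.ok = TRUE)
  purrr::map_dfr(seq_len(n_replicates), function(rep) {
    sim <- simulate_dnv_study(config)
    truth <- sim$state_true == 1L
    purrr::map_dfr(methods, function(m) {
      rej <- NULL
      converged <- TRUE
      if (m == "poisson_bh") {
        pt <- poisson_tail_test(sim$gene_table)
        rej <- pt$p_adjusted < alpha
      } else {
        res <- tryCatch(
          do.call(ndata, c(
            list(sim$gene_table, sim$network, alpha = alpha,
                 n_iter = n_iter, n_burnin = n_burnin, min_count = 0L,
                 no_network = (m == "ndata_nonet")),
            fit_args
          )),
          error = function(e) NULL
        )
        if (is.null(res)) {
          converged <- FALSE
          rej <- rep(FALSE, nrow(sim$gene_table))
        } else {
          converged <- res$fit$converged
          rej <- res$genes$rejected
        }
      }
      tp <- sum(rej & truth)
      fp <- sum(rej & !truth)
      tibble(
        replicate = rep, method = m,
        n_true_risk = sum(truth), n_rejected = sum(rej),
        power = if (sum(truth) > 0) tp / sum(truth) else NA_real_,
        fdp = fp / max(1L, sum(rej)),
        converged = converged
      )
    })
  })
}

#' Summarise a power study by method
#'
#' Means and standard errors of power and FDP across replicates.
#'
#' @param x Output of [run_power_study()].
#' @return One row per method with `mean_power`, `se_power`, `mean_fdp`,
#'   `se_fdp`, `n_replicates`.
#' @export
summarise_power_study <- function(x) {
  x |>
    dplyr::summarise(
      n_replicates = dplyr::n(),
      mean_power = mean(.data$power, na.rm = TRUE),
      se_power = stats::sd(.data$power, na.rm = TRUE) / sqrt(dplyr::n()),
      mean_fdp = mean(.data$fdp),
      se_fdp = stats::sd(.data$fdp) / sqrt(dplyr::n()),
      prop_converged = mean(.data$converged),
      .by = "method"
    )
}
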