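#' Gibbs-sampler posterior probabilities of non-association
#'
#' At the fitted hyperparameters, runs a systematic-sweep Gibbs sampler over
#' the latent labels, each gene's full conditional being proportional to its
#' Poisson emission times the logistic-form MRF conditional. The returned
#' `q_i` is the fraction of post-burn-in sweeps in which gene *i* was
#' labelled `-1`, i.e. the estimated local false discovery rate
#' `P(S_i = -1 | Y)`. The sweep order is lexicographic and all randomness
#' comes from R's RNG, so results are reproducible under `set.seed()`.
#'
#' @param object An [mrf_fit], or a [gene_table] (then `network`, `params`
#'   and `gamma` must be given).
#' @param n_iter Total Gibbs sweeps (default 5000).
#' @param n_burnin Burn-in sweeps discarded from the average (default 2000).
#'   At least 2000 sweeps with the first 1000 as burn-in are advisable for
#'   stable estimates.
#' @param network,params,gamma,n_trios Model pieces when `object` is a gene
#'   table.
#' @param state_init Optional initial labels; defaults to the fitted labels
#'   (or all `-1`).
#' @param ... Unused.
#' @return A tibble with `gene` and `q`.
#' @export
gibbs_posterior <- function(object, ...) UseMethod("gibbs_posterior")

#' @rdname gibbs_posterior
#' @export
gibbs_posterior.mrf_fit <- function(object, n_iter = 5000L, n_burnin = 2000L,
                                    state_init = NULL, ...) {
  gibbs_posterior_impl(
    object$gene_table, object$network, object$params, object$gamma,
    object$n_trios, n_iter, n_burnin,
    if (is.null(state_init)) object$state else state_init
  )
}

#' @rdname gibbs_posterior
#' @export
gibbs_posterior.default <- function(object, network, params, gamma,
                                    n_trios = NULL, n_iter = 5000L,
                                    n_burnin = 2000L, state_init = NULL, ...) {
  if (is.null(n_trios)) n_trios <- n_trios(object)
  x <- gene_table(as_tibble(object)[c("gene", "count", "mutability")], n_trios)
  network <- restrict_to_genes(network, x$gene)
  gibbs_posterior_impl(x, network, params, gamma, n_trios, n_iter, n_burnin,
                       state_init)
}

gibbs_posterior_impl <- function(x, net, params, gamma, n_trios,
                                 n_iter, n_burnin, state_init = NULL) {
  n_iter <- as.integer(n_iter)
  n_burnin <- as.integer(n_burnin)
  if (!(n_iter > n_burnin && n_burnin >= 0)) {
    abort("Need `n_iter > n_burnin >= 0`.")
  }
  if (is.null(state_init)) {
    state_init <- setNames(rep(-1L, nrow(x)), x$gene)
  }
  state_init <- align_state(state_init, net)
  csr <- network_csr(net)
  led <- log_emission_diff(x$count, x$mutability, n_trios, gamma)
  res <- .gibbs_sweeps_cpp(csr$idx, csr$nbr, csr$w, params$h, params$tau0,
                           params$tau1, led, unname(state_init),
                           n_iter, n_burnin)
  tibble(gene = csr$genes, q = res$q)
}

#' Global-FDR rejection rule on local fdr values
#'
#' Orders the local fdr values `q` ascending (most likely associated first;
#' ties broken by position) and rejects the largest prefix whose running mean
#' stays at or below `alpha`. Because the global FDR of a rejection set is
#' the expected local fdr over that set, this controls the global FDR at
#' `alpha`.
#'
#' @param q Numeric vector of local fdr values in `[0, 1]`.
#' @param alpha Target global FDR level in (0, 1).
#' @return Logical vector, `TRUE` for rejected (declared risk) genes, in the
#'   input order.
#' @examples
#' fdr_select(c(0.01, 0.02, 0.10, 0.50), alpha = 0.05)
#' @export
fdr_select <- function(q, alpha = 0.05) {
  if (any(q < 0 | q > 1, na.rm = TRUE)) abort("`q` must lie in [0, 1].")
  if (!(alpha > 0 && alpha < 1)) abort("`alpha` must be in (0, 1).")
  o <- order(q)
  cm <- cumsum(q[o]) / seq_along(q)
  m <- max(c(0L, which(cm <= alpha)))
  rejected <- logical(length(q))
  if (m > 0) rejected[o[seq_len(m)]] <- TRUE
  rejected
}

#' Restrict a rejection set to genes with observed DNVs
#'
#' Genes can be prioritized purely through their network neighbourhood while
#' carrying no DNV in the cohort; for reporting, such genes are filtered out.
#' Keeps rejected genes with `count >= min_count`.
#'
#' @param rejected Logical vector aligned with `x`.
#' @param x A [gene_table] (or data frame with a `count` column).
#' @param min_count Minimum DNV count to report (default 1; 0 disables the
#'   filter).
#' @return Logical vector: rejected and passing the count filter.
#' @export
apply_dnv_filter <- function(rejected, x, min_count = 1L) {
  stopifnot(length(rejected) == nrow(x), min_count >= 0)
  rejected & (x$count >= min_count)
}

#' Network-assisted de novo association test
#'
#' The full pipeline: fit the MRF burden model ([mrf_fit()]), estimate
#' per-gene posterior probabilities of non-association by Gibbs sampling
#' ([gibbs_posterior()]), reject at a global FDR level ([fdr_select()]), and
#' restrict reporting to genes with at least `min_count` DNVs
#' ([apply_dnv_filter()]).
#'
#' @inheritParams mrf_fit
#' @param alpha Global FDR level.
#' @param n_iter,n_burnin Gibbs sweeps and burn-in for the posterior.
#' @param min_count Minimum DNV count for the reported set.
#' @param ... Passed to [mrf_fit()].
#' @return An object of class `ndata_result` with elements `genes` (tibble:
#'   `gene`, `count`, `mutability`, `degree`, `q`, `rejected`, `reported`),
#'   `fit` (the [mrf_fit]), and the run settings. [tidy()] returns the gene
#'   tibble, [glance()] a one-row run summary, and [autoplot()] the sorted
#'   local-fdr curve against the FDR level.
#' @examples
#' set.seed(7)
#' sim <- simulate_dnv_study(sim_config(n_genes = 300, n_trios = 5000))
#' res <- ndata(sim$gene_table, sim$network, n_iter = 500, n_burnin = 200)
#' glance(res)
#' @export
ndata <- function(x, network = NULL, n_trios = NULL, alpha = 0.05,
                  n_iter = 5000L, n_burnin = 2000L, min_count = 1L, ...) {
  fit <- mrf_fit(x, network, n_trios = n_trios, ...)
  post <- gibbs_posterior(fit, n_iter = n_iter, n_burnin = n_burnin)
  stopifnot(identical(post$gene, fit$gene_table$gene))
  rejected <- fdr_select(post$q, alpha)
  reported <- apply_dnv_filter(rejected, fit$gene_table, min_count)
  genes <- fit$gene_table |>
    dplyr::left_join(
      fit$network$nodes[c("gene", "degree")], by = "gene"
    ) |>
    dplyr::mutate(
      q = post$q, rejected = rejected, reported = reported
    ) |>
    as_tibble()
  structure(
    list(
      genes = genes, fit = fit, alpha = alpha,
      n_iter = as.integer(n_iter), n_burnin = as.integer(n_burnin),
      min_count = as.integer(min_count)
    ),
    class = "ndata_result"
  )
}

#' @export
print.ndata_result <- function(x, ...) {
  cat(sprintf(
    paste0("<ndata_result> %d genes; FDR level %.3g\n",
           "  %d rejected; %d reported (count >= %d)\n",
           "  gamma = %.2f (log rr = %.2f), h = %.3f, tau1 = %.3f\n"),
    nrow(x$genes), x$alpha, sum(x$genes$rejected), sum(x$genes$reported),
    x$min_count, x$fit$gamma, log(x$fit$gamma), x$fit$params$h,
    x$fit$params$tau1
  ))
  invisible(x)
}

#' @describeIn ndata Per-gene results tibble.
#' @exportS3Method
tidy.ndata_result <- function(x, ...) x$genes

#' @describeIn ndata One-row run summary.
#' @exportS3Method
glance.ndata_result <- function(x, ...) {
  dplyr::bind_cols(
    glance(x$fit)[c("h", "tau0", "tau1", "gamma", "log_gamma", "converged")],
    tibble(
      alpha = x$alpha,
      n_rejected = sum(x$genes$rejected),
      n_reported = sum(x$genes$reported),
      n_iter = x$n_iter, n_burnin = x$n_burnin
    )
  )
}

#' @describeIn ndata Sorted local-fdr curve with the running mean and the
#'   FDR level.
#' @exportS3Method
autoplot.ndata_result <- function(object, ...) {
  df <- object$genes |>
    dplyr::arrange(.data$q) |>
    dplyr::mutate(
      rank = dplyr::row_number(),
      running_mean = cumsum(.data$q) / .data$rank
    )
  ggplot2::ggplot(df, ggplot2::aes(.data$rank)) +
    ggplot2::geom_step(ggplot2::aes(y = .data$q, colour = "local fdr")) +
    ggplot2::geom_step(ggplot2::aes(y = .data$running_mean,
                                    colour = "running mean")) +
    ggplot2::geom_hline(yintercept = object$alpha, linetype = 2) +
    ggplot2::labs(x = "Genes ranked by local fdr", y = NULL, colour = NULL)
}

#' Write pipeline results to disk
#'
#' Writes the per-gene table as TSV and the run metadata (parameters, FDR
#' level, sampler settings) as JSON.
#'
#' @param result An `ndata_result`.
#' @param tsv_path,json_path Output paths (`NULL` to skip either).
#' @return `result`, invisibly.
#' @export
write_ndata_result <- function(result, tsv_path, json_path = NULL) {
  stopifnot(inherits(result, "ndata_result"))
  if (!is.null(tsv_path)) {
    out <- dplyr::mutate(result$genes,
      rejected = as.integer(.data$rejected),
      reported = as.integer(.data$reported)
    )
    readr::write_tsv(out, tsv_path)
  }
  if (!is.null(json_path)) {
    meta <- list(
      h = result$fit$params$h, tau0 = result$fit$params$tau0,
      tau1 = result$fit$params$tau1, gamma = result$fit$gamma,
      iterations = result$fit$iterations, converged = result$fit$converged,
      pclk_trace = result$fit$pclk_trace,
      alpha = result$alpha, n_iter = result$n_iter,
      n_burnin = result$n_burnin, min_count = result$min_count,
      n_rejected = sum(result$genes$rejected),
      n_reported = sum(result$genes$reported)
    )
    jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(result)
}
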