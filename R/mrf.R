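#' MRF hyperparameters
#'
#' The latent risk states follow a discrete Markov random field (nearest
#' neighbour Gibbs measure) on the gene network with joint density
#' proportional to
#' `exp{ h * #(S_i = +1) + tau0 * sum_{edges, both -1} (w_i + w_j) +
#'       tau1 * sum_{edges, both +1} (w_i + w_j) }`.
#' `h` sets the marginal log-odds that an isolated gene is a risk gene;
#' `tau0` and `tau1` weight edges between concordant non-risk and risk pairs
#' respectively, so positive `tau1` makes risk genes cluster on the network.
#'
#' @param h Marginal log-odds of association (real).
#' @param tau0,tau1 Nonnegative edge affinities for non-risk/risk concordant
#'   pairs.
#' @return An `mrf_params` object.
#' @export
mrf_params <- function(h, tau0 = 0, tau1 = 0) {
  stopifnot(is.finite(h), is.finite(tau0), is.finite(tau1))
  if (tau0 < 0 || tau1 < 0) abort("`tau0` and `tau1` must be nonnegative.")
  structure(list(h = h, tau0 = tau0, tau1 = tau1), class = "mrf_params")
}

#' @export
print.mrf_params <- function(x, ...) {
  cat(sprintf("<mrf_params> h = %.4g, tau0 = %.4g, tau1 = %.4g\n",
              x$h, x$tau0, x$tau1))
  invisible(x)
}

# state must be a vector of +/-1 aligned with (or named by) the network's genes
align_state <- function(state, net) {
  genes <- net$nodes$gene
  if (!is.null(names(state))) {
    if (!setequal(names(state), genes)) {
      abort("`state` names do not match the network's genes.")
    }
    state <- state[genes]
  } else if (length(state) != length(genes)) {
    abort(sprintf("`state` has length %d but the network has %d genes.",
                  length(state), length(genes)))
  }
  state <- as.integer(state)
  if (!all(state %in% c(-1L, 1L))) abort("`state` entries must be -1 or +1.")
  names(state) <- genes
  state
}

#' Unnormalized log prior of a latent state configuration
#'
#' @param state Vector of latent risk states in `{-1, +1}`, aligned with (or
#'   named by) the network's genes.
#' @param net A [gene_network][as_gene_network].
#' @param params An [mrf_params] object.
#' @return The log of the unnormalized Gibbs density.
#' @export
log_prior_unnorm <- function(state, net, params) {
  state <- align_state(state, net)
  w <- setNames(net$nodes$weight, net$nodes$gene)
  e <- net$edges
  sa <- state[e$gene_a]
  sb <- state[e$gene_b]
  wsum <- w[e$gene_a] + w[e$gene_b]
  params$h * sum(state == 1L) +
    params$tau0 * sum(wsum[sa == -1L & sb == -1L]) +
    params$tau1 * sum(wsum[sa == 1L & sb == 1L])
}

#' Neighbour covariates of the pseudo-likelihood logistic form
#'
#' For gene *i* with weight `w_i` and neighbours `N_i`,
#' `x1_i = w_i * #(risk neighbours) + sum of weights of risk neighbours`, and
#' `x0_i` analogously for non-risk neighbours. These are the sufficient
#' statistics through which a gene's full conditional depends on its
#' neighbourhood; both are zero for isolated genes.
#'
#' @inheritParams log_prior_unnorm
#' @return A tibble with `gene`, `x1`, `x0`.
#' @export
compute_covariates <- function(state, net) {
  state <- align_state(state, net)
  adj <- network_adjacency(net)
  w <- net$nodes$weight
  n <- length(state)
  x1 <- numeric(n)
  x0 <- numeric(n)
  for (i in seq_len(n)) {
    nb <- adj[[i]]
    if (length(nb) == 0) next
    pos <- state[nb] == 1L
    x1[i] <- w[i] * sum(pos) + sum(w[nb][pos])
    x0[i] <- w[i] * sum(!pos) + sum(w[nb][!pos])
  }
  tibble(gene = net$nodes$gene, x1 = x1, x0 = x0)
}

#' Full conditional probability of association
#'
#' The MRF's full conditional for each gene is logistic in the neighbour
#' covariates: `logit P(S_i = +1 | S_{N_i}) = h + tau1 * x1_i - tau0 * x0_i`.
#' For an isolated gene this reduces to `plogis(h)`, the marginal association
#' probability.
#'
#' @inheritParams log_prior_unnorm
#' @return Named vector of `P(S_i = +1 | neighbours)` over the network genes.
#' @export
conditional_prob <- function(state, net, params) {
  cov <- compute_covariates(state, net)
  setNames(
    plogis(params$h + params$tau1 * cov$x1 - params$tau0 * cov$x0),
    cov$gene
  )
}

#' Estimate the MRF hyperparameters by penalized pseudo-likelihood
#'
#' Maximizes `sum_i log P(S_i | S_{N_i}, h, tau0, tau1) -
#' lambda * (h^2 + tau0^2 + tau1^2)` by Newton-Raphson on the equivalent
#' logistic regression with design `(1, x1, -x0)` and response
#' `I(S_i = +1)`. With `nonneg = TRUE` (default) the edge affinities are
#' constrained to be nonnegative via exact active-set enumeration (the
#' penalized objective is concave, so the KKT point is the optimum). The
#' ridge term keeps the estimate finite when the labels are separable; with
#' `lambda = 0` and separable data the fit diverges and an error of class
#' `dnvnet_separation_error` is raised carrying the last iterate and gradient
#' norm.
#'
#' @inheritParams log_prior_unnorm
#' @param lambda Ridge penalty (`>= 0`), applied to all three parameters.
#' @param nonneg Constrain `tau0, tau1 >= 0`.
#' @param max_iter Newton iteration cap per active set.
#' @return An [mrf_params] with attributes `iterations` and `gradient_norm`.
#' @export
fit_theta0 <- function(state, net, lambda = 0.1, nonneg = TRUE,
                       max_iter = 100L) {
  state <- align_state(state, net)
  if (lambda < 0) abort("`lambda` must be >= 0.")
  cov <- compute_covariates(state, net)
  y <- as.numeric(state == 1L)
  X <- cbind(1, cov$x1, -cov$x0) # coefficients (h, tau1, tau0)
  zero_col <- apply(X == 0, 2, all)

  obj <- function(b) {
    eta <- drop(X %*% b)
    sum(y * eta - log1p(exp(eta))) - lambda * sum(b^2)
  }
  grad <- function(b) {
    eta <- drop(X %*% b)
    drop(crossprod(X, y - plogis(eta))) - 2 * lambda * b
  }

  newton_fixed <- function(fixed) {
    # coordinates in `fixed` (and all-zero columns) held at 0
    free <- setdiff(which(!zero_col), fixed)
    b <- c(0, 0, 0)
    if (length(free) == 0) {
      return(list(b = b, iters = 0L, gnorm = 0, ok = TRUE))
    }
    f_old <- obj(b)
    for (it in seq_len(max_iter)) {
      eta <- drop(X %*% b)
      p <- plogis(eta)
      g <- drop(crossprod(X[, free, drop = FALSE], y - p)) - 2 * lambda * b[free]
      Wv <- p * (1 - p)
      H <- crossprod(X[, free, drop = FALSE] * Wv, X[, free, drop = FALSE]) +
        diag(2 * lambda, length(free))
      step <- tryCatch(solve(H, g), error = function(e) NULL)
      if (is.null(step)) return(list(b = b, iters = it, gnorm = sqrt(sum(g^2)), ok = FALSE))
      # step halving for global stability
      t <- 1
      repeat {
        b_new <- b
        b_new[free] <- b[free] + t * step
        f_new <- obj(b_new)
        if (f_new >= f_old - 1e-12 || t < 1e-6) break
        t <- t / 2
      }
      b <- b_new
      f_old <- f_new
      # |log-odds| beyond ~20 means the likelihood is flat to machine
      # precision: quasi-separation, not a meaningful maximum
      if (max(abs(b)) > 20) {
        return(list(b = b, iters = it, gnorm = sqrt(sum(g^2)), ok = FALSE))
      }
      if (sqrt(sum(g^2)) < 1e-10) {
        return(list(b = b, iters = it, gnorm = sqrt(sum(g^2)), ok = TRUE))
      }
    }
    g <- grad(b)[free]
    list(b = b, iters = max_iter, gnorm = sqrt(sum(g^2)),
         ok = sqrt(sum(g^2)) < 1e-8)
  }

  fail <- function(res) {
    abort(
      sprintf(paste0(
        "Pseudo-likelihood logistic fit did not converge ",
        "(gradient norm %.3g); the labels may be separable. ",
        "Use a positive ridge `lambda`."), res$gnorm),
      class = "dnvnet_separation_error",
      last_estimate = res$b,
      gradient_norm = res$gnorm
    )
  }

  if (!nonneg) {
    res <- newton_fixed(integer(0))
    if (!res$ok) fail(res)
    b <- res$b
  } else {
    # active sets over the two sign-constrained coordinates (tau1 = b2, tau0 = b3)
    best <- NULL
    for (fixed in list(integer(0), 2L, 3L, c(2L, 3L))) {
      res <- newton_fixed(fixed)
      if (!res$ok) {
        if (length(fixed) == 2) fail(res) # even the intercept-only fit failed
        next
      }
      b <- res$b
      if (any(b[2:3] < -1e-9)) next # infeasible
      g <- grad(b)
      kkt <- all(g[intersect(fixed, which(!zero_col))] <= 1e-7)
      if (!kkt) next
      cand <- list(b = b, res = res, value = obj(b))
      if (is.null(best) || cand$value > best$value) best <- cand
    }
    if (is.null(best)) {
      fail(newton_fixed(integer(0)))
    }
    b <- best$b
    res <- best$res
  }
  b[2:3][abs(b[2:3]) < 1e-12] <- 0
  out <- mrf_params(h = b[1], tau0 = max(b[3], 0), tau1 = max(b[2], 0))
  attr(out, "iterations") <- res$iters
  attr(out, "gradient_norm") <- res$gnorm
  out
}

#' Closed-form relative-risk estimate
#'
#' Given latent labels, the Poisson likelihood over risk-labelled genes is
#' maximized at `gamma_hat = sum(count) / sum(2 * n_trios * mutability)`,
#' both sums over genes labelled `+1`. The estimate is clipped below at 1
#' (the model defines `gamma = 1` for non-risk genes; risk genes carry excess
#' risk). When no gene is labelled `+1` the previous value is returned with a
#' `degenerate` flag.
#'
#' @param state Latent labels in `{-1, +1}`, aligned with `x`.
#' @param x A [gene_table].
#' @param n_trios Cohort size; defaults to the table's attribute.
#' @param gamma_prev Value to return when no gene is labelled `+1`.
#' @return List with `gamma` and logical `degenerate`.
#' @export
estimate_gamma <- function(state, x, n_trios = NULL, gamma_prev = 1) {
  if (is.null(n_trios)) n_trios <- n_trios(x)
  state <- as.integer(state)
  if (length(state) != nrow(x)) abort("`state` and `x` have different lengths.")
  risk <- state == 1L
  if (!any(risk)) {
    warn("No gene labelled +1; keeping the previous relative risk.")
    return(list(gamma = gamma_prev, degenerate = TRUE))
  }
  g <- sum(x$count[risk]) / sum(2 * n_trios * x$mutability[risk])
  list(gamma = max(g, 1), degenerate = FALSE)
}

#' One iterated-conditional-modes sweep of the latent labels
#'
#' Sequentially (in lexicographic gene order, with immediate updates) sets
#' each gene to the state maximizing the product of its Poisson emission, its
#' own full conditional, and the full conditionals of its neighbours
#' re-evaluated under the candidate state. Ties favour the null label `-1`.
#'
#' @inheritParams log_prior_unnorm
#' @param gamma Relative risk (`>= 1`).
#' @param x A [gene_table] aligned with the network.
#' @param n_trios Cohort size; defaults to the table's attribute.
#' @param n_sweeps Number of full sweeps (stops early if no label changes).
#' @return Updated named state vector.
#' @export
icm_update <- function(state, net, params, gamma, x, n_trios = NULL,
                       n_sweeps = 1L) {
  if (is.null(n_trios)) n_trios <- n_trios(x)
  state <- align_state(state, net)
  if (!identical(x$gene, net$nodes$gene)) {
    abort("Gene table and network are not aligned; use `restrict_to_genes()`.")
  }
  csr <- network_csr(net)
  led <- log_emission_diff(x$count, x$mutability, n_trios, gamma)
  res <- .icm_sweeps_cpp(csr$idx, csr$nbr, csr$w, params$h, params$tau0,
                         params$tau1, led, unname(state), as.integer(n_sweeps))
  setNames(res$state, csr$genes)
}

# log pseudo conditional likelihood at (params, gamma, state)
pclk <- function(state, net, params, gamma, x, n_trios) {
  p1 <- conditional_prob(state, net, params)
  em <- log_emission(x$count, x$mutability, n_trios, unname(state), gamma)
  sum(em) + sum(ifelse(state == 1L, log(p1), log1p(-p1)))
}

#' Fit the network-assisted DNV burden model
#'
#' Empirical-Bayes estimation of the MRF hyperparameters `(h, tau0, tau1)`,
#' the relative risk `gamma`, and the latent risk labels, by coordinate-wise
#' maximization of the pseudo conditional likelihood (PCLK): a penalized
#' logistic fit for the network parameters, an iterated-conditional-modes
#' sweep for the labels, and the closed-form `gamma` estimate, repeated until
#' the labels are stable and the parameters have converged.
#'
#' With `network = NULL` (or a network in zero-weight mode) every gene is
#' treated as isolated: the model collapses to a two-group Poisson mixture
#' whose mixing proportion is `plogis(h)`, and the edge affinities play no
#' role.
#'
#' @param x A [gene_table].
#' @param network A [gene_network][as_gene_network] or `NULL` for the
#'   no-network mode. The network is aligned to the table's genes with
#'   [restrict_to_genes()] (table genes missing from the network become
#'   isolated nodes).
#' @param n_trios Cohort size; defaults to the table's attribute.
#' @param no_network Force zero weights even when a network is supplied.
#' @param lambda Ridge penalty for the logistic step.
#' @param gamma_init Initial relative risk (default `exp(3)`, the low end of
#'   plausible log relative risks for damaging DNVs).
#' @param init Label initialization: `"pvalue"` starts from genes with
#'   Poisson upper-tail p below `init_pvalue`; `"seeds"` from `seed_genes`;
#'   `"random"` runs `n_starts` random initializations (each gene `+1` with
#'   probability `init_prob`) and keeps the best final PCLK.
#' @param init_pvalue,seed_genes,init_prob,n_starts Initialization controls.
#' @param tol Relative-change tolerance on `(h, tau0, tau1, gamma)`.
#' @param max_iter Maximum outer iterations.
#' @param nonneg Constrain `tau0, tau1 >= 0` in the logistic step.
#' @return An object of class `mrf_fit`: fitted `params`, `gamma`, named
#'   `state` vector, `iterations`, `converged`, the PCLK trace, and the
#'   aligned inputs. Use [tidy()] for per-gene labels and [glance()] for a
#'   one-row parameter summary.
#' @examples
#' set.seed(1)
#' sim <- simulate_dnv_study(sim_config(n_genes = 200, n_trios = 5000))
#' fit <- mrf_fit(sim$gene_table, sim$network)
#' glance(fit)
#' @export
mrf_fit <- function(x, network = NULL, n_trios = NULL,
                    no_network = FALSE, lambda = 0.1, gamma_init = exp(3),
                    init = c("pvalue", "seeds", "random"),
                    init_pvalue = 0.01, seed_genes = NULL, init_prob = 0.05,
                    n_starts = 5L, tol = 1e-4, max_iter = 100L,
                    nonneg = TRUE) {
  init <- match.arg(init)
  if (is.null(n_trios)) n_trios <- n_trios(x)
  x <- gene_table(as_tibble(x)[c("gene", "count", "mutability")], n_trios)
  if (is.null(network)) {
    network <- new_gene_network(x$gene, tibble(
      gene_a = character(0), gene_b = character(0), score = integer(0)
    ), "zero")
  } else {
    network <- restrict_to_genes(network, x$gene)
  }
  if (no_network) {
    network <- new_gene_network(network$nodes$gene, network$edges, "zero")
  }

  init_states <- switch(init,
    pvalue = {
      p <- poisson_tail_test(x, n_trios)$p_value
      list(setNames(ifelse(p < init_pvalue, 1L, -1L), x$gene))
    },
    seeds = {
      if (is.null(seed_genes)) abort("`init = \"seeds\"` needs `seed_genes`.")
      list(setNames(ifelse(x$gene %in% seed_genes, 1L, -1L), x$gene))
    },
    random = {
      lapply(seq_len(n_starts), function(i) {
        setNames(ifelse(runif(nrow(x)) < init_prob, 1L, -1L), x$gene)
      })
    }
  )

  run_one <- function(s0) {
    s <- align_state(s0, network)
    gamma <- gamma_init
    params <- NULL
    trace <- numeric(0)
    all_null_always <- TRUE
    converged <- FALSE
    it <- 0L
    for (it in seq_len(max_iter)) {
      params_new <- fit_theta0(s, network, lambda = lambda, nonneg = nonneg)
      s_new <- icm_update(s, network, params_new, gamma, x, n_trios)
      gam <- estimate_gamma(s_new, x, n_trios, gamma_prev = gamma)
      if (any(s_new == 1L)) all_null_always <- FALSE
      old <- c(
        if (is.null(params)) rep(NA_real_, 3) else
          c(params$h, params$tau0, params$tau1),
        gamma
      )
      new <- c(params_new$h, params_new$tau0, params_new$tau1, gam$gamma)
      rel <- abs(new - old) / pmax(abs(old), 1)
      trace <- c(trace, pclk(s_new, network, params_new, gam$gamma, x, n_trios))
      stable <- identical(unname(s_new), unname(s)) &&
        all(is.finite(rel)) && max(rel) < tol
      s <- s_new
      params <- params_new
      gamma <- gam$gamma
      if (stable) {
        converged <- TRUE
        break
      }
    }
    if (all_null_always) {
      warn(paste(
        "Weak signal: no gene was ever labelled a risk gene;",
        "estimates reflect the null-only fit."
      ))
    }
    list(params = params, gamma = gamma, state = s, iterations = it,
         converged = converged, pclk_trace = trace)
  }

  runs <- lapply(init_states, run_one)
  best <- runs[[which.max(vapply(
    runs, function(r) r$pclk_trace[length(r$pclk_trace)], numeric(1)
  ))]]

  structure(
    c(best, list(
      gene_table = x, network = network, n_trios = n_trios,
      settings = list(lambda = lambda, tol = tol, max_iter = max_iter,
                      init = init, gamma_init = gamma_init, nonneg = nonneg)
    )),
    class = "mrf_fit"
  )
}

#' @export
print.mrf_fit <- function(x, ...) {
  cat(sprintf(
    paste0("<mrf_fit> %d genes, %d edges\n",
           "  h = %.3f, tau0 = %.3f, tau1 = %.3f, gamma = %.2f ",
           "(log rr = %.2f)\n  %s after %d iteration(s); %d risk-labelled\n"),
    nrow(x$gene_table), nrow(x$network$edges),
    x$params$h, x$params$tau0, x$params$tau1, x$gamma, log(x$gamma),
    if (x$converged) "converged" else "NOT converged", x$iterations,
    sum(x$state == 1L)
  ))
  invisible(x)
}

#' @describeIn mrf_fit Per-gene tibble of counts and fitted labels.
#' @exportS3Method
tidy.mrf_fit <- function(x, ...) {
  dplyr::left_join(
    x$gene_table, x$network$nodes,
    by = "gene"
  ) |>
    dplyr::mutate(state = unname(x$state)) |>
    as_tibble()
}

#' @describeIn mrf_fit One-row summary of fitted parameters.
#' @exportS3Method
glance.mrf_fit <- function(x, ...) {
  tibble(
    h = x$params$h, tau0 = x$params$tau0, tau1 = x$params$tau1,
    gamma = x$gamma, log_gamma = log(x$gamma),
    n_genes = nrow(x$gene_table), n_risk_labelled = sum(x$state == 1L),
    iterations = x$iterations, converged = x$converged,
    pclk = x$pclk_trace[length(x$pclk_trace)]
  )
}

#' @describeIn mrf_fit PCLK trace across outer iterations.
#' @param object An `mrf_fit`.
#' @exportS3Method
autoplot.mrf_fit <- function(object, ...) {
  df <- tibble(iteration = seq_along(object$pclk_trace),
               pclk = object$pclk_trace)
  ggplot2::ggplot(df, ggplot2::aes(.data$iteration, .data$pclk)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Iteration", y = "log pseudo conditional likelihood")
}
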