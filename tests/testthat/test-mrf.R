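test_that("unnormalized log prior matches hand computation", {
  # every term vanishes: no +1 gene, tau0 = 0
  net <- as_gene_network(tibble::tibble(gene_a = "A", gene_b = "B"))
  s <- c(A = -1, B = -1)
  expect_equal(log_prior_unnorm(s, net, mrf_params(-1, 0, 0.5)), 0)
  # single edge, both +1, unit weights: h*2 + tau1*(1+1)
  expect_equal(
    log_prior_unnorm(c(A = 1, B = 1), net, mrf_params(-1, 0, 0.5)),
    -2 + 0.5 * 2
  )
  # random 3-node paths against independent term-by-term summation
  set.seed(31)
  path3 <- as_gene_network(tibble::tibble(
    gene_a = c("A", "B"), gene_b = c("B", "C")
  ))
  for (rep in 1:20) {
    s <- setNames(sample(c(-1L, 1L), 3, replace = TRUE), c("A", "B", "C"))
    par <- random_mrf_params()
    expect_equal(
      log_prior_unnorm(s, path3, par),
      log_joint_oracle(s, path3, par)
    )
  }
})

test_that("neighbour covariates match their definitions and identity", {
  star <- as_gene_network(tibble::tibble(
    gene_a = "C", gene_b = paste0("L", 1:4)
  ))
  s_all_plus <- setNames(rep(1L, 5), star$nodes$gene)
  cov <- compute_covariates(s_all_plus, star)
  expect_equal(cov$x1[cov$gene == "C"], 2 * 4 + 4 * 1)
  expect_equal(cov$x0[cov$gene == "C"], 0)
  s_leaves_minus <- setNames(ifelse(star$nodes$gene == "C", 1L, -1L),
                             star$nodes$gene)
  cov <- compute_covariates(s_leaves_minus, star)
  expect_equal(cov$x1[cov$gene == "C"], 0)
  expect_equal(cov$x0[cov$gene == "C"], 12)
  # x1 + x0 == w_i * d_i + sum of neighbour weights, on random graphs
  set.seed(32)
  for (rep in 1:10) {
    net <- random_network(7, p = 0.5)
    s <- setNames(sample(c(-1L, 1L), 7, replace = TRUE), net$nodes$gene)
    cov <- compute_covariates(s, net)
    adj <- lapply(net$nodes$gene, function(g) {
      c(net$edges$gene_b[net$edges$gene_a == g],
        net$edges$gene_a[net$edges$gene_b == g])
    })
    w <- setNames(net$nodes$weight, net$nodes$gene)
    expected <- vapply(seq_len(7), function(i) {
      w[i] * length(adj[[i]]) + sum(w[adj[[i]]])
    }, numeric(1))
    expect_equal(cov$x1 + cov$x0, unname(expected))
  }
})

test_that("full conditionals are logistic and consistent with the joint", {
  # isolated gene: marginal plogis(h)
  lone <- as_gene_network(tibble::tibble(
    gene_a = character(0), gene_b = character(0)
  ), genes = "A")
  p <- conditional_prob(c(A = -1), lone, mrf_params(-4, 0.3, 0.3))
  expect_equal(unname(p), exp(-4) / (1 + exp(-4)), tolerance = 1e-12)
  # no coupling: plogis(h) for every gene on any network
  set.seed(33)
  net <- random_network(6, p = 0.5)
  s <- setNames(sample(c(-1L, 1L), 6, replace = TRUE), net$nodes$gene)
  expect_equal(
    unname(conditional_prob(s, net, mrf_params(-2, 0, 0))),
    rep(plogis(-2), 6)
  )
  # agreement with enumeration of the joint measure on small graphs
  for (rep in 1:25) {
    n <- sample(2:4, 1)
    net <- random_network(n, p = 0.6)
    s <- setNames(sample(c(-1L, 1L), n, replace = TRUE), net$nodes$gene)
    par <- random_mrf_params()
    cond <- conditional_prob(s, net, par)
    for (i in seq_len(n)) {
      expect_equal(
        unname(cond[i]),
        exact_conditional_oracle(i, s, net, par),
        tolerance = 1e-10
      )
    }
  }
})

test_that("the pseudo-likelihood logistic fit recovers known solutions", {
  # intercept-only: h is exactly the empirical logit of the +1 fraction
  genes <- sprintf("g%02d", 1:40)
  nonet <- as_gene_network(tibble::tibble(
    gene_a = character(0), gene_b = character(0)
  ), genes = genes, weight_mode = "zero")
  s <- setNames(c(rep(1L, 10), rep(-1L, 30)), genes)
  fit <- fit_theta0(s, nonet, lambda = 0)
  expect_equal(fit$h, qlogis(0.25), tolerance = 1e-8)
  expect_equal(fit$tau0, 0)
  expect_equal(fit$tau1, 0)
  # one-class labels: ridge keeps the estimate finite and negative
  s_null <- setNames(rep(-1L, 40), genes)
  fit <- fit_theta0(s_null, nonet, lambda = 0.1)
  expect_true(is.finite(fit$h) && fit$h < 0)
  # separable data with lambda = 0 raises a typed error with diagnostics
  s_all <- setNames(rep(1L, 40), genes)
  err <- tryCatch(fit_theta0(s_all, nonet, lambda = 0),
                  error = function(e) e)
  expect_s3_class(err, "dnvnet_separation_error")
  expect_true(is.numeric(err$gradient_norm))
  expect_length(err$last_estimate, 3)
})

test_that("fit_theta0 matches an independent numerical optimizer", {
  set.seed(34)
  for (lambda in c(0, 0.01, 0.1, 1)) {
    net <- random_network(40, p = 0.12)
    repeat {
      s <- setNames(sample(c(-1L, 1L), 40, replace = TRUE, prob = c(0.6, 0.4)),
                    net$nodes$gene)
      fit <- tryCatch(fit_theta0(s, net, lambda = lambda),
                      error = function(e) NULL)
      if (!is.null(fit)) break
    }
    cov <- compute_covariates(s, net)
    y <- as.numeric(s == 1L)
    negobj <- function(th) {
      eta <- th[1] + th[3] * cov$x1 - th[2] * cov$x0
      -(sum(y * eta - log1p(exp(eta))) - lambda * sum(th^2))
    }
    neggrad <- function(th) {
      eta <- th[1] + th[3] * cov$x1 - th[2] * cov$x0
      r <- y - plogis(eta)
      -(c(sum(r), sum(-cov$x0 * r), sum(cov$x1 * r)) - 2 * lambda * th)
    }
    opt <- optim(c(0, 0, 0), negobj, neggrad, method = "L-BFGS-B",
                 lower = c(-Inf, 0, 0),
                 control = list(factr = 10, pgtol = 1e-12, maxit = 2000))
    expect_equal(c(fit$h, fit$tau0, fit$tau1), opt$par, tolerance = 1e-6)
  }
})

test_that("closed-form gamma estimate is the Poisson MLE, clipped at one", {
  tbl <- gene_table(
    tibble::tibble(
      gene = c("a", "b", "c"), count = c(2L, 1L, 0L),
      mutability = c(1e-6, 2e-6, 1e-6)
    ),
    n_trios = 1000
  )
  s <- c(1L, 1L, 1L)
  est <- estimate_gamma(s, tbl)
  expect_equal(est$gamma, 3 / (2 * 1000 * 4e-6))
  expect_false(est$degenerate)
  # all-zero counts among risk genes clip to 1
  tbl0 <- gene_table(
    tibble::tibble(gene = c("a", "b"), count = c(0L, 0L),
                   mutability = c(1e-6, 1e-6)),
    n_trios = 1000
  )
  expect_equal(estimate_gamma(c(1L, 1L), tbl0)$gamma, 1)
  # no risk-labelled gene: previous value kept, flagged, with a warning
  expect_warning(
    est <- estimate_gamma(c(-1L, -1L), tbl0, gamma_prev = 7),
    "previous"
  )
  expect_equal(est$gamma, 7)
  expect_true(est$degenerate)
  # closed form equals the 1-D numerical maximizer of the risk-gene likelihood
  set.seed(35)
  for (rep in 1:10) {
    n <- 30
    tblr <- gene_table(
      tibble::tibble(
        gene = sprintf("g%02d", 1:n),
        count = rpois(n, 2),
        mutability = 10^runif(n, -6.5, -5)
      ),
      n_trios = 5000
    )
    s <- sample(c(-1L, 1L), n, replace = TRUE)
    if (!any(s == 1L)) s[1] <- 1L
    risk <- s == 1L
    score <- function(g) {
      sum(tblr$count[risk]) / g - sum(2 * 5000 * tblr$mutability[risk])
    }
    root <- if (score(1) <= 0) 1 else {
      uniroot(score, c(1, 1e6), tol = 1e-12)$root
    }
    est <- estimate_gamma(s, tblr)
    expect_equal(est$gamma, root, tolerance = 1e-8)
  }
})

test_that("ICM updates follow the local objective", {
  # gamma = 1 and no coupling with h < 0: everything goes null
  set.seed(36)
  net <- random_network(6, p = 0.5)
  tbl <- random_gene_table_for(net)
  s <- setNames(rep(1L, 6), net$nodes$gene)
  s_new <- icm_update(s, net, mrf_params(-1, 0, 0), gamma = 1, x = tbl)
  expect_true(all(s_new == -1L))
  # isolated gene: flips to +1 exactly when the emission ratio beats the
  # prior odds; the boundary is (rate0*(gamma-1) - h) / log(gamma)
  lone <- as_gene_network(tibble::tibble(
    gene_a = character(0), gene_b = character(0)
  ), genes = "A")
  gamma <- exp(3)
  mu <- 1e-6
  n_tr <- 2000
  boundary <- (2 * n_tr * mu * (gamma - 1) + 4) / 3 # h = -4
  y_below <- floor(boundary)
  y_above <- ceiling(boundary)
  for (y in c(y_below, y_above)) {
    tbl1 <- gene_table(
      tibble::tibble(gene = "A", count = y, mutability = mu), n_tr
    )
    s1 <- icm_update(c(A = -1L), lone, mrf_params(-4, 0, 0), gamma, tbl1)
    expect_equal(unname(s1), if (y > boundary) 1L else -1L)
  }
})

test_that("an ICM sweep matches a step-by-step brute-force oracle", {
  set.seed(37)
  path3 <- as_gene_network(tibble::tibble(
    gene_a = c("A", "B"), gene_b = c("B", "C")
  ))
  for (rep in 1:15) {
    tbl <- random_gene_table_for(path3)
    par <- random_mrf_params()
    gamma <- exp(runif(1, 1, 4))
    s0 <- setNames(sample(c(-1L, 1L), 3, replace = TRUE), path3$nodes$gene)

    # oracle: sequential argmax of emission * own conditional * neighbour
    # conditionals, evaluated from scratch at every step
    s_or <- s0
    genes <- path3$nodes$gene
    for (i in seq_along(genes)) {
      score <- function(si) {
        s_try <- s_or
        s_try[i] <- si
        cond <- conditional_prob(s_try, path3, par)
        nbrs <- which(vapply(seq_along(genes), function(k) {
          any(path3$edges$gene_a == genes[i] & path3$edges$gene_b == genes[k]) ||
            any(path3$edges$gene_b == genes[i] & path3$edges$gene_a == genes[k])
        }, logical(1)))
        own <- if (si == 1L) cond[i] else 1 - cond[i]
        nbr_terms <- vapply(nbrs, function(k) {
          if (s_try[k] == 1L) cond[k] else 1 - cond[k]
        }, numeric(1))
        log_emission(tbl$count[i], tbl$mutability[i], n_trios(tbl), si, gamma) +
          log(own) + sum(log(nbr_terms))
      }
      s_or[i] <- if (score(1L) > score(-1L)) 1L else -1L
    }
    s_cpp <- icm_update(s0, path3, par, gamma, tbl)
    expect_identical(unname(s_cpp), unname(s_or))
  }
})

test_that("no-network fits ignore edge structure entirely", {
  set.seed(38)
  netA <- random_network(60, p = 0.1)
  netB <- random_network(60, p = 0.3)
  netB$nodes$gene <- netA$nodes$gene # same gene universe, different edges
  tbl <- random_gene_table_for(netA, n_trios = 4000L)
  fitA <- mrf_fit(tbl, netA, no_network = TRUE)
  fitB <- suppressWarnings(mrf_fit(tbl, netB, no_network = TRUE))
  expect_equal(glance(fitA)[c("h", "tau0", "tau1", "gamma")],
               glance(fitB)[c("h", "tau0", "tau1", "gamma")])
  expect_identical(fitA$state, fitB$state)
  # edge affinities are irrelevant when all weights are zero
  expect_equal(fitA$params$tau0, 0)
  expect_equal(fitA$params$tau1, 0)
})

test_that("the PCLK trace is non-decreasing up to tolerance-level wiggle", {
  set.seed(39)
  sim <- simulate_dnv_study(
    sim_config(n_genes = 400, n_trios = 5000, tau1 = 0.5, beta = 3.5)
  )
  fit <- mrf_fit(sim$gene_table, sim$network)
  expect_true(fit$converged)
  tr <- fit$pclk_trace
  expect_gt(length(tr), 0)
  if (length(tr) > 1) {
    expect_true(all(diff(tr) > -1e-3 * abs(tr[-length(tr)])))
  }
})
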