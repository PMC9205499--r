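#' Per-gene DNV count tables
#'
#' A DNV gene table holds, for each gene, the observed count of damaging de
#' novo variants in a trio cohort (`count`) and the gene's mutability
#' (`mutability`): the expected de novo mutation rate for the damaging variant
#' class, per haploid genome per generation. The cohort size `n_trios` (number
#' of sequenced parent-offspring trios) is stored once as an attribute: under
#' the burden model the expected null count for gene *i* is
#' `2 * n_trios * mutability_i`.
#'
#' @param x A data frame with columns `gene`, `count`, `mutability`.
#' @param n_trios Cohort size (number of trios), a positive integer.
#' @return A tibble of class `dnv_gene_table` sorted by gene, with the
#'   `n_trios` attribute set.
#' @examples
#' gene_table(
#'   data.frame(gene = c("g1", "g2"), count = c(0L, 3L),
#'              mutability = c(1e-06, 2e-06)),
#'   n_trios = 1000
#' )
#' @export
gene_table <- function(x, n_trios) {
  x <- as_tibble(x)
  need <- c("gene", "count", "mutability")
  if (!all(need %in% names(x))) {
    abort(sprintf(
      "Gene table needs columns %s.", paste0("`", need, "`", collapse = ", ")
    ))
  }
  x$gene <- as.character(x$gene)
  if (anyDuplicated(x$gene)) {
    abort(sprintf(
      "Duplicate gene identifier: '%s'.", x$gene[duplicated(x$gene)][1]
    ))
  }
  if (!is.numeric(x$count) || any(x$count < 0) || any(x$count != round(x$count))) {
    abort("`count` must be nonnegative integers.")
  }
  if (!is.numeric(x$mutability) || any(!is.finite(x$mutability)) ||
      any(x$mutability <= 0)) {
    abort("`mutability` must be positive and finite.")
  }
  n_trios <- as.integer(n_trios)
  if (length(n_trios) != 1 || is.na(n_trios) || n_trios < 1) {
    abort("`n_trios` must be a single positive integer.")
  }
  x$count <- as.integer(x$count)
  x <- dplyr::arrange(x, .data$gene)
  attr(x, "n_trios") <- n_trios
  class(x) <- c("dnv_gene_table", class(x))
  x
}

#' @rdname gene_table
#' @export
n_trios <- function(x) {
  n <- attr(x, "n_trios")
  if (is.null(n)) abort("`x` carries no `n_trios` attribute; pass `n_trios` explicitly.")
  n
}

#' Read a per-gene DNV count table
#'
#' Expects a TSV with header columns `gene`, `count`, `mutability`. The cohort
#' size is supplied separately since it is a property of the study, not of any
#' gene.
#'
#' @param path Path to a TSV file.
#' @inheritParams gene_table
#' @return A [gene_table] tibble.
#' @export
read_gene_table <- function(path, n_trios) {
  lines <- read_text_lines(path)
  if (length(lines) == 0) abort("Empty gene table file.")
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  need <- c("gene", "count", "mutability")
  if (!all(need %in% header)) {
    abort(sprintf(
      "Gene table header must contain %s; got: %s",
      paste(need, collapse = ", "), lines[[1]]
    ))
  }
  body <- lines[-1]
  keep <- nzchar(trimws(body))
  body <- body[keep]
  line_no <- (seq_along(lines))[-1][keep]
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != length(header))
  if (length(bad) > 0) {
    abort(sprintf(
      "Line %d has %d fields; expected %d.",
      line_no[bad[1]], lengths(parts)[bad[1]], length(header)
    ))
  }
  get_col <- function(name) {
    j <- match(name, header)
    vapply(parts, `[[`, character(1), j)
  }
  cnt <- suppressWarnings(as.numeric(get_col("count")))
  mut <- suppressWarnings(as.numeric(get_col("mutability")))
  bad <- which(is.na(cnt) | cnt < 0 | cnt != round(cnt))
  if (length(bad) > 0) {
    abort(sprintf("Line %d: invalid DNV count '%s'.", line_no[bad[1]],
                  get_col("count")[bad[1]]))
  }
  bad <- which(is.na(mut) | mut <= 0)
  if (length(bad) > 0) {
    abort(sprintf("Line %d: invalid mutability '%s' (must be > 0).",
                  line_no[bad[1]], get_col("mutability")[bad[1]]))
  }
  gene_table(
    tibble(gene = get_col("gene"), count = as.integer(cnt), mutability = mut),
    n_trios = n_trios
  )
}

#' Poisson emission log-likelihood of a DNV count
#'
#' Under the burden model a gene's DNV count is Poisson with rate
#' `2 * n_trios * mutability` for a non-risk gene (`state = -1`) and
#' `2 * n_trios * mutability * gamma` for a risk gene (`state = +1`), where
#' `gamma >= 1` is the relative risk of damaging DNVs in risk genes.
#'
#' @param count Observed DNV count(s).
#' @param mutability Per-gene mutability.
#' @param n_trios Cohort size.
#' @param state Latent risk state, `+1` (risk) or `-1` (non-risk); recycled.
#' @param gamma Relative risk, `>= 1`.
#' @return Log Poisson probability mass, vectorized over genes.
#' @export
log_emission <- function(count, mutability, n_trios, state, gamma) {
  if (any(gamma < 1)) abort("`gamma` must be >= 1.")
  if (!all(state %in% c(-1, 1))) abort("`state` entries must be -1 or +1.")
  # gamma^I(state = +1), with standard recycling across all four arguments
  rate <- 2 * n_trios * mutability * gamma^((state + 1) / 2)
  dpois(count, rate, log = TRUE)
}

# log f(Y|+1) - log f(Y|-1) per gene; the only emission summary the samplers need
log_emission_diff <- function(count, mutability, n_trios, gamma) {
  rate0 <- 2 * n_trios * mutability
  count * log(gamma) - rate0 * (gamma - 1)
}

#' Per-gene Poisson upper-tail burden test
#'
#' A network-free baseline: for each gene, the one-sided probability of
#' observing at least the recorded DNV count under the null rate
#' `2 * n_trios * mutability`, with Benjamini-Hochberg adjustment across
#' genes. A count of zero gives p = 1.
#'
#' @param x A [gene_table] (or data frame with `gene`, `count`, `mutability`).
#' @param n_trios Cohort size; defaults to the table's attribute.
#' @return A tibble with `gene`, `count`, `expected`, `p_value`, `p_adjusted`.
#' @export
poisson_tail_test <- function(x, n_trios = NULL) {
  if (is.null(n_trios)) n_trios <- n_trios(x)
  rate <- 2 * n_trios * x$mutability
  p <- ppois(x$count - 1, rate, lower.tail = FALSE)
  tibble(
    gene = x$gene,
    count = x$count,
    expected = rate,
    p_value = p,
    p_adjusted = p.adjust(p, method = "BH")
  )
}
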