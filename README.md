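# dnvnet

Network-assisted identification of disease risk genes from *de novo*
variant (DNV) counts in trio sequencing cohorts.

## What it does, and for whom

Family-based sequencing studies of early-onset disorders count damaging
de novo variants per gene. Under the standard mutational null, the count
for gene *i* across *N* trios is Poisson with mean 2·*N*·μᵢ, where μᵢ is
the gene's mutability for the damaging variant class; risk genes inflate
this rate by a relative risk γ > 1. Because expected null counts are tiny
and risk genes rare, per-gene burden tests are underpowered at realistic
cohort sizes.

`dnvnet` is for statistical geneticists analysing such cohorts who also
have a protein–protein interaction (PPI) network, e.g. a STRING-style
scored edge list. It couples the latent per-gene risk states
Sᵢ ∈ {−1, +1} through a discrete Markov random field prior on the network,

> P(S | h, τ₀, τ₁) ∝ exp{ h Σᵢ I₊(Sᵢ) + τ₀ Σ₍ᵢⱼ₎ (wᵢ+wⱼ) I₋(Sᵢ)I₋(Sⱼ)
> + τ₁ Σ₍ᵢⱼ₎ (wᵢ+wⱼ) I₊(Sᵢ)I₊(Sⱼ) },  wᵢ = √degreeᵢ,

with Poisson emissions Yᵢ | Sᵢ = −1 ~ Pois(2Nμᵢ) and
Yᵢ | Sᵢ = +1 ~ Pois(2Nμᵢγ). Hyperparameters are estimated empirically by
maximizing the pseudo conditional likelihood (penalized logistic
regression for (h, τ₀, τ₁) + iterated conditional modes for S + a closed
form for γ); per-gene posterior probabilities of non-association
qᵢ = P(Sᵢ = −1 | Y) — local false discovery rates — come from a Gibbs
sampler, and genes are called by the cumulative local-fdr rule that
controls the global FDR. The package also ships the full simulation
framework for power/FDR studies under this generative model and an
edge-count permutation test for checking that candidate genes are more
interconnected than chance before trusting the network to help.

## Worked example

Simulate a synthetic study at reference conditions (1000 genes, 5000
trios, h = −4, τ₁ = 0.5, log relative risk β = 3.5), run the pipeline,
and check the network preflight:

```r
library(dnvnet)
library(dplyr)
set.seed(2026)

sim <- simulate_dnv_study(sim_config(n_genes = 1000, n_trios = 5000))
sim
#> <dnv_sim> 1000 genes, 999 edges, 105 true risk genes, 245 DNVs total

res <- ndata(sim$gene_table, sim$network, alpha = 0.05,
             n_iter = 2000, n_burnin = 1000)
res
#> <ndata_result> 1000 genes; FDR level 0.05
#>   49 rejected; 45 reported (count >= 1)
#>   gamma = 35.38 (log rr = 3.57), h = -4.745, tau1 = 0.589

tidy(res) |> filter(reported) |> arrange(q) |> head(5)
#> # A tibble: 5 × 7
#>   gene  count mutability degree     q rejected reported
#>   <chr> <int>      <dbl>  <int> <dbl> <lgl>    <lgl>
#> 1 g0003     3 0.00000997     24     0 TRUE     TRUE
#> 2 g0007     1 0.00000134     12     0 TRUE     TRUE
#> 3 g0008    22 0.0000523      27     0 TRUE     TRUE
#> 4 g0025     7 0.0000183       3     0 TRUE     TRUE
#> 5 g0030     4 0.00000417      3     0 TRUE     TRUE
```

The fit recovers the generative parameters (true h = −4, τ₁ = 0.5,
log γ = 3.5): here 49 genes are rejected at global FDR 0.05, of which 45
carry at least one DNV and are reported; against the known truth this run
has power 0.47 with a realized false discovery proportion of 0. The
interpretation of each column: `q` is the posterior probability that the
gene is *not* a risk gene (local fdr), `rejected` marks the global-FDR
call, and `reported` additionally requires an observed DNV.

Is the network informative? Count edges among the top genes against
random same-size gene sets:

```r
top <- tidy(res) |> arrange(q) |> pull(gene) |> head(30)
edge_enrichment_test(top, sim$network, n_perm = 10000)
#> <edge_enrichment> k = 30 genes: 24 edges observed
#>   null 95th percentile 3.0; p = 9.999e-05 (10000 permutations)
```

Real data enter the same way: `read_gene_table()` (TSV with columns
`gene`, `count`, `mutability`, plus the cohort size), `read_edge_list()`
(TSV `gene_a`, `gene_b`, `score` 0–1000, e.g. STRING at threshold 400),
and `build_seed_subnetwork()` to focus a large database on seed genes and
their high-confidence neighbours. `ndata(..., no_network = TRUE)` runs
the same model with all weights zero for a network-free baseline, and
`inst/cli/dnvnet.R` exposes `fit`, `simulate`, `enrich`, `build-network`
and `make-fixtures` subcommands for shell use.

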