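# mmirtree

Respondents answering 5-point rating items do not all use the scale the
same way: some favour the extreme categories (extreme response style,
ERS), some the middle category (midpoint response style, MRS), some both,
some neither. Treating everyone as if they shared one response process
biases trait estimates and item parameters. `mmirtree` implements a
**mixture multidimensional IRTree (MM-IRTree)** model for psychometricians
working with self-report rating data: each response is decomposed into
three sequential binary decisions — disagreement, neutrality, extremity —
and four latent classes of respondents differ in which response-style
traits enter those decisions alongside the substantive trait.

Each decision node follows a 2PL logistic model. With substantive trait
θ, style traits η_ers and η_mrs, loadings α, node difficulties β and a
proportionality constant ω for the substantive trait at the extremity
node:

    P(disagree)            = logit⁻¹(−α_θ θ − α_mrs η_mrs − β₀)
    P(neutral | ¬disagree) = logit⁻¹(−α_θ θ + α_mrs η_mrs − β₁)
    P(extreme | branch ±)  = logit⁻¹(± ω α_θ θ + α_ers η_ers − β₂)

The four classes — "ERS only", "MRS only", "2RS" (both), "0RS" (neither)
— share α_θ and ω but have class-specific style loadings (structurally
zero where a style is unused) and node difficulties; class membership is
a latent categorical variable with Dirichlet-distributed proportions.
Estimation is Bayesian: a Gibbs sampler with Pólya-Gamma augmentation of
every logistic node (written in C++), DIC for model comparison against
the four single-class benchmark IRTrees, modal assignment from posterior
class probabilities, and a simulation harness that reproduces the
generating design of the accompanying parameter-recovery study.

## Worked example

```r
library(mmirtree)

# simulate one equal-proportions dataset: 500 persons, 20 items
cond <- sim_condition("equal", n_persons = 500, n_items = 20,
                      n_replications = 1, master_seed = 42)
d <- generate_condition(cond)[[1]]

# fit the four-class mixture model (two chains at desk scale)
fit <- fit_irtree(d$ratings, "mm", chains = 2, iterations = 1500,
                  burnin = 500, seed = 101)
fit
#> <irtree_fit> model=mm  persons=500 items=20  chains=2 x 1500 (burn-in 500)
#>   DIC 24280.8 (Dbar 22667.8, pV 1613.0)  max Rhat 1.123  ...
#>   class proportions: ers=0.242 mrs=0.258 2rs=0.249 0rs=0.251

# how well are respondents classified?
hit_rate(modal_assignment(fit), d$z)
#> # A tibble: 4 x 4
#>   class label    n_true hit_rate
#>   <int> <chr>     <int>    <dbl>
#> 1     1 ERS only    125    0.928
#> 2     2 MRS only    125    0.992
#> 3     3 2RS         125    0.976
#> 4     4 0RS         125    0.984
```

The estimated class proportions sit at the generating value of 0.25 each,
and 93–99% of respondents in every class are assigned back to their
generating class by modal assignment — at one quarter of the full study's
sample size. `tidy(fit)` returns posterior means, SDs and Rhat per
parameter; `glance(fit)` a one-row overview; `select_model()` compares
fits by DIC; `autoplot(fit)` shows the posterior class probabilities.

A thin command-line interface wrapping the same functions (simulate /
fit / evaluate / run-study / make-fixture) ships in
`inst/cli/mmirtree.R`.

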