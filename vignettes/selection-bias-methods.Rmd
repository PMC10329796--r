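---
title: "Interval methods for detecting taxonomic selection bias"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interval methods for detecting taxonomic selection bias}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(florabias)
```

## The question

Ethnobotanical theory holds that local populations do not pick useful plants
uniformly at random from the surrounding flora: some botanical families are
*overused* (more of their species enter use than chance predicts) and others
*underused*. florabias operationalizes this test at the family level. The
data are a count table: for family $j$, $n_j$ native species of which $x_j$
have a recorded use; the flora-wide totals are $N = \sum_j n_j$ and
$X = \sum_j x_j$. The question is whether the family-level use proportion
$\theta_j$ differs from the flora-wide proportion $\theta$ by more than
sampling uncertainty can explain.

## The two interval constructions

Both methods summarize uncertainty about a proportion with a two-sided
interval built from beta quantiles, i.e. from the inverse regularized
incomplete beta function (`beta_quantile()`, backed by `stats::qbeta`).
Write $B^{-1}(p; a, b)$ for the $p$-quantile of a Beta$(a, b)$ distribution
and $\alpha = (1 - \text{level})/2$.

**Exceedance pair ("Bayesian" model).** The bounds come from the pair of
beta distributions whose tail probabilities bracket the observed count:

$$L_j = B^{-1}(\alpha;\; x_j,\; n_j - x_j + 1), \qquad
  U_j = B^{-1}(1-\alpha;\; x_j + 1,\; n_j - x_j).$$

This pair is algebraically identical to the exact Clopper–Pearson binomial
interval: inverting the binomial tail with the beta-binomial duality gives
exactly these two quantiles. It is exact-conservative — its frequentist
coverage is at least the nominal level for every $(n, \theta)$ — a fact the
test suite checks by simulation. A literal single-posterior variant
(both bounds from Beta$(x+1, n-x+1)$ under a flat prior) is available via
`bayes_interval(..., scheme = "posterior")` for comparison; it is *not* the
construction that reproduces the reference table.

**Imprecise Dirichlet Model (IDM).** The IDM replaces the single prior by a
set of Dirichlet priors with total prior weight $s$, which after observation
yields the envelope

$$L_j = B^{-1}(\alpha;\; x_j,\; n_j - x_j + s), \qquad
  U_j = B^{-1}(1-\alpha;\; x_j + s,\; n_j - x_j).$$

At $s = 1$ the envelope coincides with the exceedance pair; larger $s$
yields strictly nested, wider intervals (`idm_interval()` is tested for
this nesting). The package default is $s = 4$, the value consistent with
imprecision applied to both the used-species count and the total count, and
the value that reproduces the bundled reference bounds digit-for-digit.

**Boundary counts.** $x = 0$ fixes the lower bound at exactly 0 and $x = n$
fixes the upper bound at exactly 1; `beta_quantile()` treats zero shape
parameters as point masses so these come out as exact constants rather than
numerical near-zeros.

## Classification rule

The flora-wide interval for $\theta$ is computed from $(X, N)$, and each
family is compared against it (`classify_family()`):

* **overused** iff $L_j > U_\theta$ (strict),
* **underused** iff $U_j < L_\theta$ (strict),
* **ns** otherwise, including exact ties.

Strict inequalities make "ns" the conservative default. Comparisons use
full-precision computed bounds, not the 7-decimal printed values; for the
bundled reference data no family's call depends on that choice (the closest
case, Solanaceae, misses the global upper bound by about $3.5\times10^{-5}$
and is ns either way under the default convention).

No multiplicity correction is applied across families; the procedure's
family-wise error behaviour is characterized empirically instead (below).

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `level` | 0.95 | two-sided credibility/confidence level; quantiles at 0.025 and 0.975 |
| `idm_s` | 4 | IDM imprecision (prior weight); larger is more conservative |
| `global_convention` | `"shared"` | how the flora-wide interval is built |
| `bayes_scheme` | `"exceedance"` | exceedance pair vs single flat-prior posterior |

Two of these deserve comment because the reference analysis left them
implicit; both were fixed by requiring that recomputation reproduce the
published 7-decimal table, and both are configurable:

* **level = 0.95.** The printed upper bound for a family with $n = 1$,
  $x = 0$ is exactly 0.9750000 $= 1 - \alpha$, which pins the level at 95%
  two-sided.
* **idm_s = 4.** The printed IDM bounds match the $s = 4$ envelope exactly
  (e.g. the $n=1, x=0$ IDM upper bound 0.9936905 $= 0.975^{1/4}$).

**The shared global convention.** The reference table prints *identical*
total-row bounds for both model columns, and those bounds equal the IDM
($s=4$) computation on $(X, N)$. The default `global_convention = "shared"`
reproduces this: both model columns are classified against that one
interval. Whether the published convention was a deliberate choice or a
spreadsheet economy cannot be known from the table itself, so the
principled alternative (`"per_model"`, each model compared against its own
global interval) is provided. The choice matters exactly where a family
hugs the global bound: under `per_model` the narrower Bayesian global
interval flips Solanaceae to overused, and the report header notes the
convention in use.

**Equal-tailed, not HPD.** "Most probable values" language around such
analyses can suggest highest-posterior-density intervals, but the published
bounds are equal-tailed beta quantiles, and that is what the package
implements. For the very skewed small-$n$ posteriors involved, HPD and
equal-tailed intervals differ materially; only the equal-tailed form
reproduces the reference values.

## Numerical choices

* Quantiles come from `stats::qbeta`; the test suite cross-checks 100
  random quantiles against an independent bisection-plus-numerical-
  integration oracle at $10^{-8}$.
* Reproduction tests use an absolute tolerance of $10^{-5}$ against the
  printed 7-decimal values. The reference table was produced with a
  spreadsheet inverse-beta iteration whose results deviate from exact
  quantiles by up to a few $10^{-7}$ (e.g. printed 0.0125791 vs exact
  0.0125786 for $x=1, n=2$), so demanding agreement at printed precision
  would fail on the source's own rounding, while $10^{-5}$ is far below any
  classification-relevant difference.
* Serialized bounds are formatted at 7 decimals with round-half-up,
  matching the reference layout.

## The synthetic-flora generator

Because the underlying literature compilation cannot be re-collected, the
package characterizes the procedure on floras it generates itself
(`simulate_flora()`). The generator states a world and stays there:

* **Family sizes** follow a discrete power law $P(n) \propto n^{-1.5}$
  truncated to $[1, 3000]$, mimicking the heavy tail of real floras — a
  few families with thousands of species, many monotypic ones. A lognormal
  alternative is available.
* **Baseline use proportion** `theta_base = 0.008`, the order of magnitude
  observed for wild food use at national-flora scale.
* **Bias structure**: each family is independently over-selected with
  probability `frac_over = 0.05`, under-selected with `frac_under = 0.05`;
  its true $\theta_j$ is `theta_base` times `effect_over = 10` (or
  `effect_under = 0`, i.e. complete avoidance). These four defaults are not
  estimated from any dataset; they are a stated, plausible alternative
  hypothesis — a minority of families with an order-of-magnitude use
  enrichment, and avoidance as the underuse mechanism.
* **Counts** are binomial, $x_j \sim \mathrm{Bin}(n_j, \theta_j)$: use
  discovery is modelled as independent per-species reporting, the same
  sampling model the interval constructions assume. No hypergeometric
  finite-pool correction and no phylogenetic correlation between families
  is modelled.
* **Reproducibility**: each family draws from its own substream derived
  from the master seed, so enlarging a flora leaves existing families'
  draws untouched.

What a green simulation test establishes is therefore limited: the pipeline
detects order-of-magnitude enrichment in well-sampled families
(sensitivity $\ge 0.9$ at $\theta_j = 0.12$, $n_j \ge 300$), stays quiet on
null floras (flag rate well under 5% per tail), and its intervals cover the
truth at or above nominal level under binomial sampling. It does not
establish robustness to reporting-effort heterogeneity across biomes,
taxonomic misassignment, or correlated use among related families — none of
which the generator emulates.

## Known limitations

* The denominators $n_j$ are treated as known constants from a flora
  checklist; checklist errors propagate directly (the bundled reference
  data themselves contain a few implausible rows, reproduced verbatim).
* Families with tiny $n_j$ can be flagged overused on one or two used
  species (the $n=2, x=2$ pattern), which is statistically valid under the
  model but fragile to a single misrecorded species.
* The shared-global default couples the two model columns; users wanting
  fully model-consistent inference should set
  `global_convention = "per_model"` and expect near-boundary calls to move.
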