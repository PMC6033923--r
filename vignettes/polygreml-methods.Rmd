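---
title: "Models and methods in polygreml"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in polygreml}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polygreml)
```

## The scientific question

polygreml implements the analytic machinery for asking whether a
case-control disease trait (the motivating case is schizophrenia, SCZ)
shares genetic architecture with a quantitative reproductive trait —
a woman's age at first birth (AFB) — measured in a completely independent
cohort. Offspring of both young and old mothers carry elevated psychotic
disorder risk (a U-shaped epidemiological curve), and one candidate
mechanism is pleiotropy: alleles that raise disease liability also shift
the mother's age at first birth. Because the two cohorts share no samples,
the only bridge between the traits is genome-wide SNP data, and every
estimator in the package works through that bridge: polygenic scores
carried across cohorts, variance components tied together by a genomic
relationship matrix, and LD score regression on summary statistics.

## The mixed model

The core estimator is multi-trait genomic REML. For trait $t$ observed on
sample set $S_t$,

$$\mathbf{y}_t = \mathbf{X}_t \mathbf{b}_t + \mathbf{g}_t + \mathbf{e}_t,
\qquad \operatorname{Cov}(g_{ti}, g_{t'j}) = G_{ij}\,\sigma_{g(t,t')},
\qquad \mathbf{e}_t \sim N(0, \mathbf{I}\sigma^2_{e_t}),$$

where $G$ is the genomic relationship matrix (GRM) over the union of all
samples,

$$G_{jk} = \frac{1}{m_{jk}} \sum_i
\frac{(x_{ij} - 2p_i)(x_{ik} - 2p_i)}{2p_i(1-p_i)},$$

with $x_{ij}$ the count of the A1 allele and $m_{jk}$ the pairwise-complete
variant count. The disease trait is analysed on the observed 0/1 scale (the
transformation to the liability scale is a separate, explicit step,
`observed_to_liability_h2()`). Because the cohorts are disjoint by design —
relatedness pruning enforces it — residual covariances between traits are
structurally zero and are not parameters: only the per-trait genetic and
residual variances and the pairwise genetic covariances are estimated. This
is the identifiability assumption that makes the three-trait model (disease,
younger-AFB stratum, older-AFB stratum) well posed.

Genetic correlations are
$r_g = \sigma_{g(t,t')} / \sqrt{\sigma^2_{g(t)} \sigma^2_{g(t')}}$ with
delta-method standard errors from the full average-information (AI)
sampling covariance, including the covariance between the variance
estimates. Hypothesis tests are Wald tests; the heterogeneity test compares
$r_g$ against 1.

### The REML algorithm and its numerical choices

`fit_greml()` maximises the restricted likelihood by AI updates after three
EM warm-up iterations, with these safeguards, each of which exists because
the motivating design puts one variance (the older-stratum heritability,
about 0.03) close to zero:

* **Boundary handling.** Variances are floored at $10^{-6}$ of the
  phenotypic variance and flagged. A genetic covariance whose parent
  variance sits at the floor is pinned to zero — at the boundary it is not
  estimable, and letting it creep with the free parameters stalls
  convergence.
* **Active-set AI steps.** Components held at the boundary with the score
  still pointing outward are removed from the AI solve; keeping them in the
  system damps the steps of the free parameters.
* **Step halving** on any proposal that makes the covariance matrix
  indefinite or drops the restricted likelihood.
* **Loose covariance cap.** Genetic covariances are capped at
  $1.5\sqrt{\sigma^2_{g(t)}\sigma^2_{g(t')}}$ rather than at the
  correlation-one boundary, so the raw $r_g$ estimate may exceed $|1|$ as
  in unconstrained REML tools. This matters for the $r_g = 1$ Wald test: a
  hard cap just below 1 would push every estimate to one side of the null
  and bias the test's size. Reported correlations are projected onto
  $[-1, 1]$; the raw value is kept alongside.
* **Convergence** is declared when the maximum relative parameter change
  falls below `tol` ($10^{-6}$ by default), or when the restricted
  likelihood is flat to `tol` with parameter movement below
  $\sqrt{\texttt{tol}}$ — the secondary rule exists for fits with a
  boundary-pinned component, whose strict relative changes never settle.

The AI optimum was verified against an exhaustive eigen-rotated grid search
of the restricted likelihood (agreement to $10^{-4}$ in log-likelihood on
small fits; the grid oracle is part of the test suite).

### GBLUP polygenic scores

`predict()` on a single-trait fit returns
$\hat u_\tau = \hat\sigma^2_g G_{\tau o} V_o^{-1}(y - X\hat b)$ for any
target samples in the GRM — in the motivating design, disease genetic-value
predictions for the quantitative-trait cohort, obtained purely through
cross-cohort relationships. The implementation is checked against a dense
solve of Henderson's mixed-model equations to $10^{-8}$. The alternative
profile score (`profile_score()`) weights allele counts by per-SNP
association estimates; no p-value thresholding or LD clumping is applied,
matching whole-genome profile scoring. The two routes agree strongly on
simulated data but are not the same estimator: under linkage
disequilibrium the profile score targets marginal effects and GBLUP joint
effects, so their mutual correlation does not converge to 1 as the
training cohort grows, even as each becomes more accurate against the true
genetic values. The test suite asserts exactly that pattern.

## The U-shape response regression

The epidemiological U-shape enters as a fixed quadratic transform
$z = 2.7214 - 0.1105X + 0.0018X^2$ of age at first birth $X$, a published
registry-derived polynomial treated as a constant (its vertex sits at
$X \approx 30.7$ years). `regress_response_on_prs()` regresses $z$ on a
polygenic score plus covariates and reports the **incremental**
$R^2$ of the PRS term ($R^2_{\text{full}} - R^2_{\text{covariates}}$) —
with dozens of covariates the full-model $R^2$ says little about the PRS,
and the tiny published effect sizes (order $10^{-4}$–$10^{-3}$) only make
sense as increments. The full-model value is returned alongside. The AFB
cut-point for stratified analyses defaults to the fixed integer 26 rather
than the recomputed sample mean: reproducibility over self-reference; a
`"mean"` option exists. Bin comparisons use Welch's unequal-variance
t-test.

## LD score regression

`compute_ld_scores()` sums bias-adjusted squared correlations
$\tilde r^2 = r^2 - (1-r^2)/(n-2)$ within a 1000 kb window (self term
included). `ldsc_h2()` regresses $\chi^2$ on $n\,l_j/m$; `ldsc_rg()`
regresses $z_1 z_2$ on $\sqrt{n_1 n_2}\,l_j/m$ and normalises by the two
univariate slopes. Design choices:

* Regression weights are $1/\max(l_j, 1)$ — a deliberate simplification of
  the full iterative heteroskedasticity weighting; the package's checks of
  LDSC are recovery-based, not replications of a specific implementation.
* "Constraining the intercept" means cross-trait intercept 0 and
  univariate intercepts 1, the values implied by provably disjoint samples;
  both switches are exposed. With sample overlap the free cross-trait
  intercept absorbs the confounding.
* Standard errors come from a delete-one-block jackknife over contiguous
  variant blocks (default 200, reduced proportionally for small panels; at
  the simulated panel sizes the suite uses about 25 blocks so each block
  exceeds the LD correlation length).

## The synthetic-cohort generator

No usable public data exist at desk scale — the motivating individual-level
datasets are access-restricted — so the generator is a first-class module
that encodes the study's statistical structure as settable truths:

* **Genotypes**: haplotypes from a latent Gaussian AR(1) process within LD
  blocks (default block size 20, correlation 0.7 — enough LD to make LD
  scores non-trivial), thresholded at allele frequencies drawn from
  U(0.05, 0.5); variants placed 1 kb apart.
* **Effects**: per causal variant, a trivariate normal across the three
  architectures (disease liability, younger-AFB, older-AFB) whose
  covariance encodes the target heritabilities and genetic correlations;
  the implied correlation matrix is validated as positive semi-definite at
  construction.
* **Disease cohort**: liability = genetic value + normal residual; cases
  exceed $\Phi^{-1}(1-K)$ with prevalence $K = 0.01$; the population is
  sampled in batches until the case/control quotas (defaults 1,500/1,500)
  are filled, reproducing heavy case oversampling.
* **AFB cohort** (default 5,000 women): a latent propensity that is only
  weakly genetic (1% of its variance) assigns each woman to the younger or
  older stratum, so that *architecture differences, not selection*, drive
  the between-stratum correlation; within the stratum, AFB = stratum mean +
  sd × (√h² × standardised stratum genetic value + residual). Residuals of
  women whose AFB would cross the 26-year cut-point are redrawn (a mild
  truncation): without this a non-trivial fraction of women carries the
  wrong stratum's architecture into the observed strata, the stratum
  heritabilities attenuate, and the generator would not encode the truths
  the recovery tests measure. Stratum means/SDs default to 22.5 ± 2.3 and
  29.5 ± 2.8 years, chosen as realistic values around the cohort mean of
  26. An optional truncation interval discards AFB outside it, for the
  truncation-robustness analyses.
* **Relatedness injection** creates cross-cohort parent-offspring pairs
  (one transmitted gamete plus one population haplotype; expected GRM entry
  0.5) to exercise the cross-cohort pruning.

What the generator does **not** emulate: realistic demography, mutation or
recombination maps, assortative mating, covariate confounding (an optional
year-of-birth trend is the only hook), non-normal residuals, and real LD
beyond block-AR structure. Passing recovery tests therefore demonstrate
the estimators' correctness under the assumed model, not robustness to
everything real cohorts contain.

## Quality control

All published filter thresholds are applied with their printed strictness
("call rate < 0.95 excluded" keeps a variant at exactly 0.95): variant call
rate 0.95, MAF 0.01, exact Hardy-Weinberg p-value $10^{-6}$ in controls and
$10^{-10}$ in cases (single-stratum $10^{-7}$), sample call rate 0.98,
ancestry outliers beyond 6 reference SDs on PC1/PC2 (inclusive), and
relatedness pruning above GRM 0.05. The Hardy-Weinberg test is the exact
conditional test (two-sided by summing configurations no more probable
than the one observed) rather than chi-square, which misbehaves at
rare-variant margins; the implementation is swept exhaustively against a
full enumeration oracle for all totals up to 200. Relatedness pruning is
greedy — repeatedly removing the individual with the most above-threshold
partners, ties broken by a seeded draw — which matches the published
"randomly removed" wording while approximately minimising removals; the
survivor set is verified against the threshold on every call. Imputation
is out of scope: imputation-quality filters act as pass-through filters on
a supplied per-variant quality column.

One desk-scale caveat: with a few hundred simulated markers the GRM noise
SD (about $1/\sqrt{m_{\text{eff}}}$) exceeds 0.05, so the published
cross-cohort pruning threshold would delete entire cohorts. The pipeline
therefore prunes at the larger of 0.05 and 4.5 noise SDs, which still
removes injected first-degree relatives (entries near 0.5). At real marker
densities the adaptive floor is far below 0.05 and the printed threshold
binds.

## The pipeline and reproducibility

`run_pipeline()` executes the seven stages — simulate, QC, GRM,
GREML (with GBLUP), association + profile scoring, U-shape regression,
LDSC — writing PLINK-1 filesets, tab-separated tables and a JSON manifest
with per-stage wall times and artifact checksums. Every stochastic step
derives its stream from the configuration seed, so a rerun with the same
configuration is bit-reproducible; the test suite asserts it.

## Problem sizes, power, and honest limits

Dense REML costs $O(n^3)$ per iteration, so the package's simulation
studies run at deliberately chosen desk scales; the generator's *defaults*
keep the emulated design (1,500/1,500 cases/controls, 5,000 women, 5,000
SNPs), while tests pass smaller explicit configurations:

* **Trivariate recovery** (the acceptance backbone): 500/500 cases and
  controls, 2,000 women, 200 SNPs all causal, 30 replicates. The marker
  count is small on purpose: the sampling SE of every genetic (co)variance
  scales with $\sqrt{m_{\text{eff}}/(n_1 n_2)}$, so fewer effective markers
  buy precision at fixed $n$, and making all markers causal removes
  realised-truth noise (the SD of a realised correlation over $m_c$ causal
  draws is $(1-r_g^2)/\sqrt{m_c}$). Under this configuration the three
  genetic correlations are recovered in the mean across replicates.
* A limit stated plainly: the *per-replicate sign pattern* (negative with
  the younger stratum, positive with the older, between-strata below 1)
  is **not** reliably resolvable at desk scale. The model-implied standard
  error of $r_g(\text{disease}, \text{older})$ is roughly 0.25–0.3 at any
  configuration a single CPU can fit — the truth of +0.14 with a stratum
  heritability of 0.03 is only a ~0.5-SE signal — and the corresponding
  acceptance check is expected to fail. Resolving that sign is precisely
  what required a biobank-scale cohort (where the same quantity carries a
  standard error of 0.08); the suite keeps the check at its stated
  threshold rather than weakening it.
* **Calibration studies** (heterogeneity-test size, null uniformity,
  truncation robustness, LDSC/GREML concordance) run at n of a few hundred
  to 1,400 with 50–200 replicates each — sizes at which each study
  completes in minutes while the quantity under test (a size, a bias, a
  concordance) is measured with adequate replicate counts.
* A second limitation found while calibrating: the Wald test of
  $r_g = 1$ over-rejects when the marker panel is very small — at fixed n
  its empirical size falls back to the nominal 5% only once the panel
  carries a few hundred markers. The variance estimates behind $r_g$ live
  on the GRM's relatedness spectrum, and with few effective markers their
  distribution is too skewed for the normal approximation. The calibration
  study in the test suite therefore runs at a 300-marker panel (which is
  also far closer to the emulated design's 5,000 markers); users applying
  the heterogeneity test to very sparse panels should not trust its
  nominal size.
* The LDSC intercept is only identifiable when LD scores vary across
  variants. The generator's homogeneous default blocks produce
  near-constant scores, so LDSC-focused simulations pass a vector of
  per-block AR correlations (`ld_rho`) to create heterogeneous LD, as real
  genomes have.
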