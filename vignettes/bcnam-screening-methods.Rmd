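---
title: "Genomic screening of backcross introgression lines: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic screening of backcross introgression lines: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Backcross nested-association mapping (BC-NAM) programs introgress diversity
from unadapted donors into elite inbreds: each population is `donor x elite`,
backcrossed once to the elite recurrent parent and selfed to BC1F3. In a
hybrid crop such as grain sorghum, the worth of every derived line must be
measured in testcross combination with elite male-sterile testers, which is
expensive at the scale of dozens of populations. `bcnamScreen` implements
the statistical pipeline for asking whether marker data can prescreen such
lines: per-environment variance-component analysis and BLUE extraction,
marker-based relationship kernels extended to hybrids, Bayesian GBLUP with
additive and dominance terms, and two cross-validation schemes that mimic
the breeder's decisions (CV1: new lines from sampled populations; CV3: a
new population predicted from an already-phenotyped one).

# The phenotypic model

For each environment and trait the plot model is

$$y = 1\mu + Z_1 h + Z_2 r + \varepsilon,$$

with hybrid effects $h \sim N(0, \sigma_h^2 I)$, replicate (block) effects
$r \sim N(0, \sigma_r^2 I)$ and residuals $\varepsilon \sim N(0,
\sigma_\varepsilon^2 I)$. `fit_random_model()` estimates the components by
REML through lme4 (optimizer `bobyqa` tightened to `rhoend = 2e-9` so that
balanced fixtures agree with the ANOVA closed form to $10^{-6}$ relative).
From the components it reports:

* **percent of total** per component, $100\,\sigma_k^2/\sum_j \sigma_j^2$;
* **entry-mean repeatability** $R = \sigma_h^2 / (\sigma_h^2 +
  \sigma_\varepsilon^2 / r)$ with $r$ the replicate count. The sources this
  package follows print $R$ without a formula; this entry-mean form
  reproduces their printed values from the printed components (e.g.
  $1.19/(1.19 + 0.86/2) = 0.735$) for five of six trait-environment rows to
  three decimals, the sixth to within rounding of the inputs;
* **CVe** $= 100\sqrt{\sigma_\varepsilon^2}/\bar y$, the residual
  coefficient of variation;
* a **one-sided Wald p-value** for $\sigma_h^2$: $z =
  \hat\sigma_h^2/\mathrm{SE}$, with the SE taken from the inverse numerical
  Hessian of the package's own restricted log-likelihood at the lme4
  optimum (lme4 does not expose variance-component standard errors). A
  boundary-corrected likelihood-ratio alternative
  ($\tfrac12\chi^2_0 + \tfrac12\chi^2_1$) is available via `test = "lrt"`.
  Negative component estimates are truncated at zero and flagged.

BLUEs come from the same model with hybrid as a fixed effect
(`fit_blues()`); on a balanced complete design they reduce to hybrid means,
and with missing plots they are the GLS solution under the fit's replicate
and residual variances. A lone hybrid (no estimable replicate contrast) is
returned as its plot mean.

`combine_gate()` decides whether environments may be pooled: Shapiro-Wilk
on pooled residuals, Bartlett across environments, and the two-group
variance-ratio F. The verdict is "keep-separate" if either of the first
two rejects at $\alpha = 0.05$. Both Bartlett's $\chi^2$ and the F ratio
are reported because published tables in this literature sometimes label
the homogeneity statistic simply "F"; neither is privileged downstream.
All later stages are strictly per-environment, so the pipeline deliberately
has no combined multi-environment model.

# Kernels

With dosage matrix $X$ (individuals $\times$ markers, alternate-allele
counts) and in-sample frequencies $p_i$:

* **additive (VanRaden)**: columns centred by $2p_i$, $K_A = XX' / (2\sum_i
  p_i(1-p_i))$;
* **dominance (Vitezica orthogonal coding)**: per marker the covariate is
  $-2q_i^2$, $2p_iq_i$, $-2p_i^2$ for dosages 2, 1, 0, and $K_D = WW' /
  \sum_i (2p_iq_i)^2$.

Frequencies are estimated on the panel being processed (lines + testers +
parents jointly in the pipeline): self-contained and standard, though it
means kernels change if the panel composition changes. Markers with minor
allele frequency *strictly below* 0.05 are removed first (a marker at
exactly the threshold stays, matching a "less than 5% removed" rule).

Hybrid kernels are the Kronecker product of the parental blocks, ordered
tester $\otimes$ line, with rows/columns extracted for the realized
(line, tester) pairs only; the entry for hybrids $(l_1,t_1)$ and
$(l_2,t_2)$ is $K_T[t_1,t_2]\,K_L[l_1,l_2]$.

Genetic distance is $1 -$ mean identity-by-state share, where the share per
marker is $(2 - |x_i - x_j|)/2$. This is the common "1 − IBS" distance;
equivalence with any particular GUI implementation's dialect is not
claimed, and the output metadata label the definition. PCoA is classical
metric scaling (double-centring, eigendecomposition), with non-positive
axes dropped from the percent-variance base.

# The GBLUP sampler

Per environment the prediction model on BLUEs is

$$y = \mu + u_A + u_D + \varepsilon,\qquad
u_A \sim N(0, K_A\sigma_A^2),\quad u_D \sim N(0, K_D\sigma_D^2).$$

`fit_gblup()` is a Gibbs sampler that eigendecomposes each kernel once and
samples its effects in the eigenbasis, where the full conditional is
diagonal. Numerical choices:

* eigenvalues below $10^{-8}$ are dropped (rank truncation doubles as the
  PSD jitter guard);
* variance components get scaled-inverse-$\chi^2$ priors, df 5, with
  scales chosen so the prior splits an expected $R^2 = 0.5$ equally
  between the additive and dominance terms and leaves the rest to the
  residual — the common default family for this model class;
* missing phenotypes are data-augmented with posterior-predictive draws
  each iteration, so cross-validation masks entries rather than rebuilding
  the model; a hybrid with zero kernel covariance to the data predicts at
  the intercept;
* defaults 15,000 iterations, 5,000 burn-in, thinning 5 — generous for
  $n \approx 150$; effective sample sizes (Geyer initial positive
  sequence) are reported and a warning is raised when a variance chain's
  ESS drops below 100.

With variance components held fixed the posterior means agree with the
closed-form mixed-model (BLUP) solution, which the tests assert on small
panels. Exchangeability under reordering of hybrids is checked at Monte-
Carlo tolerance rather than bit-identity: LAPACK eigenvectors of a permuted
kernel are not the permuted eigenvectors, so chains diverge numerically
while targeting the same posterior.

`variance_partition()` scales each posterior-mean variance by the mean
diagonal of its kernel (the sample variance that term contributes) and
normalizes with the residual to percentages. Two behaviours of this
partition are worth knowing. First, on an unstructured (near-identity)
dominance kernel $\sigma_D^2$ is barely identified against
$\sigma_\varepsilon^2$, and the posterior shares drift toward the prior's;
informative partitions need family structure in the kernels, which
testcross panels have. Second, at very low heritability the split is
informed only by the leading eigendirections, so small panels stay
prior-bound; the package's test of the "residual dominates at $h^2 =
0.05$" property therefore runs at ~600 hybrids, where the likelihood wins.

# Cross-validation and metrics

`selection_metrics()` scores a prediction vector by Pearson correlation
with the observations, top-15% selection accuracy and bottom-50%
elimination accuracy. Set sizes use round-half-away-from-zero with a floor
of one (at $n = 143$: top $k = 21$, bottom $k = 72$), and rank ties break
deterministically by id. Under random ranking the exact null expectations
are $k/n$ — numerically 0.147 and 0.503 at $n = 143$, i.e. the nominal
0.15/0.50 baselines.

`run_cv1()` repeats a random 50/50 split (stratified by population when
labels are supplied, so both populations stay in training), fits the
sampler on the training half, and scores the held-out half; summaries are
means with SE $= \mathrm{SD}/\sqrt{\text{reps}}$ over 20 repetitions.
`run_cv3()` trains on all of a base population plus a fraction
$f \in \{0, 0.05, 0.10, 0.20\}$ of the target population
($\lfloor f\,n_\text{target}\rfloor$ lines) and scores the remaining
target lines; at $f = 0$ the training set is deterministic but repetitions
are retained so every fraction reports in the same format. Checks
(non-experimental hybrids) are excluded from metric computation. Whether
pooled CV1 metrics should be computed per population is left open by the
sources; pooled-with-stratified-splits is what this package implements and
labels.

# The simulator

`simulate_trial()` generates the full study: founders, two BC1F3
populations, testers, checks, the trial design and phenotypes.

* **Founders** are fully homozygous; the donor differs from the recurrent
  parent at `floor(divergence * n_markers)` positions (default divergence
  0.3, 2,000 markers on 10 chromosomes of 150 cM — sorghum-like and fast).
* **Meiosis** uses a no-interference Poisson crossover model (rate = map
  length in Morgans per chromosome, uniform positions, random start
  phase), which implies Haldane's map function
  $r = \tfrac12(1 - e^{-2d})$ and makes recombination analytically
  checkable.
* **BC1F3 lines** follow single-plant descent (F1 → BC1F1 → two selfs);
  the propagation scheme is not documented by the sources, and single-seed
  descent is the assumption made here. Expected donor-allele frequency at
  segregating loci is 0.25 and expected residual heterozygosity 0.125.
* **Testers and checks** are modelled as homozygous elite-pool inbreds
  differing from the recurrent parent at a configurable fraction of
  markers (default 0.15); the sources give no genotypes for them, so this
  is a package choice documented here.
* **Hybrids** take one gamete per line per hybrid id — each hybrid is one
  genotype, with residual line heterozygosity entering through that single
  sampled gamete, matching how a testcross seed lot is treated in analysis.
* **Phenotypes** follow the plot model above with genetic values built
  from causal loci that are a subset of the genotyped markers (no hidden
  QTL by default; a `hidden_qtl_frac` option exists for robustness
  studies). Additive values act on centred dosages; dominance deviations
  act on the heterozygote indicator and are then orthogonalized against
  the additive values — which is what "dominance deviation" means in the
  quantitative-genetics decomposition — so planted variances add exactly.
  When `target_var_a`/`target_var_d` are set (per environment if named),
  effects are rescaled so the realized variances across the trial's
  hybrids equal the requested values; this realized-scaling device (as in
  standard breeding-program simulators) is what lets the default
  configurations plant, e.g., a 1.19/0.15/0.86 grain-yield structure in
  the Bushland-like environment exactly.

The default trait configurations (`default_trait_configs()`) carry the
published two-environment variance structure for grain yield, plant height
and days to anthesis, with trait means implied by the printed CVe values;
the genetic target splits 80% additive / 20% dominance, a typical ratio
for yield-type traits when no better information exists.

What the simulator does *not* emulate: selection during population
development (real BC-NAM lines were selected for agronomic fitness),
epistasis, genotype-by-environment correlation beyond independent
per-environment parameters, genotyping error and missingness, and linkage
disequilibrium with un-genotyped causal variants. Passing tests therefore
demonstrate internal consistency of the statistical machinery under the
stated generative model, not field-data performance.

# Scale choices in the test suite

Test problem sizes were chosen so each property is measured with
Monte-Carlo error well inside its tolerance: the variance-recovery loop
uses 400 phenotype redraws of the 143-hybrid trial because the replicate
component — a variance estimated from two block levels — has per-seed
scatter of about 0.47 around 0.15, and 400 draws put the standard error of
its mean near 1.5% of truth; the additive-only recovery study uses 20
simulated trials of ~300 hybrids; recombination checks use 20,000 gametes
per distance. The boundary-truncated REML estimator of the replicate
variance carries a small positive bias (a few percent at these settings) —
an inherent property of nonnegative estimation on one degree of freedom,
visible in the recovery results and not corrected for.

# Known limitations

* The Wald SE for $\sigma_h^2$ relies on asymptotic normality of a
  boundary-constrained estimator; at the boundary it is flagged rather
  than reported, and the LRT alternative is preferred there.
* The dominance share of small, weakly structured panels is prior-bound
  (see above); report ESS and treat partitions at $n \lesssim 150$ as
  descriptive.
* CV1 metrics on a *single* noise realization are not centred at the null
  baselines — the realized alignment between that draw and the kernel
  eigenspace acts as a fixed offset; null behaviour holds across
  independent phenotype draws, which is how the tests assess it.
* The pipeline consumes a clean dosage matrix; variant calling, imputation
  and their artefacts are upstream and out of scope (a fail-fast missing
  check with an optional mean-impute flag is the only concession).
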