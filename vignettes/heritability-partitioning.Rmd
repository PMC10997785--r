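---
title: "Partitioning heritability with thresholded GRMs: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning heritability with thresholded GRMs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heritpart)
```

## The model

An animal model treats an individual's additive genetic value as a
random effect whose covariance across individuals is proportional to a
relationship matrix. For records $y$ (possibly several per individual),

$$ y = X\beta + \sum_r Z_r u_r + W g + \varepsilon, \qquad
   g \sim N(0,\, M\,\sigma^2_g), $$

where $X$ carries the fixed effects, each $Z_r$ is the incidence matrix
of a non-genetic random effect (birth-year cohort, maternal identity,
permanent environment), and $W$ maps records to individuals so that
repeated measures share one genetic value — the repeatability model
obtained by fitting individual identity as a random effect. Four
choices of genetic structure are supported, fitted singly or jointly:

1. **GRM-only**: $M = M_g$, the identity-by-state GRM of the whole
   sample; its variance ratio is $h^2_\mathrm{GRM}$.
2. **GRM + thresholded GRM**: adds $W k_t$ with
   $k_t \sim N(0, M_{kt}\sigma^2_{kin})$, where $M_{kt}$ equals $M_g$
   except that every off-diagonal entry *equal to or less than* a
   threshold $t$ is set to zero (defaults $t \in \{0.05, 0.1\}$). The
   two ratios are $h^2_{pop}$ and $h^2_{kin}$; their sum $h^2_{pk}$ is
   comparable to pedigree heritability.
3. **GRM + MAF-restricted GRM**: the second matrix is instead built
   from the SNPs whose minor allele frequency lies strictly *under* a
   threshold (defaults 0.1, 0.05, 0.01, 0.005, 0.001), probing
   rare-allele variance.
4. **Pedigree**: $M = A$, Henderson's numerator relationship matrix,
   giving $h^2_{ped}$.

Both matrices in the joint models capture identity-by-descent among
close relatives; only the full GRM also tracks identity-by-state among
nominal non-relatives. Family-associated variance — dominance,
epistasis, common environment not captured by the explicit random
effects, and additive variance segregating within families — therefore
loads on the thresholded matrix.

The GRM is the MAF-weighted IBS estimator: with $s_{iz}$ the counted
(reference) allele dosage and $p_z$ its sample frequency,

$$ A_{ij} = \frac{1}{N}\sum_z
   \frac{(s_{iz}-2p_z)(s_{jz}-2p_z)}{2p_z(1-p_z)} \ (i \ne j), \qquad
   A_{ii} = 1 + \frac{1}{N}\sum_z
   \frac{s_{iz}^2-(1+2p_z)s_{iz}+2p_z^2}{2p_z(1-p_z)}. $$

Sharing a rare allele contributes more evidence of relatedness than
sharing a common one, which is what lets the estimator separate IBD
from background IBS. The diagonal minus one is the Fhat3 inbreeding
estimator, zero in expectation under Hardy–Weinberg.

## Numerical choices

**Boundary conventions.** Thresholding zeroes off-diagonals with
$A_{ij} \le t$ (inclusive) and never touches the diagonal —
self-relatedness must survive for the covariance structure to remain
usable. MAF selection is strict (`maf < threshold`). Region windows
are 1-based inclusive, matching `.bim` coordinates, and a GRM is
refused (a typed condition, recorded as a skipped row by the suite
runner) when fewer than 10 SNPs remain: averages over a handful of
SNPs are too noisy to fit. QC keeps a SNP only if MAF and call rate
are strictly above their thresholds, an individual only if its call
rate is strictly above its threshold and its identity-by-state
proportion with every earlier-listed individual is strictly below the
ceiling; of an offending IBS pair the later-listed member is dropped,
a deterministic rule where common tooling leaves the choice
unspecified.

**Missing genotypes.** Missing dosages contribute zero to both the
off-diagonal and diagonal GRM sums, with the averaging denominator
kept at the panel size $N$ (mean-substitution at $2p_z$; substituting
literally into the diagonal identity would contribute $-1$ per missing
call and bias inbreeding downward, so "zero contribution" is applied
uniformly). `per_pair_n = TRUE` switches to per-pair non-missing
counts, the convention of common GRM software; both are exposed
because nearly-complete imputed panels make the difference negligible
while fully observed panels make them identical. Phenotype records
with missing responses or covariates are dropped and counted, never
imputed.

**REML.** `reml_fit()` maximizes the restricted likelihood
$-\tfrac12[\log|V| + \log|X'V^{-1}X| + y'Py + (n-p)\log 2\pi]$ (the
constant is included) with $V = \sum_c \sigma^2_c V_c + \sigma^2_e I$,
genetic structures entering as $W M W'$ and grouping factors as
$Z_rZ_r'$. The algorithm is a short expectation–maximization warm
start (3 scaled-gradient steps) followed by average-information
updates with step-halving; a step is only accepted if the likelihood
does not decrease. Convergence requires $|\Delta \log L| < 10^{-8}$
and a maximum relative parameter change below $10^{-6}$, within 200
iterations; non-convergence is reported on the fit, never fatal to a
suite. Under the default non-negativity constraint, components whose
updates go negative are pinned to a floor of $10^{-8}\times$ the
phenotypic variance and flagged; pinned components are dropped from
the AI system while their score points outward (an active-set step)
and their standard errors are reported as `NA`. Thresholded and
rare-allele GRMs are routinely indefinite (the excess-homozygosity
diagonal is not the cross-product diagonal), so the starting point
shrinks the non-residual components geometrically until $V$ is
positive definite. The sampling covariance of the estimates is the
inverse average-information matrix at the optimum; ratio standard
errors use the delta method over the full component covariance.
`constrain = FALSE` removes the floor (V must merely stay positive
definite along the path), which matters below.

**Likelihood-ratio tests.** $\Lambda = \max(0,
2(\log L_\mathrm{full} - \log L_\mathrm{reduced}))$. The default
reference distribution is a central $\chi^2_1$, matching how such
tests are usually reported; because a variance sits on the boundary of
its parameter space under the null, the boundary-correct 50:50 mixture
of a point mass at zero and $\chi^2_1$ is available as
`null_mode = "mixture_50_50"` and is what the calibration tests use.
The plain $\chi^2_1$ is conservative by about a factor of two.

**Monogenic traits** are categorical; two observed classes are coded
0/1 and three classes 0/1/2 in stated order, and the same linear
machinery is fitted on the observed scale — no liability-threshold
model is attempted. Sex-limited architectures (dominant in males,
codominant in females, as for horn type) code each sex separately.

## The synthetic-data generator

`simulate_study()` emulates the features of a multigenerational wild
ungulate study that the analysis actually leans on:

* **Pedigree**: overlapping generations with both sexes promiscuous —
  each offspring draws its dam and sire independently from the
  adults of the preceding two generations. Defaults (150 founders,
  4 generations of 250) give roughly 1150 individuals with a
  half-sib:full-sib pair ratio far above 10:1, mean pairwise pedigree
  relatedness around 0.009, and mild inbreeding from the finite
  mating pool — about 4.7% of GRM off-diagonals above 0.05, closely
  matching the relatedness profile such populations show.
* **Genotypes**: gene dropping of unlinked biallelic SNPs — founders
  from Hardy–Weinberg at uniform frequencies in [0.05, 0.5],
  descendants by Mendelian segregation. The realized GRM then
  converges to the pedigree expectation $A$ as SNPs are added, the
  premise that links the GRM and pedigree models. Drift-fixed SNPs
  are removed from the analysis panel, as any QC step would.
* **Phenotypes**: fixed sex effect plus additive values from a random
  causal subset (default 200 SNPs) with MAF-standardized effects —
  per-allele effect variance proportional to $1/(2p(1-p))$, the
  architecture the weighted GRM models — plus family-associated,
  maternal, cohort and permanent-environment components and
  record-level residuals. Each realized component is rescaled to its
  exact target variance fraction, so simulated "truth" is free of
  Monte-Carlo drift in the component sizes.

The family-associated component has three modes. `"kinship"` (the
default) draws it from the thresholded GRM itself, i.e. simulates
exactly the covariance structure Model 2 fits; this is the only mode
under which recovering the generating fraction is a well-posed target,
and it is what the calibration tests use. `"common_env"` gives
maternal sibships a shared deviate: the two-GRM model then *detects*
the family variance (the LRT fires) but the fitted $\sigma^2_{kin}$
converges to roughly the shared variance divided by the mean
within-family relatedness (~0.25), not to the generating fraction —
a structure mismatch inherent to the method, not a defect of the
fit. `"dominance"` sums per-SNP dominance deviations, with a similar
caveat. What passing calibration shows is therefore that the
estimator and its standard errors behave as advertised *when the
model matches the generating process*; it does not certify the
partition's interpretation on real data, where the family covariance
is never exactly proportional to a thresholded GRM.

The generator makes no attempt at linkage disequilibrium, selection,
survival or demographic fluctuation; cohort effects are carried as
covariates only.

## Calibration results computed by the tests

The test suite (and `scripts/acceptance.R`, which recomputes the same
kind of quantities from scratch) verifies, among others:

* the GRM against a brute-force double-loop evaluation of the printed
  estimator ($10^{-10}$ on panels up to 20 × 50), and $A$ against an
  independent recursive coancestry oracle ($10^{-12}$, pedigrees up
  to 200);
* the restricted likelihood against a dense generic-solver oracle
  ($10^{-8}$, $n \le 50$) and the closed-form balanced one-way REML
  solution ($10^{-6}$);
* recovery: with $h^2_{pop} = 0.30$ and a kinship-structured family
  fraction of 0.15 at ~1000 phenotyped individuals and 3000 SNPs, the
  mean fitted $\hat h^2_{pop}$ and $\hat h^2_{kin}$ over 25 replicates
  lie within two Monte-Carlo standard errors of truth;
* null calibration at ~500 individuals and 1500 SNPs over 100
  replicates: the mixture-mode LRT rejects at close to its nominal 5%
  level, and the *unconstrained* $\hat h^2_{kin}$ centres on zero —
  the constrained estimator cannot, since flooring censors its
  sampling distribution at zero and pushes the null mean up; this is
  why the package exposes `constrain = FALSE` at all.

These problem sizes are the package's chosen trade-off between
sampling noise and runtime; they are stated here so the reported
calibration can be read at the scale it was computed.

## Known limitations

* The partition's identifiability degrades as mean relatedness rises:
  when most pairs sit above the threshold the two matrices become
  collinear and single-replicate splits of $h^2_{pk}$ between
  $h^2_{pop}$ and $h^2_{kin}$ are noisy (their sum is stable).
* Standard errors come from the inverse average information and the
  delta method; they are asymptotic and silently optimistic near
  boundaries, where the package instead reports `NA`.
* No bivariate models, no liability-scale models for categorical
  traits, no LD-aware SNP weighting, no dominance GRM.
* `build_A` is quadratic in pedigree size and dense; it is meant for
  study populations (up to a few thousand individuals), not national
  evaluations.
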