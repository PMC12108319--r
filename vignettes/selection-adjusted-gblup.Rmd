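---
title: "Selection-adjusted GBLUP: models, simulator and the enrichment diagnostic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selection-adjusted GBLUP: models, simulator and the enrichment diagnostic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

GBLUP predicts breeding values from a genomic relationship matrix (GRM),
and the GRM encodes an assumption about how marker effect sizes relate to
allele frequency. The classic VanRaden GRM assumes every SNP has the same
effect-size variance regardless of frequency; the GCTA standardized GRM
assumes every SNP explains the same heritability. Both are special cases
of a one-parameter family: if the effect variance of a variant with
counted-allele frequency $p$ scales as $[2p(1-p)]^S$, then $S = 0$ gives
VanRaden, $S = -1$ gives GCTA, $S < -1$ describes strong negative
selection (rare alleles carry larger effects) and $S > 0$ mimics positive
selection. Livestock populations have been under intense artificial
selection, so the "right" $S$ is trait-specific and unknown; this package
implements the machinery to model it, to simulate traits under a known
$S$, and to diagnose which $S$ fits a real trait.

## Models

**GBLUP-S.** The mixed model is $y = Z a + e$ with
$a \sim N(0, G \sigma_a^2)$ and $e \sim N(0, I \sigma_e^2)$, where

$$G = \frac{M M'}{\sum_i [2 p_i (1 - p_i)]^{S+1}},
  \qquad
  m_{ij} = (x_{ij} - 2 p_i)\,[2 p_i (1 - p_i)]^{S/2},$$

$x_{ij} \in \{0, 1, 2\}$ counting copies of the A1 allele. The printed
form of the matrix element is ambiguous in much of the literature; this
package uses the reading above because it is the only one under which
$S = 0$ reproduces the VanRaden GRM and $S = -1$ the GCTA
average-of-standardized-products GRM exactly — both equivalences are
enforced by unit tests against independent per-SNP-loop oracles. For a
single SNP the $S$-powers cancel between numerator and denominator, so a
one-SNP GRM is independent of $S$; that algebraic identity is also a
test.

**GBLUP-SMS.** SNPs are partitioned into five MAF bins (0.01–0.1,
0.1–0.2, 0.2–0.3, 0.3–0.4, 0.4–0.5; intervals right-closed, the first
closed on both ends) and the model becomes
$y = \sum_{t=1}^{5} Z_t a_t + e$ with one GRM per bin, each built by the
same formula from its own SNPs with its own denominator. Because the
numerators add, the denominator-weighted sum of the five matrices
reconstructs the whole-panel GRM
($G = \sum_t (d_t / d) G^{(t)}$), which the tests verify to $10^{-10}$.
Giving each bin its own denominator is deliberate: each component carries
its own variance $\sigma_{a,t}^2$, so any common scaling is absorbed into
the estimate, and the per-bin heritability shares remain interpretable.

**Frequencies.** $p_i$ is always the counted-allele frequency (not the
folded MAF): centering by $2p_i$ requires it, while the scaling weight
$2p(1-p)$ is symmetric either way. Frequencies are estimated once from
the full QC-passing panel and reused when centering candidates, so
reference and candidate individuals live on a common scale. Missing
genotypes are mean-imputed at GRM construction only ($x \to 2p_i$),
which makes their centered contribution exactly zero; the stored panel
keeps its missing codes.

## REML and prediction

`fit_reml()` maximizes the restricted likelihood of
$y \sim N(1\mu, \sum_t G^{(t)}\sigma_t^2 + I\sigma_e^2)$. Phenotypes are
expected to be pre-adjusted for fixed effects; the intercept is still
projected out for robustness. Two paths:

* **Single component:** one eigendecomposition of $G$, then the
  restricted likelihood is profiled on $h^2$ (the scale has a closed
  form). A coarse 101-point scan brackets the optimum before
  `optimize()` refines it, and the boundary values $h^2 \in \{0, 1\}$
  are always compared, so boundary optima are found exactly. A
  2000-point dense-likelihood grid oracle agrees within $10^{-3}$ in
  $h^2$.
* **Multiple components:** average-information (AI) REML. The first
  step is an expectation-maximization (EM) update; afterwards each AI
  step is vetted by step-halving against the restricted likelihood, and
  plain EM is the fallback when the AI system is unsolvable or no
  halved step improves. Components estimated at the non-negativity
  floor ($10^{-8} \times \mathrm{var}(y)$) with negative gradient are
  pinned and dropped from the AI system (active set); without pinning,
  boundary components force EM crawl (we observed ~190 iterations where
  the pinned version needs 8 on the same instance, at the same
  optimum). Convergence requires both $|\Delta \log L| < 10^{-6}$ and a
  maximum relative parameter change $< 10^{-4}$, with a cap of 200
  iterations; non-convergence is flagged, never silent. A length-one
  component list agrees with the single-component path to $10^{-6}$ in
  $h^2$.

The LRT statistic is $2(\log L_{\mathrm{full}} - \log L_{\mathrm{null}})$
against the residual-only null, floored at zero, reported as a raw fit
gauge. For the multi-component model the null removes all genetic
components jointly (one statistic per model). Because the null parameter
sits on a boundary, the optional p-value (single-component only) uses
the $\tfrac12\chi^2_0 + \tfrac12\chi^2_1$ mixture.

`predict_gebv()` computes, per component,
$\hat a_t(\mathrm{cand}) = \sigma_t^2\, G^{(t)}[\mathrm{cand},
\mathrm{train}]\, V^{-1} (y - \hat\mu)$ — the conditional expectation,
which a test verifies against a dense Henderson mixed-model-equations
solve to $10^{-8}$.

## Trait simulator

`simulate_trait()` draws causal variants (CVs) uniformly from the panel,
effects $g_i = [2p_i(1-p_i)]^{S/2} g_i^*$ with $g_i^* \sim N(0,1)$, true
breeding values $\mathrm{tbv} = X_{\mathrm{cv}} g$, and residuals with
variance $\sigma_a^2 (1-h^2)/h^2$ where $\sigma_a^2$ is the *empirical*
variance of the realized TBV vector. The empirical choice (rather than a
theoretical variance) calibrates each replicate, keeping realized
$\mathrm{var(tbv)}/\mathrm{var}(y)$ tight around the target $h^2$; the
acceptance test confirms a mean within 0.01 of 0.1 over 50 replicates.
The per-CV heritability $h_i^2 = 2p_i(1-p_i) g_i^2$ then has expectation
proportional to $[2p(1-p)]^{S+1}$: flat in MAF at $S = -1$, decreasing
for $S < -1$, increasing above — the simulated-architecture profile the
tests check by binned means.

Simulated CVs stay inside the analysis SNP set (they are not masked from
the GRM), matching the design in which CVs are drawn from the QC-passing
panel; users can pass `snp_subset` to `build_grm()` to study imperfect
tagging instead. Replicates redraw CV positions independently.

`generate_panel()` draws allele frequencies uniformly on $[0.01, 0.5]$
and genotypes as two Bernoulli allele draws (HWE), in linkage
equilibrium by default; an optional Gaussian-copula block generator adds
within-block correlation but is off by default since the models ignore
LD. SNPs whose realized sample MAF falls below the 0.01 QC floor are
resampled, so a synthetic panel behaves like a QC-filtered one — which
is what it stands in for. One master seed derives per-stage child seeds
(`derive_seeds()`), making the full pipeline bit-reproducible.

What the synthetic panels deliberately lack: linkage disequilibrium,
family/pedigree structure, and selection-induced allele-frequency
spectra. Tests passing on these panels therefore demonstrate the
estimation machinery (exact GRM algebra, REML optima, calibration of
the enrichment diagnostic under the model's own assumptions), not
robustness to LD between CVs and markers or to close relatives — both of
which inflate or bias heritability estimates in real livestock data.

## Choosing S: enrichment and the chi-square

From a five-component GBLUP-SMS fit, the observed heritability
proportion of bin $i$ is $O_i = \hat h_i^2 / \sum_t \hat h_t^2$; its
expected share under the model's own $S$ is

$$E_i = \frac{\sum_{j \in \mathrm{bin}\,i} [2p_j(1-p_j)]^{S+1}}
             {\sum_j [2p_j(1-p_j)]^{S+1}},$$

the enrichment is $O_i / E_i$, and the goodness-of-fit statistic is
$\chi^2 = \sum_i (O_i - E_i)^2 / E_i$. Both $O$ and $E$ are proportions
summing to one, so the statistic is dimensionless and comparable across
traits; expected shares are computed with the model's $S$, so the
statistic measures the internal consistency of that $S$ and its minimum
over an $S$ grid identifies the best-calibrated exponent. Degrees of
freedom are fixed at 4 (five bins minus one) when a p-value is
requested; by default only the statistic is reported.

## Study conditions used by the tests and the acceptance script

All checks run on synthetic panels at sizes chosen to finish on a single
CPU while retaining statistical power; these are the package's own
desk-scale study conditions:

* heritability recovery: $n = 1500$, $m = 8000$, $h^2 = 0.3$, 1000 CVs,
  20 replicates, $S_{\mathrm{true}} \in \{-1, 0\}$, matched-S fits;
* simulator calibration: $n = 1000$, $m = 5000$, $h^2 = 0.1$ (1000 CVs),
  50 replicates for the realized-$h^2$ check, 20 for the MAF-profile
  checks;
* enrichment calibration and S selection: $n = 800$, $m = 4000$,
  400 CVs, $h^2 = 0.4$ (a moderately heritable trait makes the per-bin
  shares estimable at this $n$), $S_{\mathrm{true}} = -1$, 10
  replicates over the seven-point model grid $\{-2, \dots, 1\}$;
* prediction under strong negative selection: $n = 800$, $m = 3000$,
  150 CVs, $h^2 = 0.1$, $S_{\mathrm{true}} = -2$, 9:1 holdout,
  10 replicates, comparing model $S = -2$ against $S = +1$ and the
  grid-wide accuracy spread of GBLUP-S against GBLUP-SMS.

In the prediction comparison, a training fit that lands at the
zero-heritability boundary predicts a constant, whose correlation with
anything is undefined; such fits are scored as accuracy 0 (no predictive
ability), a convention that applies symmetrically to both models.

## Numerical choices and degenerate inputs

* The per-SNP weights $[2p(1-p)]^{S/2}$ and the denominator are
  evaluated as $\exp(k \log 2p(1-p))$, avoiding overflow for strongly
  negative $S$ at $p$ near 0.01.
* Monomorphic SNPs are an error inside `build_grm()` (zero-variance
  scaling is undefined for $S < 0$); they should have been removed by
  QC (`apply_qc()` filters missingness $> 0.05$, HWE exact-test
  $p < 10^{-5}$, MAF $< 0.01$, sequentially in that order, each SNP
  attributed to the first filter it fails). The HWE threshold is
  configurable; $10^{-6}$ is a common alternative reading.
* Fractional (imputed) dosages round to the nearest integer with ties
  going away from zero ($0.5 \to 1$), a deterministic documented rule.
* The HWE test is the exact conditional (PLINK-style) test, mid-p off,
  enumerated in log space; monomorphic sites return 1.
* Empty MAF bins drop their component with a warning; an all-empty
  binning is an error.
* GRMs are symmetrized ($G \leftarrow (G + G')/2$) after the matrix
  product to remove floating-point asymmetry, and PSD can be verified
  on request (`check_psd = TRUE`).

## Known limitations

* No LD-aware SNP weighting, no dominance or epistatic relationship
  matrices, and no Bayesian (MCMC) estimation of $S$ — the $S$ grid plus
  the chi-square diagnostic is the selection mechanism offered.
* Heritability estimates in closely related populations absorb shared
  non-genetic variance; on such data the estimates here (like any
  GREML) should be read as upper bounds on narrow-sense SNP
  heritability.
* The dense REML solver targets panels up to a few thousand
  individuals; it makes no attempt at the sparse or
  randomized-trace tricks needed for biobank scale.
* Phenotype pre-adjustment (fixed effects, pseudo-phenotype
  construction) is out of scope: the package takes adjusted,
  near-zero-mean phenotypes as input and only removes an intercept.

## A worked example

```{r, eval = FALSE}
library(selblup)

panel <- generate_panel(500, 2000, seed = 1)
trait <- simulate_trait(panel, n_cv = 200, s_true = -1, h2 = 0.4,
                        seed = 2)

scheme <- make_folds(500, "holdout91", seed = 3)
res <- run_s_grid(panel, trait$phenotypes,
                  s_grid = c(-2, -1, 0, 1),
                  model = c("gblup-s", "gblup-sms"),
                  scheme = scheme, truth = trait$tbv)
aggregate_s_grid(res)
```

In the `gblup-sms` rows the chi-square is smallest around the simulated
$S = -1$ (in a single replicate at this size the argmin can land one
grid step away; over 10 replicates at $n = 800$ the acceptance tests
find it within $\pm 0.5$ of the truth), while the badly mismatched
$S = -2$ clearly degrades the single-GRM model's accuracy.
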