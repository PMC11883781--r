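---
title: "Latent symptom factors and their genetic architecture: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent symptom factors and their genetic architecture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## What this package computes

`semgreml` implements an individual-level pipeline for studying the shared
structure of psychiatric symptom domains — here, eating-disorder symptom
scores (AN, BN, BED) and three suicidal-ideation items — and the genetic
architecture of the latent factors behind them:

1. **Phenotype preparation.** Item responses are summed into symptom scores,
   every analysis variable is residualized by OLS on age, sex, genotyping
   batch and ten ancestry principal components, and the sample is split
   (default 70/30) into exploration and confirmation halves.
2. **Latent structure.** Exploratory factor analysis (ML extraction, oblique
   quartimin rotation) on the training half; confirmatory models fitted by
   full-information maximum likelihood (FIML) on the holdout; a zoo of
   theoretical structures (two correlated factors, a hierarchical
   second-order model, a bifactor "residual" model, and a four-factor
   model), each with and without depression/anxiety sum scores.
3. **Genetics of the factors.** Factor scores are extracted and used as GWAS
   phenotypes (per-SNP OLS, PLINK-2-style output, genomic-control
   diagnostics); SNP heritability and genetic correlations of the factors
   are estimated by univariate and bivariate average-information REML on a
   genomic relationship matrix (GRM), with a closed-form power calculator
   for bivariate designs.
4. **Synthetic data.** A generator produces genotypes and item-level
   phenotypes with known latent and genetic ground truth, so every stage is
   verifiable end to end without access to any restricted cohort data.

## The measurement model

All confirmatory models are Gaussian covariance-structure models with
saturated means,

$$\Sigma(\theta) = \Lambda \Phi \Lambda' + \Theta,$$

where $\Lambda$ is the loading pattern, $\Phi$ the latent covariance with
unit diagonal, and $\Theta$ the (diagonal) residual covariance. With
missing data the casewise log-likelihood is accumulated over missing-data
patterns using each pattern's sufficient statistics; this is exact FIML and
is valid under missing-at-random. The likelihood-ratio statistic is
$\chi^2 = 2(\ell_{sat} - \ell_{model})$ against the saturated
mean/covariance model, estimated in closed form for complete data and by EM
otherwise.

Identification is by **unit latent variance** everywhere, including the
second-order factor of the hierarchical model. Two consequences worth
knowing:

* In the hierarchical model the first-order factors keep unit *total*
  variance, so their disturbance variances are derived as
  $1 - \gamma^2$ rather than free; with only two first-order factors the
  two second-order loadings are additionally constrained equal — the
  minimal identifying constraint, since only their product enters the
  implied covariance. With two first-order factors the hierarchical model
  is therefore a reparameterization of the correlated two-factor model
  (with a non-negative implied correlation $\gamma^2$), which is why the
  two fit identically on the same cases; with three or more first-order
  factors the loadings are free.
* The bifactor ("residual") model keeps the general and specific factors
  mutually orthogonal. Three-indicator specific factors can be empirically
  under-identified; an optional equality constraint on specific loadings
  (`constrain_specific = TRUE`) is available but off by default, and
  non-convergence is always reported, never repaired silently.

Binary suicidality items are treated as continuous endogenous variables
under FIML. This is a deliberate modeling approximation (categorical FIML
is not implemented); it mirrors how such items are commonly analysed in
this literature and keeps all models in one estimation framework. The
liability-threshold generator lets users quantify the resulting attenuation
on synthetic data.

The optimizer is quasi-Newton (`nlminb` with a BFGS polish) on the free
parameters with analytic gradients assembled per missing-data pattern;
starting values are scaled by indicator standard deviations and staggered
across latents so symmetric structures (general + specific) do not start at
a saddle point. Non-positive-definite $\Sigma(\theta)$ during the search is
handled by returning a large objective value so the line search backs off.
Convergence requires a relative log-likelihood change below 1e-12 in the
optimizer and a scaled gradient norm below 1e-5 at the solution. Standard
errors come from the inverse observed information (numerical Jacobian of
the analytic gradient). Heywood cases (negative residual variances,
latent correlations beyond 1) are flagged on the fit object.

Factor scores default to the regression (Thomson) method,
$\hat F = \Phi\Lambda'\Sigma^{-1}(y-\mu)$, computed per missing-data
pattern on each case's observed subset; Bartlett scores are available. The
per-latent determinacy $\rho$ is reported: scores carry only $\rho^2$ of a
unit effect on the latent, so downstream GWAS slopes and GREML
heritabilities of factor scores are attenuated by $\rho^2$ relative to the
true latent — the test suite checks this attenuation explicitly rather than
pretending scores are the latent variable.

## Variance components

The GRM is the standard allele-sharing matrix on in-sample allele
frequencies with mean-imputation of missing dosages and per-pair SNP
counts. REML runs in the eigenbasis of the GRM: after one symmetric
eigendecomposition, $V = A\sigma^2_g + I\sigma^2_e$ is diagonal (univariate)
or block-diagonal in 2x2 site matrices (bivariate), so the exact restricted
likelihood, score vector and average-information matrix cost O(n) per
iteration. The update sequence is the standard one: starting values at half
the phenotypic (co)variance, one EM step (univariate; the bivariate
analogue uses a damped first AI step), then average-information updates
with step-halving whenever a step would reduce the likelihood or leave the
parameter space. Variance components are floored at `1e-6 * var(y)` with
active-constraint handling; covariance components are clamped so both the
genetic and residual correlations stay inside (-1, 1), and any clamping is
flagged rather than hidden. Convergence is declared when the restricted
log-likelihood changes by less than 1e-4. Standard errors come from the
inverse average-information matrix; heritabilities and the genetic
correlation get delta-method SEs. Fixed effects are an intercept per trait
because phenotypes are expected to arrive residualized; a covariate matrix
can be passed for standalone use. The bivariate fitter requires complete
trait overlap.

The power calculator uses the closed-form sampling variances that follow
from the equivalence between GREML on unrelateds and Haseman–Elston
regression on off-diagonal GRM entries:
$\mathrm{var}(\hat h^2) = 2/(N^2 v)$ and, for fully overlapping samples,
$$\mathrm{var}(\hat r_G) = \frac{(1 - r_G r_P)^2 + (r_G - r_P)^2}
  {h^2_1 h^2_2 N^2 v},$$
with $v$ the variance of the off-diagonal GRM entries (default `2e-5`, the
conventional genome-wide value for unrelateds; about $1/m$ for $m$
independent SNPs). Power for detecting $r_G \ne 0$ is the upper tail of a
1-df noncentral chi-square with noncentrality $r_G^2/\mathrm{var}(\hat
r_G)$. The test suite validates this variance expression against the
empirical spread of bivariate REML estimates on a small-$n$ design whose
off-diagonal GRM variance is measured directly. Note the strong sensitivity
of this power to its inputs: the noncentrality scales with $h^2_1 h^2_2
N^2$, so halving both heritabilities or the sample size moves power across
almost its whole range; any reported power figure is only interpretable
together with the exact inputs used.

## The synthetic-data generator

The generator is the package's substitute for restricted cohort data and
defines the conditions under which every claim is tested:

* **Genotypes.** SNPs are independent (no LD), allele frequencies uniform
  on a configurable range (default 0.05–0.5), hard calls under
  Hardy–Weinberg equilibrium, monomorphic draws redrawn. GREML with the
  standard GRM is unbiased under this design; what it does **not** emulate
  is LD structure, rare variants, relatedness, or population
  stratification, so passing tests say nothing about LD-dependent biases.
* **Latent genetics.** Per-SNP effects for the causal subset are drawn
  multivariate normal across latent components with the requested genetic
  correlation; genetic values are rescaled so realized heritabilities match
  the generative values exactly, which makes parameter-recovery tests sharp
  at small n.
* **Phenotypes.** Environmental components receive the covariance needed
  for the *total* factor correlation to equal the requested $\Phi$ (or are
  independent when `factor_corr = NULL`, in which case the factor
  correlation is the genetically induced one). Indicators have unit total
  variance with residuals set by their communality. Default loadings are
  0.7 for the two-factor structure and its generative factor correlation is
  0.5; heritabilities default to 0.09 and the genetic correlation to 0.71
  (the study-scale values the pipeline is designed around). The bifactor
  generative loadings are deliberately **heterogeneous** (general 0.45–0.65,
  specific 0.35–0.55): with equal loadings per block the bifactor,
  hierarchical and correlated-factor structures are covariance-equivalent
  (all blocks compound-symmetric) and no fit index could separate them —
  a point worth remembering when interpreting real-data model comparisons.
* **Measurement extras.** Binary suicidality items by liability threshold
  at configurable prevalences; additive age/sex/batch effects with
  configurable coefficients so residualization has signal to remove;
  ancestry PCs computed from the simulated genotypes (eigenvectors of the
  GRM), not simulated independently; MCAR missingness on item columns only.
  All randomness flows from one master seed with per-stage substreams.

The generator does not model the ascertainment of the real cohorts
(oversampling of anxiety/depression and eating-disorder cases), realistic
minor-allele-frequency spectra, item-level Likert response formats, or
missingness that depends on the data; FIML's missing-at-random assumption
is satisfied by construction here, which a real questionnaire cannot
guarantee.

## Simulation sizes and numerical choices

Recovery checks run at n = 2,000 individuals and m = 5,000 SNPs with 25
replicates for the variance-component targets, and n = 20,000 with 25
replicates for the factor-correlation target — sizes chosen so Monte-Carlo
error is a small multiple of the quantities under test while a full run
stays desk-scale. Heritability recovery uses the study-scale generative
value 0.09; the genetic-correlation recovery uses generative rG = 0.71 with
both heritabilities raised to 0.30 because at h2 = 0.09 the per-replicate
SE of rG at this n and m (about 0.4) would swamp the estimate — the raised
heritability tests the same estimator at the same rG with usable precision.
The EFA/CFA split and all seeds are explicit function arguments; identical
seeds reproduce identical datasets, masks and splits bit for bit.

Numerical tie-breaks worth documenting: EFA factors are ordered by
explained variance with signs fixed so each factor's largest loading is
positive; the oblique rotation is quartimin via gradient projection with
column-normalized oblique transforms; `factanal` supplies the ML
extraction. The grid-search REML oracle in the tests uses a 0.005 grid, the
agreement tolerance of the estimator check. Degenerate inputs are errors,
not warnings: rank-deficient covariate designs name the offending columns,
communalities above 1 abort generation, zero surviving SNPs abort GRM
construction.

## Known limitations

* Categorical indicators are modeled as continuous; no WLSMV/ordinal
  estimation.
* The bivariate REML requires complete trait overlap; per-trait missingness
  support is future work.
* No LD-aware GRM, no MAF/LD-stratified components, no BLUP prediction, no
  mixed-model GWAS (the GRM feeds GREML only).
* Profile-likelihood confidence intervals for variance components are not
  provided; SEs are average-information/delta-method and can be optimistic
  near boundaries (clamped estimates are flagged).
* The EFA/CFA split is simple random, unstratified.
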