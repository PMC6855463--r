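---
title: "Genomic selection for clonal crops: models, designs and simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic selection for clonal crops: models, designs and simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`clonalGS` implements a two-stage genomic selection workflow for clonally
propagated crops (cassava being the motivating case), together with the
population-structure-aware cross-validation designs needed to judge how far
genomic predictions travel across germplasm groups. This vignette documents
the models, the tunable parameters, the synthetic-data generator, and the
numerical and design choices a user should know about.

## Stage 1: clonal mixed model and deregression

Plot-level records from multi-environment trials are modelled as

y_ijl = mu + c_i + beta_j + r_l(j) + e_ijl

with clone `c_i ~ N(0, sigma2_c)` random, the location-year combination
`beta_j` fixed, replicate-within-location-year `r_l(j) ~ N(0, sigma2_r)`
random, and residual `e ~ N(0, sigma2_e)`. `fit_clonal_lmm()` fits this by
REML (through lme4) and then solves Henderson's mixed-model equations at the
estimated components to extract clone BLUPs and *exact* prediction error
variances (PEV) from the clone block of the inverted coefficient matrix.
We deliberately do not use lme4's conditional variances: they condition on
the fixed effects, whereas the MME inverse carries the fixed-effect
uncertainty, which matters for deregression. The dense solve is exact and
cheap at the intended scale (up to a few thousand clones).

Deregression removes shrinkage so stage-2 models see an unshrunken
response: reliability `rel_i = 1 - PEV_i / sigma2_c` and
`deregressed_i = BLUP_i / rel_i`. As `rel -> 0` the ratio explodes, so
clones at or below a reliability floor (default 0.05; the source study is
silent, and 0.05 discards only pathologically uninformative clones) are
flagged and excluded from training — never silently dropped.

Phenotypic heritability defaults to the plot basis
`sigma2_c / (sigma2_c + sigma2_r + sigma2_e)`; an entry-mean basis (rep and
residual variances divided by the harmonic mean number of plots per clone)
is available via `basis = "entry_mean"`. The plot basis is the default
because it is the calibration target of the simulator and the denominator
of the prediction-accuracy statistic.

Degenerate layouts are handled explicitly: a replicate factor with a single
level, or with one record per level, is inseparable from the intercept or
the residual and is dropped (its variance reported as zero); location-year
levels without records raise an error naming the aliased levels.

## Marker QC and kernels

QC order is fixed: call-rate filter (default minimum 0.90), modal-dosage
imputation (ties resolved to the heterozygote code 0), then the minor
allele frequency filter (default 0.05, boundary inclusive). Modal
imputation is intentionally naive — the prediction models only need a
complete dosage matrix, and haplotype imputation is out of scope.
Allele frequencies are taken from the post-imputation dosages in a single
deterministic pass.

Two kernels drive the predictions:

* **Additive G** (VanRaden): `G = Zc Zc' / (2 * sum p_i (1 - p_i))` with
  columns centered by `2(p_i - 0.5)`. The literal uncentered cross-product
  is available behind `center = FALSE`, but centering is the default
  because it gives `E[diag(G)] ~ 1` under Hardy-Weinberg and makes the
  RR-BLUP/G-BLUP equivalence exact. A ridge of 1e-6 on the diagonal keeps
  G invertible.
* **Gaussian K**: `K = exp(-h * D / median(D))` with `D` the squared
  Euclidean distance between dosage rows and the median taken over
  off-diagonal entries (the diagonal zeros would only dilute the
  bandwidth). `h = 1` by default. Squared distance is the standard RKHS
  bandwidth convention; plain Euclidean distance is available as a config
  choice.

## Stage 2: five prediction methods

All methods model the deregressed BLUPs as `y_d = mu + genetic + e` on the
training set, exposed through one fitting function `gs_fit(y, ..., method=)`
returning a classed object with `predict`, `coef`, `summary`, `fitted` and
`residuals` methods.

* **G-BLUP / RKHS**: single-kernel mixed models solved by REML. The kernel
  is eigendecomposed once and the restricted likelihood is profiled down
  to the variance ratio `delta = sigma2_e / sigma2_g`, optimised on the
  log scale over [-14, 14] to tolerance 1e-10. Genomic heritability is
  `sigma2_g / (sigma2_g + sigma2_e)`.
* **RR-BLUP**: the same REML fit on `G0 = Zc Zc' / c`, back-transformed to
  marker effects `beta = Zc' V^{-1}(y - mu) / c`; GEBVs equal the G-BLUP
  GEBVs to machine precision, and `sigma2_g = sigma2_beta * c` with
  `c = 2 sum p(1-p)`.
* **BayesB**: Gibbs sampler with a per-marker mixture prior — point mass
  at zero with probability `1 - pi`, and a normal slab whose
  marker-specific variance has a scaled-inverse-chi-square prior (df 5,
  scale solved from an R² = 0.5 heuristic against the response variance).
  `pi` — the prior probability that a marker has a *nonnull* effect — is
  sampled under a mild Beta(2, 2) prior. Integrating the effect out of the
  inclusion odds gives a collapsed, well-mixing sampler.
* **Bayesian LASSO**: the exponential-mixing hierarchy
  (`beta_j ~ N(0, tau_j^2 sigma_e^2)`, `tau_j^2 ~ Exp(lambda^2/2)`,
  `lambda^2 ~ Gamma`), with inverse-Gaussian draws for `1/tau_j^2` and the
  Gamma hyperprior's mode matched to the same R² heuristic. The posterior
  mean `lambda` is reported.

MCMC defaults are 10 000 iterations, 2 000 burn-in, thinning 10. The
samplers are compiled (Rcpp) but use R's RNG, so a fixed seed makes runs
bit-reproducible. Retained chains of the residual variance and the genetic
variance (variance of `Z beta` per retained sample) feed the Raftery-Lewis
run-length diagnostic (`raftery_lewis()`, computed through coda), whose
minimum-chain-length constant for the defaults q = 0.025, r = 0.005,
s = 0.95 is `ceiling(qnorm(0.975)^2 * q(1-q) / r^2) = 3746`.

Out-of-sample prediction: marker methods use `Z_new beta` with the training
centering; kernel methods project through the relationship matrix,
`K[new, train] K[train, train]^{-1} g_train` (ridge 1e-8 for stability).
Predicting the training set returns the fitted GEBVs.

A practical note on the kernels: in a *panmictic* panel the pairwise
squared distances concentrate around their median, the Gaussian kernel is
then locally linear in D, and RKHS is empirically indistinguishable from
G-BLUP even when non-additive variance is present. The kernel's extra
capacity only engages when relatedness varies — families, clusters,
duplicated clones — which is exactly the situation of a structured
germplasm collection.

## Population structure and cross-validation designs

`dapc_fit()` performs discriminant analysis of principal components:
PCA of the centered dosages (or the eigendecomposition of a kinship
matrix), retaining axes to 85% cumulative variance; k-means on the
retained PCs (25 restarts, seeded; k chosen by the conventional BIC
`n log(WSS/n) + k log(n)` over 2..10 when `k = "auto"`); then linear
discriminant analysis of the k-means labels, keeping discriminant
functions to 94% of discriminant variance. Final labels are
nearest-centroid assignments in that space with ties to the lowest
cluster index. The two variance thresholds are independent knobs because
their interaction in the source methodology is ambiguous.

Four CV designs (`make_cv_plan()`):

* **S1** random k-fold over all clones (5 folds x 3 replicates);
* **S2** folds within each cluster (3 x 3);
* **S3** leave-cluster-out: validation is a fold-part of one cluster,
  training the matching fold-parts of all other clusters. The source
  description is ambiguous between fold-parts and full clusters; the
  fold-part version is the default (it equalises training sizes against
  S4) and `full_training = TRUE` gives the other reading;
* **S4** as S3 with one additional cluster removed from training, every
  choice of absent cluster enumerated.

Folds are simple random within the relevant unit, with no stratification.
A plan is seed-locked, and `run_cv()` serves identical train/validation
sets to every method. Per fold it computes predictive ability
`r = cor(GEBV_val, BLUP_val)` (validation uses BLUPs, not deregressed
BLUPs), bias as the regression slope `cov(GEBV_train, y_train)/var(GEBV_train)`
(slope > 1 means effects were underestimated; the literal sd-denominator
variant is behind `denominator = "sd"`), accuracy `r / h_phen` with
`h_phen` the square root of the phenotypic heritability, and the genomic
heritability of the training fit. Folds with fewer than 3 usable
validation clones return NA metrics with a warning.

## Method comparison

`deviance_analysis()` fits, by ML, `y = s + m + e` (and `y = s + p + m + e`
when a population-structure interaction applies), with `s` the CV run
(replicate x fold), `p` the validation-by-absent-cluster interaction, `m`
the fixed method effect. Terms are tested by likelihood-ratio tests:
methods on `n_methods - 1` df, variance components on the naive 1-df
chi-square — not the boundary-corrected mixture, which makes the random-term
tests conservative-looking but matches the 1-df convention of the source
tables; users needing calibrated variance-component p-values should halve
them. The per-fold table is used directly (rather than replicate means):
more residual degrees of freedom, and `s` absorbs the run effect.

Tukey mean separation is computed on the balanced CV layout from the
studentized range, with a compact letter display built from contiguous
runs of mutually non-separated sorted means (exact under the equal-SE
balance that the shared plan guarantees). Reported dispersions are the SD
of fold-level values per method.

Cohen's kappa selection coincidence: at each selection proportion SP the
top `ceiling(SP * n)` clones by each GEBV vector are coded 1/0 and
`kappa = (p_o - p_e)/(1 - p_e)` with `p_e` from the marginal selection
rates. Ceiling reproduces the fractional SPs that integer selection counts
produce; GEBV ties break by id order so curves are deterministic.

## The synthetic-data generator

`simulate_structured_genotypes()` draws per-cluster allele frequencies
from a Balding-Nichols distribution (Beta with parameters `p(1-F)/F`,
`(1-p)(1-F)/F`) around ancestral frequencies uniform on
[maf_floor, 1 - maf_floor], then Hardy-Weinberg genotypes within cluster,
redrawing markers whose realized MAF falls under the floor, then inserting
missing calls uniformly. Markers are spread evenly over chromosomes with
ordered positions. The default world mirrors the motivating study: five
clusters of 162/175/185/155/211 clones, 18 chromosomes, MAF floor 0.05,
call missingness 10%. Divergence defaults to fst 0.15 — "moderate but
clearly clustered", chosen once as a realistic stand-in since the study
reports clusters but no Fst.

`simulate_phenotypes()` samples additive effects at `n_qtl` markers;
non-additive variance is dominance deviations at the QTL plus
additive-by-additive effects on random QTL pairs, each component rescaled
so the non-additive share matches the configuration (split equally between
the two components). Trials follow the configured layouts: RCBD with all
clones per replicate block, or augmented designs where only check clones
repeat across blocks and test entries are randomized uniformly to blocks.
Replicate and residual variances are solved so the *plot-basis additive
heritability* hits `h2_additive` (defaults 0.34, the low end of the
study's trait range); the non-genetic variance splits 20% replicate / 80%
residual by default, and location-year effects are drawn with variance
half the non-genetic total, so the `h2 = 1` limit is exactly noise-free.
One caveat: in a single-block trial the replicate effect is a constant
absorbed by the trial mean, so calibration targets that rely on the rep
stratum should set `rep_var_fraction = 0`.

What the generator does *not* emulate: linkage disequilibrium (markers are
exchangeable given their frequencies), genotyping-error structure, and
trait correlations. Consequences worth knowing: without LD the effective
number of independent genome segments equals the marker count, which makes
kernel-REML heritability estimates noisier than on real GBS data
(sampling SD ~ sqrt(2m)/n for an unstructured panel), and it removes the
LD-driven part of the RKHS advantage. It also flattens the contrast
between *within-cluster* and *leave-cluster-out* validation: with
exchangeable markers, a small same-cluster training set has no
effective-dimensionality advantage over an equally sized other-cluster
one, so only the drop from random CV to either structured design is a
stable desk-scale signal. A green parameter-recovery test here therefore
says the estimators are correct, not that real-data precision will match.

## Numerical choices, in one place

* REML (kernels): eigendecomposition + profiled ratio, log-scale search
  in [-14, 14], tolerance 1e-10.
* Stage-1 MME: dense solve with a 1e-8 floor on the clone penalty so the
  zero-residual limit stays invertible.
* G ridge 1e-6; kernel-prediction solve ridge 1e-8.
* Gibbs: slab df 5, R² heuristic 0.5, Beta(2, 2) on pi, Gamma shape 1.1
  on lambda²; residual prior df 5 scaled to (1 - R²) var(y).
* k-means: 25 restarts, up to 10 re-seeded retries on empty clusters.
* Ties: imputation mode ties -> heterozygote; nearest-centroid ties ->
  lowest cluster index; GEBV ties in selection -> id order.
* Seeds are explicit arguments everywhere; the pipeline derives fixed
  per-stage child seeds from the master seed so stages can be rerun in
  isolation.

## Known limitations

Single-trait stage 1 only; no spatial field-trend correction; no LD-aware
simulation or haplotype imputation; the deviance analysis assumes the
balanced layout its own CV plans produce; BayesA/BayesC-pi variants and
multi-kernel RKHS averaging are out of scope.
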