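---
title: "Methods: phylogenetic community structure and its spatial determinants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phylogenetic community structure and its spatial determinants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, eval = FALSE}
library(phylospat)
```

This vignette is the package's own account of its statistical machinery:
the models, the conventions adopted where the literature allows several,
the tunable parameters and their defaults, what the synthetic-data
generator does and does not emulate, and the numerical choices that make
the results reproducible.

## 1. The question

Communities assembled by environmental filtering are expected to contain
species more closely related than chance (phylogenetic clustering), while
competitive exclusion of close relatives produces overdispersion. The
pipeline quantifies this per site, contrasts it across bedrock types,
and then asks — with spatial dependence between neighbouring sites
modelled explicitly — which environmental factors predict species
richness and phylogenetic structure.

## 2. Diversity metrics

For a site holding taxa set $S$ on a rooted tree with branch lengths:

* **Faith's PD**: total branch length of the minimal subtree spanning
  $S$. Two conventions exist; the default here is **root-inclusive**
  (the spanning subtree is connected to the tree root), which is the
  convention of the classic community-phylogenetics software lineage and
  makes single-species PD equal to the root-to-tip depth. The MRCA-rooted
  (exclusive) variant is available via `include_root = FALSE`. The choice
  shifts PD by the stem length above the MRCA; SES values are much less
  sensitive because the null uses the same convention.
* **MPD**: mean cophenetic distance over the $\binom{|S|}{2}$ unordered
  pairs. **MNTD**: mean over $i \in S$ of $\min_{j \ne i} d(i,j)$.
  Both are abundance-**unweighted**: the pipeline analyses occurrences,
  and abundance weighting is deliberately not implemented.

Cophenetic distances are path sums of branch lengths; zero-length
branches (e.g. polytomy grafts from megatree construction) are legal,
negative ones are rejected at parse time. The tests verify the distance
matrix against an independent per-pair LCA-walk oracle on random trees.

## 3. The randomization null and the SES indices

"999 random combinations" is implemented as the **taxa-label null**:
each draw samples, uniformly without replacement, a species set of the
observed richness from the species pool. This preserves richness exactly
and is equivalent to shuffling tip labels on the distance matrix. The
pool defaults to the union of species over all analysed sites and is
configurable; other nulls (frequency-preserving, independent swap) are
out of scope and the chosen scheme is recorded in every output's
metadata header rather than asserted as the only defensible choice.

The indices are

$$\mathrm{PDI} = \frac{PD_{obs} - \overline{PD}_{null}}{\sigma(PD_{null})},
\qquad
\mathrm{NRI} = -\frac{MPD_{obs} - \overline{MPD}_{null}}{\sigma(MPD_{null})},
\qquad
\mathrm{NTI} = -\frac{MNTD_{obs} - \overline{MNTD}_{null}}{\sigma(MNTD_{null})}.$$

The leading minus on NRI/NTI makes **positive values = clustering**.
For classification, PDI's sign is read inversely (a PD deficit relative
to the null indicates clustering). When the null has zero spread
($\sigma < 10^{-12}$; e.g. the community equals the pool, or a star tree
makes every subset equivalent) the SES is flagged *undefined* and
propagates to downstream regressions as missing — never as $\pm\infty$.

Within a site the three indices are computed against the **same** null
assemblages (one shared set of draws), which is faster and internally
consistent. Reproducibility contract: one master seed; each site's null
stream is derived from the seed and the site index
(`derive_seed(seed, site)`), so results are independent of evaluation
order and bit-identical across reruns.

Calibration property (verified in the tests): on neutrally assembled
communities the SES indices are approximately standard normal — mean
within ±0.15 of 0 and sd within [0.8, 1.2] over 500 sites at 999 nulls.

## 4. Preprocessing

* **Hellinger transform** $\sqrt{x_{sj}/x_{s\cdot}}$ applied to the
  site × species matrix (the standard target of the transform);
  transformed rows have unit Euclidean norm. The species-richness
  response used in regressions is always the raw row count — the
  transform never alters it.
* **Range normalization** $(x-\min)/(\max-\min)$ for elevation, slope,
  aspect and climate predictors; errors on constant vectors rather than
  silently producing NaN. Aspect enters as supplied (no circular
  transform by default; a northness/eastness option was considered and
  rejected as an un-asked-for change of variable).
* **Collinearity screen**: greedy scan in declared column order; a
  column correlated beyond the threshold (default 0.95) with any
  already-retained column is dropped and logged. The screen uses
  $|r|$ by default — a signed rule would wave through $r = -0.99$ —
  with `absolute = FALSE` available since the signed reading of
  "correlation greater than 0.95" is also defensible. Zero-variance
  columns are removed (with a warning) before any correlation is
  computed, since $r$ is undefined for them.

## 5. Group contrasts and regression

* **Welch t** (unequal variances, Satterthwaite df) is the default for
  bedrock contrasts, with a pooled-variance flag; Welch is the safer
  default when group sizes and variances differ, as they do across
  bedrock classes. Two constant equal samples return $t=0, p=1$.
  Stars: \* $p<0.05$, \*\* $p<0.01$, \*\*\* $p<0.001$.
* **Stepwise-AIC Gaussian GLM** for all four responses (SR, NRI, NTI,
  PDI): identity link, both-direction search, each step taking the
  single add/remove that most lowers AIC and stopping at a local
  minimum. The bedrock factor enters and leaves as a block of dummies
  with granite as the reference level. Perfectly collinear candidates
  are excluded with a warning before the search (their coefficients are
  not estimable). AIC counts every estimated parameter including the
  error variance, so adding a parameter with zero likelihood gain
  raises AIC by exactly 2 — a property the tests assert directly.
  AIC ties are resolved by the declared candidate order.

## 6. Spatial stage

* **Weights**: k-nearest neighbours, default $k=4$, row-standardized.
  The neighbour scheme is a modelling choice, not something the data
  dictate; it is recorded in the output metadata. Coordinates that look
  like lon/lat (within ±180/±90) get great-circle distances on a
  spherical WGS84 approximation via `geosphere`; anything else is
  planar Euclidean. Distance ties, including duplicate coordinates
  (warned), break by site order.
* **Moran's I** with permutation expectation $-1/(n-1)$ and the
  standard randomization-moment variance (the kurtosis-corrected
  formula); p-values from a two-sided normal approximation. The tests
  check the observed statistic against `ape::Moran.I` and the variance
  against a brute-force permutation distribution.
* **Spatial-lag model** $y = \rho W y + X\beta + \varepsilon$, fitted by
  maximum likelihood with the log-likelihood concentrated over $\rho$:
  $\log|I - \rho W|$ is evaluated as $\sum_i \log(1-\rho\lambda_i)$ from
  the (possibly complex; conjugate pairs sum real) eigenvalues of $W$,
  and the search is confined to $(1/\lambda_{\min}, 1/\lambda_{\max})$
  of the real parts, shrunk by $10^{-6}$ of its width to keep the
  log-determinant finite. $\hat\beta$ follows from the two auxiliary
  OLS fits of $y$ and $Wy$ on $X$. Standard errors come from the
  inverse observed information (numerical Hessian over
  $(\rho, \beta, \log\sigma^2)$), with a conditional-on-$\rho$ fallback
  if the Hessian is not positive definite; coefficients are tested by
  asymptotic z. AIC $= 2k - 2\log L$ with $k = p + 2$ ($\beta$s, $\rho$,
  $\sigma^2$). A spatial-**error** variant
  ($u = \lambda W u + \varepsilon$) is available by flag; the lag model
  is the default because the scientific story — richness spilling
  between neighbouring communities through dispersal — is a lag
  mechanism. With an all-zero $W$ the fit collapses to OLS exactly,
  with $\rho$ pinned at 0.
* **"% of variation explained"** is the Nagelkerke pseudo-R²
  $1 - \exp\{(2/n)(\log L_0 - \log L_1)\}$ against the intercept-only
  OLS null, clamped to $[0,1]$ (a warning accompanies a clamp at 0,
  which only occurs within numerical noise of $L_0 = L_1$). The squared
  observed–fitted correlation is available by flag; the two can differ
  by several points, which is why the choice is explicit metadata.

In the pipeline each response's SAR uses the predictors selected by its
stepwise GLM — selection under independence, then refitting with the
spatial term, which keeps the two stages' models comparable.

## 7. The synthetic study system

The generator produces data with the statistical structure the analysis
assumes, at the scale of the motivating field system:

* **Tree**: pure-birth (Yule) with exponential epoch waiting times
  ($\mathrm{Exp}(k\lambda)$ at $k$ lineages, uniform lineage split, one
  final epoch after reaching $n$), giving closed-form expectations the
  tests verify: total length $(n-1)/\lambda$, height $(H_n-1)/\lambda$.
  Default pool 594 species.
* **Assembly**: *neutral* (uniform subsets), *filtering* (a random
  focal tip; others included with weight $e^{-d/\tau}$), *repulsion*
  (sequential selection with weight proportional to the minimum
  distance to the already-selected set). The kernels are exponential in
  cophenetic distance — the minimal mechanisms that produce the
  clustered and overdispersed signatures; no claim is made that real
  assembly follows them. $\tau$ is in branch-length units; the study
  generator scales it by the tree's mean pairwise distance and tightens
  it with elevation, so filtering strengthens upslope.
* **Landscape**: 75 sites in a ~10 × 7 km lon/lat window near 22.5° N,
  114.5° E; a dome-shaped elevation surface spanning 0–869.7 m; five
  contiguous bedrock patches (nearest-of-five-centres mosaic); a
  climate block driven by shared temperature and precipitation factors
  and containing a built-in near-duplicate pair (MAT/MTWQ, $|r|>0.95$)
  so the collinearity screen always has work to do; responses generated
  as $y = (I-\rho W)^{-1}(X\beta + \varepsilon)$ with default
  $\rho = 0.4$ and noise sd 1.

What it does **not** emulate: real floristic composition, trait
evolution, abundance dynamics, measured bioclimatic fields, or soil
chemistry. Passing tests therefore demonstrate that the estimators
recover known structure of the kinds the analysis assumes — calibrated
nulls, regime signs, $\rho$ and $\beta$ recovery — not that any
particular field inference is correct.

## 8. Problem sizes and numerical choices

Test and demonstration runs use deliberately chosen sizes: a 128-tip
pool and 500 sites for SES calibration (enough for the ±0.15 mean band
at 999 nulls), 200 sites per assembly regime, 100 landscapes of $n=200$
for $\rho$ recovery, and the full 75 × 594 system for the end-to-end
pipeline. Metric comparisons use $10^{-9}$ absolute tolerance;
$\rho$ optimization tolerance is $10^{-9}$ on a unit-scale interval;
null-sd degeneracy threshold is $10^{-12}$. Known limitations: the
normal approximation for Moran's I p-values is rough below $n \approx
20$; SES undefinedness is common on very small pools; and stepwise
selection inherits the usual post-selection-inference caveats — the
reported GLM p-values are conditional on the selected model.
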