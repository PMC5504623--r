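---
title: "Detecting chromosomal regions of correlated expression with corrseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting chromosomal regions of correlated expression with corrseg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The statistical model

`corrseg` looks for blocks of adjacent genes whose expression is more
strongly correlated across patients than the chromosomal baseline. Let
$Y$ be the $n \times p$ matrix of expression for the $p$ ordered genes
of one chromosome in $n$ patients. After per-gene centering and scaling
(see *Conventions* below), patient profiles $Y_i$ are modelled as
i.i.d. Gaussian with a block-diagonal correlation matrix $G$: the genes
split into $K$ contiguous regions with boundaries
$0 = \tau_0 < \tau_1 < \dots < \tau_K = p$; genes in different regions
are independent, and all gene pairs inside region $k$ (of length $p_k$)
share one correlation $\rho_k$ (compound symmetry). Equivalently, each
gene in region $k$ is a shared patient-level region effect $U_{ik}$
plus independent noise, with
$\mathrm{Var}(U_{ik})/\mathrm{Var}(Y_{ij}) = \rho_k$ — the natural
picture for a block of genes driven by one shared regulatory event.

The model is a deliberate simplification: real regions can contain
an unexpressed or oppositely regulated gene, and correlation need not
be constant within a block. The simulations below probe the second
point; the first is mitigated by removing non-expressed and
non-varying genes before analysis (`drop_degenerate_genes()`).

**Conventions.** Standardization divides by the standard deviation
with denominator $n$, not $n-1$, so the empirical Gram matrix
$\hat G = Y^\top Y / n$ has exact unit diagonal. All logarithms are
natural. These two conventions make the closed-form likelihood and
the identity $T_k = n\,\lambda(p_k, \hat\rho_k)$ below hold exactly
rather than up to $O(1/n)$ factors.

## Exact segmentation

For a region with fixed boundaries, the ML estimate of $\rho_k$ is the
mean off-diagonal entry of the region's block of $\hat G$, and the
maximized likelihood has the closed form
$$-2\hat{\mathcal L}_k = n\left[p_k + (p_k-1)\log(1-\hat\rho_k) +
\log(1+(p_k-1)\hat\rho_k)\right].$$
The total $-2\hat{\mathcal L}$ is additive over regions, so for each
$K$ the globally optimal boundaries are found by dynamic programming in
$O(Kp^2)$; per-patient prefix sums give each candidate segment's Gram
sum in $O(n)$. Cost ties are broken toward the smallest last
change-point, recursively, so results are deterministic.

Numerical guardrails: $\hat\rho_k$ is clamped into
$[-1/(p_k-1) + 10^{-8},\ 1 - 10^{-8}]$, since the likelihood is
undefined at the boundary and degenerate blocks (e.g. duplicated
columns) reach it; single-gene regions take $\hat\rho = 0$ and cost
$n$ by convention.

## Choosing the number of regions

For $K = 1,\dots,K_{\max}$ the maximal log-likelihoods $L_K$ are
normalized as
$$\tilde L_K = \frac{L_{K_{\max}} - L_K}{L_{K_{\max}} - L_1}
(\tilde K_{K_{\max}} - \tilde K_1) + 1, \qquad
\tilde K_j = 5j + 2j\log(p/j),$$
and $\hat K$ is chosen where $\tilde L$ shows a slope change larger
than a threshold $S$. Two design points deserve a note.

* *Where the slope change is measured.* The slope change **at** $K$ is
  the centered second difference
  $(\tilde L_{K-1} - \tilde L_K) - (\tilde L_K - \tilde L_{K+1})$.
  An off-by-one reading (indexing the forward second difference by its
  left end) systematically under-segments by one region — on easy
  simulated data with four planted regions it selects 8 segments where
  the true layout needs 9 — so `select_K()` uses the centered form.
* *Which qualifying K to keep.* Among all $K$ whose slope change
  exceeds $S$, the default keeps the largest (the rule used by the
  slope-heuristic literature this criterion follows); the smallest is
  available via `rule = "smallest"` for users who prefer the most
  parsimonious reading. If no $K$ qualifies, $\hat K = 1$.

$S$ defaults to 0.7 and is exposed everywhere (including a scan helper,
`sensitivity_scan_S()`, that reuses the dynamic program across the
grid). $K_{\max}$ defaults to $\min(\lfloor p/2\rfloor, 40)$: regions
of practical interest have at least a few genes, and the cost of the
grid is bounded; the default is user-configurable and a warning is
raised when $\hat K = K_{\max}$, which suggests raising it.

Two caveats, both verified empirically and kept as documented
behavior. First, $L_K$ is *not* guaranteed to be non-decreasing in
$K$: the block models are not nested (splitting a block discards its
cross-half correlation terms — for $p = 2$, $-2L_1 = n[2 +
\log(1-\hat\rho^2)] \le 2n = -2L_2$ always), so `select_K()` tolerates
local decreases and only refuses a globally flat profile. Second, on
fully independent genes ($\rho_0 = 0$ exactly) the normalization
multiplies noise curvature by the penalty span and the heuristic
over-segments; the exact test stage still keeps false calls rare, and
with any realistic positive background the flat-span guard returns
$\hat K = 1$. Tests assert both behaviors.

## Exact significance test

Background correlation between adjacent genes exists even without any
regional co-regulation, so each region is tested against it:
$H_0: \rho_k = \rho_0$ versus $H_1: \rho_k > \rho_0$, using
$$T_k = \sum_i \left(\bar Y^{(k)}_{i\cdot} - \bar Y^{(k)}_{\cdot\cdot}\right)^2,
\qquad T_k \sim \lambda(p_k, \rho_k)\,\chi^2_{n-1},\qquad
\lambda(p,\rho) = \frac{1 + (p-1)\rho}{p},$$
which yields exact p-values with no resampling, and the analytic power
$$Po(n, p_0, \rho) = \Pr\left\{Z > \frac{\lambda(p_0,\rho_0)}
{\lambda(p_0,\rho)}\, q_{n-1,1-\alpha}\right\},\quad Z \sim \chi^2_{n-1}.$$
At $\rho = \rho_0$ the power equals $\alpha$ exactly.

$\rho_0$ is estimated per chromosome as
$|\mathrm{median}_j\ \mathrm{corr}(Y^{j-1}, Y^j)|$ over adjacent gene
pairs — implemented literally as the absolute value of the median (not
the median of absolute values). As long as most adjacent pairs carry
only background correlation the median ignores the correlated regions;
its residual upward bias costs power but can only make the test more
conservative, never anti-conservative (monotonicity of the p-value in
$\rho_0$; asserted in the tests). P-values are adjusted genome-wide
across all regions of all chromosomes, BH-FDR by default with
Bonferroni as an option, at level $\alpha = 0.05$.

One caution: regions are tested after being *selected* by the
segmentation, so on degenerate inputs (the $\rho_0 = 0$
over-segmentation case above) the selection favors chance-correlated
blocks and a few percent of them can reach significance. With a
realistic positive background the upward-biased $\hat\rho_0$
counteracts this in practice.

## Copy-number correction

To find regions whose correlation is *not* explained by copy-number
variation, expression is first regressed on a per-gene, per-patient
copy-number covariate $x_{ij}$:
$Y_{ij} = \beta_0 + \beta_1 x_{ij} + \epsilon_{ij}$, with the
residuals $\tilde Y_{ij}$ carried forward. The covariate is built by
segmenting each patient's SNP probe signal into piecewise-constant
means (exact least-squares DP; the number of segments is chosen by the
same slope heuristic applied to the Gaussian least-squares
log-likelihood $-(m/2)\log(\mathrm{RSS}_K/m)$, and a perfect one-segment
fit short-circuits the selection), then transferring the fitted means
to genes: the fitted mean of the single overlapping probe, the average
over several overlapping probes, or — for probe-less genes — linear
interpolation of the flanking probes' *fitted* values at the gene
interval midpoint, with nearest-value extrapolation beyond the
outermost probe. Interpolating fitted rather than raw probe values
follows from the covariate being defined by the segment means;
midpoint abscissa and nearest-value extrapolation are our choices where
only "linear interpolation" is specified.

The regression itself is OLS — valid under independence across patients
only, which is all the model assumes. Whether $(\beta_0, \beta_1)$
should be shared is genuinely open: the default fits one pair per
chromosome pooling all patient-gene pairs (`mode = "global"`, matching
the single-coefficient regression written above), with a per-gene
alternative (`mode = "per-gene"`) for effects that differ across genes;
neither is claimed canonical. RNA-seq zeros can either enter the fit
(`zero_policy = "keep"`, default) or be excluded with their residuals
set to 0 (`"drop-zero"`), two options that gave similar results in our
checks. After correction the residuals are re-centered and re-scaled
per gene before segmentation — the model requires standardized input,
and the correction changes per-gene scales — even though one could
also segment the raw residuals; this re-standardization is our choice.
A zero-variance covariate degenerates to centering (with a warning in
global mode), so an all-zero covariate reproduces the uncorrected
standardized signal exactly.

The package does not implement a count-data (negative-binomial GLM /
Pearson-residual) variant of the correction; `log(1+x)`-transformed
counts are the supported route.

## Simulation generators and what they show

`simulate_expression()` draws i.i.d. Gaussian profiles with, per
chromosome, a shared factor giving every gene pair the background
correlation $\rho_0$, and per planted region an additional block
factor raising within-block correlation to $\rho_1$ (the exact
between-background-and-block structure is underdetermined by the
pairwise description; the shared-factor construction reproduces the
stated marginal correlations while keeping the covariance positive
definite). Three designs are packaged:

* the *easy case*: one chromosome of 500 genes, four regions of
  lengths 5/10/20/40 at genes 101/201/301/401 (fixed, well-separated
  placements chosen for determinism), $\rho_0 \in \{0.08, 0.18, 0.28\}$,
  $\rho_1$ from 0.3 to 0.9, $n = 50$ or 100;
* a *genome-shaped* design: 22 chromosomes with per-chromosome gene
  counts, region layouts and $\rho_0$ drawn once from 0.05–0.28 and
  shipped as a synthetic configuration file
  (`extdata/scenario2_design.tsv`);
* a *variable-correlation* variant: within-region correlation matrices
  drawn from a Wishart with scale matrix having 0.5 off-diagonal and
  $\nu = p_k 2^\beta$ degrees of freedom, rescaled to unit diagonal
  (correlation), so variability decreases as $\beta$ grows. The drawn
  matrix is re-anchored on the background as
  $C = (R - \rho_0)/(1 - \rho_0)$ and eigenvalue-clipped to the
  nearest correlation matrix when the subtraction breaks positive
  definiteness.

Evaluation is at two levels. Gene level: a gene is predicted positive
when its region's adjusted p-value passes the threshold; TPR/FPR over
genes. Region level (stricter): genes are classified TP/FP/TN/FN,
maximal runs of equal status are merged into status regions, and rates
are computed on region counts, so boundary errors create FP/FN regions.
TPR(α)/FPR(α) are tabulated on a logarithmic grid of 50 levels from
$10^{-8}$ to 1; the AUC, however, integrates the ROC traced at the
*observed* adjusted p-values (augmented with (0,0) and (1,1)), because
only that construction is invariant under monotone transformations of
the p-values — a property the test suite asserts. Chromosomes with no
true regions report region-level TPR as `NA` rather than 0.

These generators emulate exchangeable Gaussian correlation with known
block boundaries; they do not emulate heavy-tailed expression,
outlying samples, missing values, genes interrupting a region, or
correlation decaying with genomic distance — so passing simulation
benchmarks demonstrates correctness of the machinery under the model,
not robustness to all features of real cohorts.

## Problem sizes used by the checks

The packaged checks use desk-scale versions of the study conditions:
10,000 replicates for null calibration and for each point of the
analytic-vs-Monte-Carlo power grid ($\rho \in \{0.3, 0.5, 0.7\}$,
$p_0 \in \{3, 5, 10\}$, $n = 100$, $\rho_0 = 0.15$); 100 random
instances (with $p \le 12$, $K \le 4$) for the exhaustive-enumeration
check of the dynamic program; 20 replicates of the easy-case benchmark
at $n = 100$, $\rho_0 = 0.08$, $\rho_1 = 0.5$ (mean gene-level AUC
above 0.9, region-level below gene-level); and 20 replicates of a
60-gene, 60-patient cohort whose only correlated region is induced by
a simulated copy-number gain, for the correction check.

## Known limitations

* Missing expression values are rejected rather than imputed.
* The compound-symmetry block model ignores within-region correlation
  decay; simulations with Wishart-perturbed blocks suggest only the
  mean within-block correlation matters, but strongly structured
  blocks may still be split or missed.
* The slope heuristic needs $K_{\max} \ge 3$ and behaves poorly on
  fully independent genes (see above); chromosomes with fewer than a
  handful of genes fall back to $\hat K = 1$.
* Selection precedes testing, so region p-values are exact for
  pre-specified boundaries but mildly optimistic for adaptively chosen
  ones; the conservative background estimate is the practical
  counterweight.
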