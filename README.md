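# corrseg

Detection of chromosomal regions of correlated gene expression.

Neighboring genes along a chromosome are often co-expressed: a shared
copy-number change, a common epigenetic mark (e.g. DNA methylation over a
gene cluster) or a shared transcription factor can raise the expression
correlation of a whole block of adjacent genes well above the baseline
chromosomal correlation. `corrseg` finds such blocks directly from an
expression matrix, for cancer cohorts and other bulk (or pseudo-bulk)
transcriptomic datasets.

## Model and method

Patient expression profiles over the `p` ordered genes of a chromosome are
modelled as i.i.d. centered, standardized Gaussian vectors with a
block-diagonal correlation matrix `G`: the genes split into `K` contiguous
regions, genes in different regions are independent, and genes within
region `k` share one pairwise correlation `rho_k` (compound symmetry /
exchangeable correlation). The package:

1. **Segments** the correlation matrix exactly. For fixed boundaries the
   ML estimate of `rho_k` is the mean off-diagonal entry of the region's
   empirical Gram matrix `G-hat = t(Y) Y / n`, and the maximized
   likelihood has the closed form
   `-2 L-hat_k = n [ p_k + (p_k - 1) log(1 - rho-hat_k) + log(1 + (p_k - 1) rho-hat_k) ]`,
   so the total likelihood is additive over regions and the globally
   optimal boundaries for every `K` are found by dynamic programming in
   `O(K p^2)`.
2. **Chooses `K`** with a slope heuristic: the per-`K` maximal
   log-likelihoods are normalized against the penalty
   `K~_j = 5 j + 2 j log(p / j)` and the selected `K` is the largest one
   whose normalized curve shows a slope change above a threshold `S`
   (default 0.7).
3. **Tests** each region against the background correlation `rho_0` of
   its chromosome with the statistic
   `T_k = sum_i (Ybar_ik - Ybar_k)^2` (the squared, centered
   within-region patient means). Under H0 `T_k` is exactly
   `lambda(p_k, rho_0) * chi-square(n - 1)` with
   `lambda(p, rho) = (1 + (p - 1) rho) / p`, giving exact p-values, an
   analytic power function, and BH/Bonferroni genome-wide adjustment.
   `rho_0` is estimated per chromosome as the absolute median
   correlation of adjacent gene pairs.
4. Optionally **corrects for copy-number variation** first: per-patient
   SNP profiles are segmented into piecewise-constant means (exact
   least-squares DP, same selection rule), mapped to genes (averaging or
   interpolating the fitted segment means), and regressed out of the
   (log-scale) expression; the residuals are re-standardized and
   segmented as above, so the remaining regions are the ones *not*
   explained by CNV.

Simulation generators (exchangeable blocks, genome-shaped designs,
Wishart-perturbed within-block correlation) and gene-/region-level
TPR/FPR/AUC evaluation are included.

## Worked example

Simulate the easy single-chromosome design (500 genes, four planted
regions of 5/10/20/40 genes at correlation 0.5 over a 0.08 background,
100 patients) and run the full detection chain:

```r
library(corrseg)
spec <- sim_spec(scenario1_design(rho0 = 0.08), n = 100, rho1 = 0.5)
sim  <- simulate_expression(spec, seed = 1)
rt   <- detect_correlated_regions(sim$expr)
rt[rt$significant, c("chromosome","start","end","p_k","rho","rho0","p_adj")]
#>    chromosome start end p_k   rho  rho0    p_adj
#> 2        chr1   201 210  10 0.481 0.089 1.27e-20
#> 11       chr1   301 320  20 0.480 0.089 7.73e-33
#> 19       chr1   401 440  40 0.456 0.089 7.68e-40
```

The three larger planted regions are recovered at their exact
boundaries, with within-region correlation estimates near the simulated
0.5 and an estimated background near the simulated 0.08; at this
correlation level the 5-gene region is on the edge of detectability, as
the analytic power function predicts — a 3-gene region needs correlation
about 0.7 to be detected reliably:

```r
region_power(n = 100, p0 = 3, rho = 0.7, rho0 = 0.15, alpha = 0.05)
#> [1] 0.9946726
```

File-based analyses (`run_pipeline()`, YAML-configurable) and a thin
command-line interface (`inst/cli/corrseg.R`, subcommands `segment`,
`test`, `correct`, `run`, `simulate`, `evaluate`, `power`, `scan-s`)
wrap the same functions.

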