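#' Variance scaling of a within-region patient mean
#'
#' \eqn{\lambda(p, \rho) = (1 + (p-1)\rho)/p}: the variance of the mean
#' of p standardized, pairwise rho-correlated gene expressions. Scales
#' the chi-square null distribution of the region statistic.
#'
#' @param p region width in genes.
#' @param rho common pairwise correlation.
#' @return Numeric, vectorized over both arguments.
#' @export
lambda_cs <- function(p, rho) (1 + (p - 1) * rho) / p

#' Robust background correlation of a chromosome
#'
#' Absolute value of the median Pearson correlation over all adjacent
#' gene pairs (j - 1, j). Provided most adjacent pairs carry only the
#' baseline chromosomal correlation, the median ignores the few pairs
#' that fall inside highly correlated regions, so the estimate is robust
#' to the presence of such regions (at the price of a slight upward bias
#' that lowers power but never inflates the type-I error).
#'
#' @param Y a single-chromosome standardized `expr_matrix` or a numeric
#'   matrix (n patients x p genes), p >= 2.
#' @return Object of class `corrseg_rho0`: list with `rho0`, `n_pairs`
#'   and `chromosome` (label, or `NA` for plain matrices).
#' @export
estimate_rho0 <- function(Y) {
  chrom <- NA_character_
  if (inherits(Y, "expr_matrix")) {
    if (length(chromosomes(Y)) > 1)
      stop("estimate_rho0 operates on a single chromosome")
    chrom <- chromosomes(Y)
    Y <- Y$values
  }
  Y <- as.matrix(Y)
  p <- ncol(Y)
  if (p < 2) stop("background correlation needs at least 2 genes")
  r <- vapply(2:p, function(j) stats::cor(Y[, j - 1], Y[, j]), numeric(1))
  structure(list(rho0 = abs(stats::median(r)), n_pairs = p - 1L,
                 chromosome = chrom),
            class = "corrseg_rho0")
}

#' @export
print.corrseg_rho0 <- function(x, ...) {
  cat(sprintf("background correlation rho0 = %.4f (%d adjacent pairs%s)\n",
              x$rho0, x$n_pairs,
              if (is.na(x$chromosome)) "" else paste0(", ", x$chromosome)))
  invisible(x)
}

#' Region test statistic
#'
#' \eqn{T = \sum_i (\bar Y_{i\cdot} - \bar Y_{\cdot\cdot})^2}, the sum
#' over patients of the squared centered within-region mean expression.
#' Under the compound-symmetry model with correlation rho the statistic
#' is distributed as \eqn{\lambda(p_k, \rho)\,\chi^2_{n-1}}, which makes
#' the test of elevated regional correlation exact. On standardized
#' blocks the identity \eqn{T = n\,\lambda(p_k, \hat\rho_k)} links the
#' statistic to the unclamped ML correlation estimate.
#'
#' @param block numeric matrix of the region's standardized gene
#'   columns (n patients x p_k genes), n >= 2.
#' @return The scalar statistic (>= 0).
#' @export
region_statistic <- function(block) {
  block <- as.matrix(block)
  if (nrow(block) < 2) stop("region statistic needs at least 2 patients")
  m <- rowMeans(block)
  sum((m - mean(m))^2)
}

#' Exact p-value of the region correlation test
#'
#' Tests H0: rho_k = rho0 against H1: rho_k > rho0 for a region of p_k
#' genes. Under H0 the statistic is \eqn{\lambda(p_k, \rho_0)} times a
#' chi-square with n - 1 degrees of freedom, so the p-value is the exact
#' upper tail \eqn{P(\lambda(p_k,\rho_0) Z > T)} — no resampling.
#'
#' @param T observed statistic (vectorized).
#' @param p_k region width in genes.
#' @param rho0 background correlation, in \[0, 1).
#' @param n number of patients.
#' @return p-value(s) in \[0, 1\].
#' @export
region_pvalue <- function(T, p_k, rho0, n) {
  if (any(T < 0)) stop("T must be non-negative")
  if (rho0 < 0 || rho0 >= 1) stop("rho0 must lie in [0, 1)")
  if (n < 2) stop("n must be at least 2")
  stats::pchisq(T / lambda_cs(p_k, rho0), df = n - 1, lower.tail = FALSE)
}

#' Analytic power of the region correlation test
#'
#' Probability of detecting a region of width p0 whose true correlation
#' is rho, against background rho0, at nominal level alpha:
#' \eqn{Po = P\{Z > \frac{\lambda(p_0,\rho_0)}{\lambda(p_0,\rho)}
#' q_{n-1,1-\alpha}\}} with \eqn{Z \sim \chi^2_{n-1}}. Evaluated
#' exactly from the chi-square tail; no simulation. At rho = rho0 the
#' power equals alpha.
#'
#' @param n number of patients.
#' @param p0 region width in genes.
#' @param rho alternative correlation (must be >= rho0; the test is
#'   one-sided).
#' @param rho0 background correlation in \[0, 1).
#' @param alpha nominal level in (0, 1); default 0.05.
#' @return The power, a number in \[0, 1\].
#' @export
region_power <- function(n, p0, rho, rho0, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (rho0 < 0 || rho0 >= 1) stop("rho0 must lie in [0, 1)")
  if (any(rho < rho0)) stop("rho must be >= rho0 (one-sided alternative)")
  if (p0 < 1) stop("p0 must be >= 1")
  q <- stats::qchisq(1 - alpha, df = n - 1)
  stats::pchisq(lambda_cs(p0, rho0) / lambda_cs(p0, rho) * q,
                df = n - 1, lower.tail = FALSE)
}

#' Multiple-testing adjustment of region p-values
#'
#' Benjamini-Hochberg FDR (default) or Bonferroni adjustment, applied
#' genome-wide across all tested regions.
#'
#' @param pvalues numeric vector of raw p-values in \[0, 1\].
#' @param method `"BH"` (default) or `"bonferroni"`.
#' @return Adjusted p-values, same length, each >= its raw value.
#' @export
adjust_pvalues <- function(pvalues, method = c("BH", "bonferroni")) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  method <- match.arg(method)
  stats::p.adjust(pvalues, method = method)
}

#' Test every region of a segmentation against the background
#'
#' Computes the region statistic, exact p-value, adjusted p-value and
#' significance flag for each region of a segmentation, using a single
#' background correlation for the whole chromosome.
#'
#' @param seg a `corrseg_segmentation` of `Y`.
#' @param Y the standardized single-chromosome `expr_matrix` (or
#'   matrix) the segmentation refers to.
#' @param rho0 background correlation (scalar or a `corrseg_rho0`);
#'   if `NULL` (default) it is estimated from `Y` with
#'   [estimate_rho0()].
#' @param alpha significance level applied to the adjusted p-values;
#'   default 0.05.
#' @param method adjustment method for [adjust_pvalues()], or `"none"`
#'   to defer adjustment (e.g. for later genome-wide pooling).
#' @return Data frame with one row per region: `region`, `start`, `end`,
#'   `p_k`, `rho`, `T`, `rho0`, `p_value`, `p_adj`, `significant`.
#' @export
test_regions <- function(seg, Y, rho0 = NULL, alpha = 0.05,
                         method = c("BH", "bonferroni", "none")) {
  stopifnot(inherits(seg, "corrseg_segmentation"))
  method <- match.arg(method)
  Ym <- as_standardized_matrix(Y)
  if (ncol(Ym) != seg$p)
    stop("segmentation refers to ", seg$p, " genes but Y has ", ncol(Ym))
  if (is.null(rho0)) rho0 <- estimate_rho0(Ym)
  if (inherits(rho0, "corrseg_rho0")) rho0 <- rho0$rho0
  n <- nrow(Ym)
  res <- seg$regions
  res$T <- vapply(seq_len(seg$K), function(k)
    region_statistic(Ym[, res$start[k]:res$end[k], drop = FALSE]),
    numeric(1))
  res$rho0 <- rho0
  res$p_value <- region_pvalue(res$T, res$p_k, rho0, n)
  if (method == "none") {
    res$p_adj <- NA_real_
    res$significant <- NA
  } else {
    res$p_adj <- adjust_pvalues(res$p_value, method)
    res$significant <- res$p_adj <= alpha
  }
  res$neg2_loglik <- NULL
  res
}
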