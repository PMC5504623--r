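#' @section Model:
#' Within a chromosome the patient profiles are modelled as i.i.d.
#' centered Gaussian vectors whose correlation matrix is block diagonal:
#' the ordered genes split into K contiguous regions, genes in different
#' regions are independent and genes within region k share a single
#' pairwise correlation rho_k (compound symmetry). For a region of
#' length p_k the maximum-likelihood estimate of rho_k and the maximized
#' likelihood have closed forms in terms of the empirical Gram matrix
#' G-hat = t(Y) Y / n, which makes the segmentation cost additive over
#' regions and exactly optimizable by dynamic programming in O(K p^2).
#' @keywords internal
#' @name corrseg-segmentation
NULL

RHO_EPS <- 1e-8

# clamp rho into the open interval where the CS likelihood is defined:
# (-1/(pk-1), 1), with margin eps
clamp_rho <- function(rho, pk, eps = RHO_EPS) {
  lo <- -1 / (pk - 1) + eps
  pmin(pmax(rho, lo), 1 - eps)
}

# -2 log-likelihood of a CS block of length pk at correlation rho
# (natural logs; n cancels nowhere, it multiplies the whole expression)
cs_neg2ll <- function(n, pk, rho) {
  n * (pk + (pk - 1) * log1p(-rho) + log1p((pk - 1) * rho))
}

#' Maximum-likelihood equicorrelation of a gene block
#'
#' For a standardized block of p_k gene columns the ML estimate of the
#' common pairwise correlation is the mean of the off-diagonal entries
#' of the block's empirical Gram matrix:
#' \eqn{\hat\rho = (\sum_{j\ell} \hat G_{j\ell} - p_k) / (p_k^2 - p_k)}.
#' Single-gene blocks return 0 by convention.
#'
#' @param block numeric matrix, n patients x p_k genes, standardized
#'   under the 1/n convention.
#' @param clamp clamp the estimate into
#'   \eqn{[-1/(p_k-1) + \epsilon,\, 1 - \epsilon]} with
#'   \eqn{\epsilon = 10^{-8}} so the log-likelihood stays finite
#'   (default `TRUE`).
#' @return The scalar estimate.
#' @export
block_rho_mle <- function(block, clamp = TRUE) {
  block <- as.matrix(block)
  assert_standardized(block)
  pk <- ncol(block)
  if (pk == 1) return(0)
  n <- nrow(block)
  s <- sum(crossprod(block)) / n
  rho <- (s - pk) / (pk^2 - pk)
  if (clamp) rho <- clamp_rho(rho, pk)
  rho
}

#' Maximized -2 log-likelihood of a gene block
#'
#' Evaluates the closed form
#' \eqn{-2\hat L_k = n[p_k + (p_k-1)\log(1-\hat\rho_k) +
#' \log(1 + (p_k-1)\hat\rho_k)]} at the (clamped) block estimate
#' [block_rho_mle()]. Equals the direct Gaussian expression
#' \eqn{n\log|\Sigma| + \mathrm{tr}(Y\Sigma^{-1}Y^\top)} at the optimum.
#'
#' @inheritParams block_rho_mle
#' @return The scalar -2 log-likelihood.
#' @export
block_neg2_loglik <- function(block) {
  block <- as.matrix(block)
  assert_standardized(block)
  pk <- ncol(block)
  n <- nrow(block)
  if (pk == 1) return(n)
  cs_neg2ll(n, pk, block_rho_mle(block))
}

# All-segment costs from per-patient prefix sums.
# cost[a, b] = -2 Lhat of the block [a..b]; rho[a, b] = clamped MLE.
# Sum of Ghat over the block is (1/n) sum_i (C_i(b) - C_i(a-1))^2 with
# C_i the cumulative row sums, so each segment costs O(n).
segment_costs <- function(Y) {
  n <- nrow(Y)
  p <- ncol(Y)
  C <- matrix(0, n, p + 1)
  for (j in seq_len(p)) C[, j + 1] <- C[, j] + Y[, j]
  cost <- matrix(NA_real_, p, p)
  rho <- matrix(NA_real_, p, p)
  for (a in seq_len(p)) {
    D <- C[, (a + 1):(p + 1), drop = FALSE] - C[, a]
    s <- colSums(D * D) / n
    pk <- seq_len(p - a + 1)
    r <- numeric(length(pk))
    if (length(pk) > 1)
      r[-1] <- clamp_rho((s[-1] - pk[-1]) / (pk[-1]^2 - pk[-1]), pk[-1])
    cost[a, a:p] <- cs_neg2ll(n, pk, r)
    rho[a, a:p] <- r
  }
  list(cost = cost, rho = rho, n = n, p = p)
}

# Dynamic program over a precomputed cost matrix.
# dp[k, b] = minimal total cost of splitting genes 1..b into k segments.
dp_fill <- function(cost, K_max) {
  p <- ncol(cost)
  dp <- matrix(Inf, K_max, p)
  dp[1, ] <- cost[1, ]
  if (K_max >= 2) {
    for (k in 2:K_max) {
      for (b in k:p) {
        dp[k, b] <- min(dp[k - 1, (k - 1):(b - 1)] + cost[k:b, b])
      }
    }
  }
  dp
}

# Backtrack the optimal K-segmentation; ties resolved by which.min,
# i.e. the smallest admissible last change-point, applied recursively.
dp_backtrack <- function(dp, cost, K) {
  p <- ncol(cost)
  tau <- integer(K + 1)
  tau[K + 1] <- p
  b <- p
  if (K >= 2) {
    for (k in K:2) {
      a_cand <- k:b
      v <- dp[k - 1, a_cand - 1] + cost[a_cand, b]
      a <- a_cand[which.min(v)]
      tau[k] <- a - 1
      b <- a - 1
    }
  }
  tau
}

make_segmentation <- function(tau, costs) {
  K <- length(tau) - 1
  start <- tau[-(K + 1)] + 1L
  end <- tau[-1]
  idx <- cbind(start, end)
  regions <- data.frame(region = seq_len(K), start = start, end = end,
                        p_k = end - start + 1L,
                        rho = costs$rho[idx],
                        neg2_loglik = costs$cost[idx])
  structure(list(K = K, tau = tau, regions = regions,
                 neg2_loglik = sum(regions$neg2_loglik),
                 loglik = -sum(regions$neg2_loglik) / 2,
                 n = costs$n, p = costs$p),
            class = "corrseg_segmentation")
}

#' @export
print.corrseg_segmentation <- function(x, ...) {
  cat(sprintf("segmentation of %d genes into %d region(s); -2 logLik = %.4f\n",
              x$p, x$K, x$neg2_loglik))
  print(x$regions, row.names = FALSE)
  invisible(x)
}

#' Optimal segmentations for every number of regions up to K_max
#'
#' Exact dynamic programming over the additive compound-symmetry region
#' likelihood: for each K = 1..K_max the returned boundaries globally
#' minimize the total -2 log-likelihood over all partitions of the
#' ordered genes into K contiguous regions. Cost ties are broken towards
#' the smallest last change-point, recursively, so results are
#' deterministic.
#'
#' @param Y a standardized single-chromosome `expr_matrix`, or a
#'   standardized numeric matrix (n patients x p genes).
#' @param K_max largest number of regions to consider (must not exceed
#'   the number of genes).
#' @return Object of class `corrseg_dp`: a list with `segmentations`
#'   (one `corrseg_segmentation` per K), `loglik` (maximal log-likelihood
#'   L_K for each K, non-decreasing), `n`, `p`.
#' @export
segment_dp <- function(Y, K_max) {
  Y <- as_standardized_matrix(Y)
  p <- ncol(Y)
  if (K_max < 1 || K_max > p)
    stop("K_max must be between 1 and the number of genes (", p, ")")
  costs <- segment_costs(Y)
  dp <- dp_fill(costs$cost, K_max)
  segs <- lapply(seq_len(K_max), function(K)
    make_segmentation(dp_backtrack(dp, costs$cost, K), costs))
  structure(list(segmentations = segs,
                 loglik = vapply(segs, `[[`, numeric(1), "loglik"),
                 n = costs$n, p = p, K_max = K_max),
            class = "corrseg_dp")
}

as_standardized_matrix <- function(Y) {
  if (inherits(Y, "expr_matrix")) {
    if (!Y$standardized) stop("expression matrix must be standardized first")
    if (length(chromosomes(Y)) > 1)
      stop("segmentation operates on a single chromosome; use subset_chromosome()")
    Y <- Y$values
  }
  Y <- as.matrix(Y)
  assert_standardized(Y)
  Y
}

# penalty on the number of regions used by the slope heuristic
selection_penalty <- function(j, p) 5 * j + 2 * j * log(p / j)

#' Choose the number of regions by the slope heuristic
#'
#' Normalizes the maximal log-likelihoods L_K against the penalty
#' \eqn{\tilde K_j = 5j + 2j\log(p/j)} via
#' \eqn{\tilde L_K = \frac{L_{K_{max}} - L_K}{L_{K_{max}} - L_1}
#' (\tilde K_{K_{max}} - \tilde K_1) + 1} and selects a K at which the
#' normalized curve shows a slope change exceeding the threshold S. The
#' slope change at K is the centered second difference
#' \eqn{(\tilde L_{K-1} - \tilde L_K) - (\tilde L_K - \tilde L_{K+1})}.
#' By default the largest qualifying K is taken; `rule = "smallest"`
#' takes the smallest. If no K qualifies the fit is declared
#' unsegmented and K-hat = 1.
#'
#' @param loglik numeric vector of maximal log-likelihoods L_1..L_Kmax.
#' @param p number of genes (enters the penalty).
#' @param S slope-change threshold; default 0.7.
#' @param rule `"largest"` (default) or `"smallest"` qualifying K.
#' @return Object of class `corrseg_selection`: list with `K_hat`,
#'   `candidates`, `L_tilde`, `penalty`, `S`, `K_max`, `rule`.
#' @export
select_K <- function(loglik, p, S = 0.7, rule = c("largest", "smallest")) {
  rule <- match.arg(rule)
  K_max <- length(loglik)
  # L_K is typically increasing in K but the block models are not nested
  # (splitting a block drops its cross-half correlation terms), so small
  # decreases can occur; only a globally flat/degenerate profile is refused.
  pen <- selection_penalty(seq_len(K_max), p)
  out <- list(K_max = K_max, loglik = loglik, penalty = pen, S = S,
              rule = rule, L_tilde = NULL, candidates = integer(0), K_hat = 1L)
  if (K_max < 3) {
    class(out) <- "corrseg_selection"
    return(out)
  }
  span <- loglik[K_max] - loglik[1]
  if (span <= 0) {
    warning("flat likelihood across K; selecting K = 1")
    class(out) <- "corrseg_selection"
    return(out)
  }
  Lt <- (loglik[K_max] - loglik) / span * (pen[K_max] - pen[1]) + 1
  # the slope change AT K is the centered second difference
  # (Lt[K-1] - Lt[K]) - (Lt[K] - Lt[K+1]); K displaying a change > S
  # is a candidate
  ks <- 2:(K_max - 1)
  d2 <- (Lt[ks - 1] - Lt[ks]) - (Lt[ks] - Lt[ks + 1])
  cand <- ks[d2 > S]
  out$L_tilde <- Lt
  out$candidates <- cand
  out$K_hat <- if (length(cand) == 0) 1L
               else if (rule == "largest") max(cand) else min(cand)
  class(out) <- "corrseg_selection"
  out
}

#' @export
print.corrseg_selection <- function(x, ...) {
  cat(sprintf("slope-heuristic selection: K_hat = %d of K_max = %d (S = %g, rule = %s)\n",
              x$K_hat, x$K_max, x$S, x$rule))
  if (length(x$candidates))
    cat("candidates:", paste(x$candidates, collapse = ", "), "\n")
  invisible(x)
}

default_K_max <- function(p) max(1L, min(p %/% 2L, 40L))

#' Segment one chromosome into equicorrelated regions
#'
#' Runs the dynamic program up to `K_max` regions and returns the
#' segmentation at the number of regions chosen by the slope heuristic.
#'
#' @inheritParams segment_dp
#' @param K_max largest number of regions considered; default
#'   `min(floor(p/2), 40)`.
#' @param S slope-change threshold for [select_K()]; default 0.7.
#' @param rule candidate rule for [select_K()].
#' @return A `corrseg_segmentation` at K-hat, with the full [select_K()]
#'   trace attached as attribute `"selection"` and the per-K maximal
#'   log-likelihoods as attribute `"loglik"`.
#' @export
segment_chromosome <- function(Y, K_max = NULL, S = 0.7,
                               rule = c("largest", "smallest")) {
  rule <- match.arg(rule)
  Ym <- as_standardized_matrix(Y)
  p <- ncol(Ym)
  if (is.null(K_max)) K_max <- default_K_max(p)
  dp <- segment_dp(Ym, K_max)
  sel <- select_K(dp$loglik, p, S = S, rule = rule)
  if (sel$K_hat == K_max && K_max > 1)
    warning("selected K equals K_max (", K_max,
            "); the chromosome may be under-segmented, consider raising K_max")
  seg <- dp$segmentations[[sel$K_hat]]
  attr(seg, "selection") <- sel
  attr(seg, "loglik") <- dp$loglik
  seg
}
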