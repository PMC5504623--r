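# Shared fixtures and independent oracles used across the test files.

# standardize a plain matrix under the 1/n convention
std_mat <- function(m) {
  m <- sweep(m, 2, colMeans(m))
  sweep(m, 2, sqrt(colMeans(m^2)), "/")
}

# random standardized matrix
rand_std <- function(n, p, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  std_mat(matrix(rnorm(n * p), n, p))
}

# draw n i.i.d. rows from a p-variate Gaussian with exchangeable
# correlation rho (population-standardized; no empirical rescaling)
rmvn_cs <- function(n, p, rho) {
  sqrt(rho) * rnorm(n) + sqrt(1 - rho) * matrix(rnorm(n * p), n, p)
}

# exhaustive-search oracle: minimal total cost and boundaries over all
# segmentations of 1..p into K contiguous blocks, brute force
enumerate_best <- function(cost, K) {
  p <- ncol(cost)
  if (K == 1) return(list(cost = cost[1, p], tau = c(0, p)))
  cuts <- utils::combn(p - 1, K - 1)
  best <- Inf; best_tau <- NULL
  for (i in seq_len(ncol(cuts))) {
    tau <- c(0, cuts[, i], p)
    tot <- sum(cost[cbind(tau[-(K + 1)] + 1, tau[-1])])
    if (tot < best - 1e-12) { best <- tot; best_tau <- tau }
  }
  list(cost = best, tau = best_tau)
}

# compound-symmetry block cost computed independently from the Gram
# matrix definition (no prefix sums)
cs_cost_direct <- function(Y, a, b, eps = 1e-8) {
  blk <- Y[, a:b, drop = FALSE]
  n <- nrow(blk); pk <- ncol(blk)
  if (pk == 1) return(n)
  G <- crossprod(blk) / n
  rho <- (sum(G) - pk) / (pk^2 - pk)
  rho <- min(max(rho, -1 / (pk - 1) + eps), 1 - eps)
  n * (pk + (pk - 1) * log(1 - rho) + log(1 + (pk - 1) * rho))
}

cost_matrix_direct <- function(Y) {
  p <- ncol(Y)
  cost <- matrix(NA_real_, p, p)
  for (a in 1:p) for (b in a:p) cost[a, b] <- cs_cost_direct(Y, a, b)
  cost
}

# dense linear-algebra evaluation of the Gaussian -2 log-likelihood of
# a block at a given compound-symmetric correlation
gaussian_neg2ll_direct <- function(blk, rho) {
  n <- nrow(blk); pk <- ncol(blk)
  S <- matrix(rho, pk, pk); diag(S) <- 1
  n * determinant(S, logarithm = TRUE)$modulus[1] +
    sum((blk %*% solve(S)) * blk)
}

# Benjamini-Hochberg step-up applied from its definition
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in m:1) {
    prev <- min(prev, m / i * p[o[i]])
    adj[o[i]] <- prev
  }
  adj
}

# tiny two-chromosome annotation + expression files on disk
write_toy_dataset <- function(dir, n = 40, p_per_chrom = c(12, 10),
                              seed = 42) {
  set.seed(seed)
  ann <- do.call(rbind, lapply(seq_along(p_per_chrom), function(ci) {
    p <- p_per_chrom[ci]
    data.frame(gene_id = sprintf("c%dg%02d", ci, 1:p),
               chromosome = paste0("chr", ci),
               start = (0:(p - 1)) * 1000, end = (1:p) * 1000 - 100)
  }))
  vals <- matrix(rnorm(n * nrow(ann)), n, nrow(ann))
  colnames(vals) <- ann$gene_id
  bed <- file.path(dir, "genes.bed")
  writeLines(sprintf("%s\t%d\t%d\t%s", ann$chromosome, ann$start, ann$end,
                     ann$gene_id), bed)
  expr <- file.path(dir, "expr.tsv")
  df <- data.frame(gene_id = ann$gene_id, t(vals), check.names = FALSE)
  colnames(df) <- c("gene_id", sprintf("s%02d", 1:n))
  write.table(df, expr, sep = "\t", quote = FALSE, row.names = FALSE)
  list(bed = bed, expr = expr, ann = ann, values = vals)
}
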