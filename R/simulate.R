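#' Single-chromosome simulation design (easy case)
#'
#' One chromosome of `p` genes carrying a small number of correlated
#' regions at fixed, well-separated positions. Defaults: 500 genes with
#' four regions of lengths 5, 10, 20 and 40 starting at genes 101, 201,
#' 301 and 401, and background correlation 0.08 (typical of the easy
#' regime; 0.18 and 0.28 are progressively harder).
#'
#' @param p number of genes.
#' @param region_starts,region_lengths 1-based start index and length of
#'   each correlated region.
#' @param rho0 background correlation of the chromosome.
#' @param chrom chromosome label.
#' @return A design list usable by [sim_spec()].
#' @export
scenario1_design <- function(p = 500, region_starts = c(101, 201, 301, 401),
                             region_lengths = c(5, 10, 20, 40),
                             rho0 = 0.08, chrom = "chr1") {
  regions <- if (length(region_starts)) {
    data.frame(chrom = chrom, start = as.integer(region_starts),
               length = as.integer(region_lengths), stringsAsFactors = FALSE)
  } else NULL
  list(chromosomes = data.frame(chrom = chrom, p = as.integer(p),
                                rho0 = rho0, stringsAsFactors = FALSE),
       regions = regions)
}

#' Genome-shaped simulation design (realistic case)
#'
#' A packaged 22-chromosome design with per-chromosome gene counts,
#' region layouts and background correlations (rho0 drawn once from
#' 0.05-0.28) emulating the shape of a tumor expression dataset. The
#' design file is synthetic: it was generated once with a fixed seed
#' and shipped with the package (`extdata/scenario2_design.tsv`).
#'
#' @param path path to a design TSV (columns `chrom`, `p`, `rho0`,
#'   `region_starts`, `region_lengths`, the last two comma-separated
#'   lists); defaults to the packaged file.
#' @return A design list usable by [sim_spec()].
#' @export
scenario2_design <- function(path = system.file("extdata",
                                                "scenario2_design.tsv",
                                                package = "corrseg")) {
  d <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  regions <- do.call(rbind, lapply(seq_len(nrow(d)), function(i) {
    st <- as.integer(strsplit(d$region_starts[i], ",")[[1]])
    le <- as.integer(strsplit(d$region_lengths[i], ",")[[1]])
    if (length(st) == 0) return(NULL)
    data.frame(chrom = d$chrom[i], start = st, length = le,
               stringsAsFactors = FALSE)
  }))
  list(chromosomes = data.frame(chrom = d$chrom, p = as.integer(d$p),
                                rho0 = d$rho0, stringsAsFactors = FALSE),
       regions = regions)
}

#' Simulation specification
#'
#' Binds a chromosome design to the sampling parameters of one of three
#' generating scenarios: (1/2) correlated regions with a constant
#' within-region correlation `rho1`, on a single chromosome or a
#' genome-shaped design; (3) within-region correlation matrices drawn
#' from a Wishart distribution with scale matrix having 0.5
#' off-diagonal and nu = p_k * 2^beta degrees of freedom, so the
#' within-region correlation fluctuates around 0.5 with variability
#' decreasing in beta.
#'
#' @param design a design list ([scenario1_design()],
#'   [scenario2_design()] or hand-built with the same shape).
#' @param n number of patients.
#' @param rho1 within-region correlation (scenarios 1-2) or the
#'   off-diagonal of the Wishart scale matrix (scenario 3, fixed at 0.5
#'   by default).
#' @param scenario 1, 2 or 3.
#' @param beta Wishart degrees-of-freedom exponent (scenario 3 only).
#' @param rho0 optional scalar overriding the per-chromosome background
#'   correlation of the design.
#' @return Object of class `corrseg_sim_spec`.
#' @export
sim_spec <- function(design, n = 100, rho1 = 0.5, scenario = 1,
                     beta = NULL, rho0 = NULL) {
  stopifnot(scenario %in% 1:3)
  if (scenario == 3 && is.null(beta))
    stop("scenario 3 requires the Wishart exponent 'beta'")
  chromd <- design$chromosomes
  if (!is.null(rho0)) chromd$rho0 <- rho0
  if (any(chromd$rho0 < 0 | chromd$rho0 >= 1))
    stop("rho0 must lie in [0, 1)")
  if (rho1 < 0 || rho1 >= 1) stop("rho1 must lie in [0, 1)")
  regions <- design$regions
  if (!is.null(regions) && nrow(regions)) {
    m <- match(regions$chrom, chromd$chrom)
    if (anyNA(m)) stop("region on unknown chromosome")
    if (any(regions$start < 1) ||
        any(regions$start + regions$length - 1 > chromd$p[m]))
      stop("a region does not fit inside its chromosome")
    o <- order(m, regions$start)
    regions <- regions[o, , drop = FALSE]
    ends <- regions$start + regions$length - 1
    same <- duplicated(regions$chrom, fromLast = FALSE)
    if (any(same & regions$start <= c(-Inf, ends[-length(ends)])))
      stop("regions overlap within a chromosome")
    if (scenario %in% 1:2 && any(rho1 < chromd$rho0[m]))
      stop("rho1 must be >= rho0 on every chromosome carrying a region")
  }
  structure(list(design = list(chromosomes = chromd, regions = regions),
                 n = n, rho1 = rho1, scenario = scenario, beta = beta),
            class = "corrseg_sim_spec")
}

# draw a Wishart correlation matrix: scale with unit diagonal and rho1
# off-diagonal, nu degrees of freedom, draw rescaled to unit diagonal
draw_wishart_correlation <- function(pk, rho1, nu) {
  if (nu < pk) stop("Wishart degrees of freedom must be >= region width")
  Smat <- matrix(rho1, pk, pk)
  diag(Smat) <- 1
  W <- stats::rWishart(1, df = nu, Sigma = Smat)[, , 1]
  stats::cov2cor(W)
}

# clip a symmetric matrix to positive semi-definite and rescale to unit
# diagonal (used after subtracting the background from a drawn
# correlation matrix)
psd_correlation <- function(C, eps = 1e-8) {
  e <- eigen(C, symmetric = TRUE)
  if (min(e$values) >= eps) return(C)
  v <- pmax(e$values, eps)
  C2 <- e$vectors %*% (v * t(e$vectors))
  stats::cov2cor(C2)
}

#' Simulate expression with planted correlated regions
#'
#' Draws i.i.d. multivariate Gaussian patient profiles. Each chromosome
#' carries a shared factor giving every gene pair the background
#' correlation rho0; inside each planted region an additional block
#' factor (scenarios 1-2) raises the pairwise correlation to rho1,
#' while scenario 3 replaces the block structure by a Wishart-drawn
#' correlation matrix re-anchored on the background. Columns are
#' standardized (1/n convention) on output.
#'
#' @param spec a [sim_spec()].
#' @param seed optional integer seed (`set.seed` is called if given).
#' @return List with `expr` (a standardized `expr_matrix`; genes get
#'   synthetic 1-kb annotation intervals in order) and `truth` (class
#'   `corrseg_sim_truth`: `genes` with per-gene H0/H1 label and true
#'   rho, `regions`, and per-chromosome true `boundaries`).
#' @export
simulate_expression <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "corrseg_sim_spec"))
  if (!is.null(seed)) set.seed(seed)
  chromd <- spec$design$chromosomes
  regs <- spec$design$regions
  n <- spec$n
  vals <- NULL
  ann_list <- list()
  truth_genes <- list()
  truth_regions <- list()
  boundaries <- list()
  for (ci in seq_len(nrow(chromd))) {
    chrom <- chromd$chrom[ci]
    p <- chromd$p[ci]
    rho0 <- chromd$rho0[ci]
    W <- stats::rnorm(n)
    E <- matrix(stats::rnorm(n * p), n, p)
    Y <- sqrt(rho0) * W + sqrt(1 - rho0) * E
    h1 <- logical(p)
    rho_gene <- rep(rho0, p)
    cregs <- if (is.null(regs)) {
      data.frame(chrom = character(), start = integer(), length = integer())
    } else {
      regs[regs$chrom == chrom, , drop = FALSE]
    }
    creg_rho <- numeric(0)
    if (nrow(cregs)) {
      for (r in seq_len(nrow(cregs))) {
        idx <- cregs$start[r]:(cregs$start[r] + cregs$length[r] - 1)
        pk <- length(idx)
        if (spec$scenario %in% 1:2) {
          V <- stats::rnorm(n)
          Y[, idx] <- sqrt(rho0) * W + sqrt(spec$rho1 - rho0) * V +
            sqrt(1 - spec$rho1) * E[, idx]
          rho_r <- spec$rho1
        } else {
          nu <- pk * 2^spec$beta
          R <- draw_wishart_correlation(pk, spec$rho1, nu)
          Cb <- (R - rho0) / (1 - rho0)
          diag(Cb) <- 1
          Cb <- psd_correlation(Cb)
          Z <- matrix(stats::rnorm(n * pk), n, pk) %*% chol(Cb)
          Y[, idx] <- sqrt(rho0) * W + sqrt(1 - rho0) * Z
          Creal <- rho0 + (1 - rho0) * Cb
          rho_r <- mean(Creal[upper.tri(Creal)])
        }
        h1[idx] <- TRUE
        rho_gene[idx] <- rho_r
        creg_rho <- c(creg_rho, rho_r)
      }
      truth_regions[[chrom]] <- data.frame(chrom = chrom,
                                           start = cregs$start,
                                           end = cregs$start + cregs$length - 1,
                                           rho = creg_rho,
                                           stringsAsFactors = FALSE)
    }
    # true segmentation boundaries: edges of the planted regions
    bnd <- sort(unique(c(0, p,
                         if (nrow(cregs)) c(cregs$start - 1,
                                            cregs$start + cregs$length - 1))))
    boundaries[[chrom]] <- bnd
    gid <- sprintf("%s_g%04d", chrom, seq_len(p))
    ann_list[[chrom]] <- data.frame(gene_id = gid, chromosome = chrom,
                                    start = (seq_len(p) - 1) * 1000,
                                    end = seq_len(p) * 1000 - 100,
                                    stringsAsFactors = FALSE)
    colnames(Y) <- gid
    truth_genes[[chrom]] <- data.frame(chrom = chrom, index = seq_len(p),
                                       gene_id = gid, h1 = h1,
                                       rho = rho_gene,
                                       stringsAsFactors = FALSE)
    vals <- if (is.null(vals)) Y else cbind(vals, Y)
  }
  rownames(vals) <- sprintf("patient_%03d", seq_len(n))
  expr <- standardize(expression_matrix(vals, do.call(rbind, ann_list)))
  truth <- structure(list(genes = do.call(rbind, truth_genes),
                          regions = if (length(truth_regions))
                            do.call(rbind, truth_regions) else NULL,
                          boundaries = boundaries, spec = spec),
                     class = "corrseg_sim_truth")
  rownames(truth$genes) <- NULL
  if (!is.null(truth$regions)) rownames(truth$regions) <- NULL
  list(expr = expr, truth = truth)
}

#' Default diagnostic alpha grid
#'
#' Logarithmic grid of test levels from 1e-8 to 1 (50 points) at which
#' TPR and FPR are tabulated.
#' @return Numeric vector of length 50.
#' @export
default_alpha_grid <- function() 10^seq(-8, 0, length.out = 50)

# per-gene adjusted p-value implied by a region table (genes not
# covered by any region are never called)
gene_level_pvalues <- function(truth, regions) {
  key <- paste(truth$genes$chrom, truth$genes$index)
  gp <- rep(Inf, nrow(truth$genes))
  for (r in seq_len(nrow(regions))) {
    k <- paste(regions$chromosome[r], regions$start[r]:regions$end[r])
    gp[match(k, key)] <- regions$p_adj[r]
  }
  gp
}

roc_auc <- function(fpr, tpr) {
  ok <- is.finite(fpr) & is.finite(tpr)
  fpr <- c(0, fpr[ok], 1)
  tpr <- c(0, tpr[ok], 1)
  o <- order(fpr, tpr)
  fpr <- fpr[o]; tpr <- tpr[o]
  sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}

normalize_region_table <- function(regions) {
  if (!"chromosome" %in% names(regions)) {
    if ("chrom" %in% names(regions)) names(regions)[names(regions) == "chrom"] <- "chromosome"
    else regions$chromosome <- "chr1"
  }
  regions
}

#' Gene-level detection metrics against a simulation truth
#'
#' At each level alpha a gene counts as predicted positive when it lies
#' in a region with adjusted p-value <= alpha. TPR and FPR are
#' tabulated over `alpha_grid`; the AUC integrates the ROC traced at
#' the observed adjusted p-values (augmented with (0,0) and (1,1)), so
#' it depends on the p-value ranking only.
#'
#' @param truth a `corrseg_sim_truth`.
#' @param regions region table with columns `chromosome` (or `chrom`),
#'   `start`, `end` (gene indices) and `p_adj`.
#' @param alpha_grid levels at which TPR/FPR are reported.
#' @return Object of class `corrseg_eval`: list with `level = "gene"`,
#'   `curve` (data frame alpha/TPR/FPR) and `auc`.
#' @export
evaluate_gene_level <- function(truth, regions,
                                alpha_grid = default_alpha_grid()) {
  regions <- normalize_region_table(regions)
  gp <- gene_level_pvalues(truth, regions)
  h1 <- truth$genes$h1
  rates <- function(a) {
    pred <- gp <= a
    c(TPR = if (sum(h1)) sum(pred & h1) / sum(h1) else NA_real_,
      FPR = if (sum(!h1)) sum(pred & !h1) / sum(!h1) else NA_real_)
  }
  curve <- t(vapply(alpha_grid, rates, numeric(2)))
  thresholds <- sort(unique(gp[is.finite(gp)]))
  roc <- t(vapply(thresholds, rates, numeric(2)))
  structure(list(level = "gene",
                 curve = data.frame(alpha = alpha_grid, TPR = curve[, 1],
                                    FPR = curve[, 2]),
                 auc = if (length(thresholds))
                   roc_auc(roc[, 2], roc[, 1]) else 0.5),
            class = "corrseg_eval")
}

# region-level TP/FP/TN/FN counts at one level: genes get a status from
# predicted x true label, maximal runs of equal status within a
# chromosome form status regions, and regions are counted
region_status_counts <- function(truth, pred) {
  counts <- c(TP = 0, FP = 0, TN = 0, FN = 0)
  status <- ifelse(pred & truth$genes$h1, "TP",
            ifelse(pred & !truth$genes$h1, "FP",
            ifelse(!pred & truth$genes$h1, "FN", "TN")))
  for (chrom in unique(truth$genes$chrom)) {
    r <- rle(status[truth$genes$chrom == chrom])
    tab <- table(r$values)
    counts[names(tab)] <- counts[names(tab)] + as.numeric(tab)
  }
  counts
}

#' Region-level detection metrics against a simulation truth
#'
#' More stringent than the gene-level criterion: genes are classified
#' TP/FP/TN/FN from predicted versus true labels, maximal runs of genes
#' sharing a status are merged into status regions, and TPR = TP /
#' (TP + FN), FPR = FP / (FP + TN) are computed on region counts, so
#' imprecise boundaries create FP/FN regions. Empty denominators give
#' `NA`. AUC as in [evaluate_gene_level()].
#'
#' @inheritParams evaluate_gene_level
#' @return Object of class `corrseg_eval` with `level = "region"`.
#' @export
evaluate_region_level <- function(truth, regions,
                                  alpha_grid = default_alpha_grid()) {
  regions <- normalize_region_table(regions)
  gp <- gene_level_pvalues(truth, regions)
  rates <- function(a) {
    cts <- region_status_counts(truth, gp <= a)
    c(TPR = if (cts["TP"] + cts["FN"] > 0)
        unname(cts["TP"] / (cts["TP"] + cts["FN"])) else NA_real_,
      FPR = if (cts["FP"] + cts["TN"] > 0)
        unname(cts["FP"] / (cts["FP"] + cts["TN"])) else NA_real_)
  }
  curve <- t(vapply(alpha_grid, rates, numeric(2)))
  thresholds <- sort(unique(gp[is.finite(gp)]))
  roc <- if (length(thresholds))
    t(vapply(thresholds, rates, numeric(2))) else NULL
  structure(list(level = "region",
                 curve = data.frame(alpha = alpha_grid, TPR = curve[, 1],
                                    FPR = curve[, 2]),
                 auc = if (!is.null(roc)) roc_auc(roc[, 2], roc[, 1]) else 0.5),
            class = "corrseg_eval")
}

#' @export
print.corrseg_eval <- function(x, ...) {
  cat(sprintf("%s-level evaluation: AUC = %.4f\n", x$level, x$auc))
  invisible(x)
}

#' Detect correlated regions in a standardized expression matrix
#'
#' The core analysis: per chromosome, segment the genes into
#' equicorrelated blocks ([segment_chromosome()]), estimate the
#' background correlation ([estimate_rho0()]) and test every block
#' ([test_regions()]); then adjust p-values genome-wide.
#'
#' @param Y a standardized `expr_matrix` (any number of chromosomes).
#' @param S,K_max,rule passed to [segment_chromosome()].
#' @param rho0 optional known background correlation (scalar, applied
#'   to every chromosome); estimated per chromosome when `NULL`.
#' @param alpha significance level on adjusted p-values.
#' @param method genome-wide adjustment method.
#' @return Region table (data frame): `chromosome`, `start`, `end`
#'   (gene indices within chromosome), `first_gene`, `last_gene`,
#'   `p_k`, `rho`, `T`, `rho0`, `p_value`, `p_adj`, `significant`, plus
#'   genomic span columns `span_start`/`span_end`. Attributes `"K_hat"`
#'   and `"rho0"` record the per-chromosome fit.
#' @export
detect_correlated_regions <- function(Y, S = 0.7, K_max = NULL,
                                      rule = c("largest", "smallest"),
                                      rho0 = NULL, alpha = 0.05,
                                      method = c("BH", "bonferroni")) {
  stopifnot(inherits(Y, "expr_matrix"))
  if (!Y$standardized) stop("Y must be standardized")
  rule <- match.arg(rule)
  method <- match.arg(method)
  out <- list()
  K_hat <- rho0_hat <- c()
  for (chrom in chromosomes(Y)) {
    Yc <- subset_chromosome(Y, chrom)
    seg <- suppressWarnings(segment_chromosome(Yc, K_max = K_max, S = S,
                                               rule = rule))
    r0 <- if (is.null(rho0)) estimate_rho0(Yc)$rho0 else rho0
    tst <- test_regions(seg, Yc, rho0 = r0, method = "none")
    ann <- Yc$annotation
    tst$chromosome <- chrom
    tst$first_gene <- ann$gene_id[tst$start]
    tst$last_gene <- ann$gene_id[tst$end]
    tst$span_start <- ann$start[tst$start]
    tst$span_end <- ann$end[tst$end]
    out[[chrom]] <- tst
    K_hat[chrom] <- seg$K
    rho0_hat[chrom] <- r0
  }
  rt <- do.call(rbind, out)
  rownames(rt) <- NULL
  rt$p_adj <- adjust_pvalues(rt$p_value, method)
  rt$significant <- rt$p_adj <= alpha
  rt <- rt[, c("chromosome", "region", "start", "end", "first_gene",
               "last_gene", "p_k", "rho", "T", "rho0", "p_value",
               "p_adj", "significant", "span_start", "span_end")]
  attr(rt, "K_hat") <- K_hat
  attr(rt, "rho0") <- rho0_hat
  rt
}

#' Replicated end-to-end simulation benchmark
#'
#' For each replicate: simulate under `spec`, run the full detection
#' chain ([detect_correlated_regions()]) and score it at the gene and
#' region level. Fully seeded and deterministic.
#'
#' @param spec a [sim_spec()].
#' @param replicates number of replicates.
#' @param seed integer; replicate r uses seed `seed + r - 1`.
#' @param S,K_max,alpha,method passed to [detect_correlated_regions()].
#' @param alpha_grid levels for the evaluation curves.
#' @return List with `results` (data frame: replicate, gene- and
#'   region-level AUC) and `summary` (mean and sd of each AUC).
#' @export
run_benchmark <- function(spec, replicates = 20, seed = 1, S = 0.7,
                          K_max = NULL, alpha = 0.05, method = "BH",
                          alpha_grid = default_alpha_grid()) {
  res <- data.frame(replicate = seq_len(replicates),
                    auc_gene = NA_real_, auc_region = NA_real_)
  for (r in seq_len(replicates)) {
    sim <- simulate_expression(spec, seed = seed + r - 1)
    rt <- detect_correlated_regions(sim$expr, S = S, K_max = K_max,
                                    alpha = alpha, method = method)
    res$auc_gene[r] <- evaluate_gene_level(sim$truth, rt, alpha_grid)$auc
    res$auc_region[r] <- evaluate_region_level(sim$truth, rt, alpha_grid)$auc
  }
  list(results = res,
       summary = data.frame(level = c("gene", "region"),
                            mean_auc = c(mean(res$auc_gene),
                                         mean(res$auc_region)),
                            sd_auc = c(stats::sd(res$auc_gene),
                                       stats::sd(res$auc_region))))
}
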