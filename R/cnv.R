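#' Read per-patient SNP/CNV probe signal from a TSV file
#'
#' Expects columns `probe_id`, `chrom`, `pos`, then one numeric column
#' per patient. Probes are sorted by chromosome and position; positions
#' must be unique within a chromosome.
#'
#' @param path path to the SNP TSV.
#' @return List with `probes` (data frame `probe_id`, `chrom`, `pos`)
#'   and `signal` (numeric matrix, probes x patients).
#' @export
read_snp <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  need <- c("probe_id", "chrom", "pos")
  if (!all(need %in% names(dt)))
    stop("SNP file must have columns probe_id, chrom, pos, then patients")
  ord <- order(dt$chrom, dt$pos, method = "radix")
  dt <- dt[ord, , drop = FALSE]
  if (any(stats::ave(dt$pos, dt$chrom, FUN = function(x) duplicated(x)) == 1))
    stop("duplicate probe positions within a chromosome")
  sig <- as.matrix(dt[, setdiff(names(dt), need), drop = FALSE])
  if (!is.numeric(sig)) stop("non-numeric SNP signal values")
  rownames(sig) <- dt$probe_id
  list(probes = data.frame(probe_id = as.character(dt$probe_id),
                           chrom = as.character(dt$chrom),
                           pos = as.numeric(dt$pos),
                           stringsAsFactors = FALSE),
       signal = sig)
}

# least-squares cost matrix for piecewise-constant segmentation:
# cost[a, b] = residual sum of squares of segment [a..b] around its mean
ls_cost_matrix <- function(x) {
  m <- length(x)
  s1 <- c(0, cumsum(x))
  s2 <- c(0, cumsum(x^2))
  cost <- matrix(NA_real_, m, m)
  for (a in seq_len(m)) {
    b <- a:m
    len <- b - a + 1
    cost[a, b] <- pmax(s2[b + 1] - s2[a] - (s1[b + 1] - s1[a])^2 / len, 0)
  }
  cost
}

#' Segment one SNP profile into piecewise-constant means
#'
#' Fits the change-in-mean model SNP_t = mu_k + E_t (E_t i.i.d. centered
#' Gaussian) to a single patient's ordered probe signal by exact
#' least-squares dynamic programming. The number of segments is chosen
#' by the same slope heuristic as [select_K()], applied to the Gaussian
#' least-squares log-likelihood -(m/2) log(RSS_K / m); if one segment
#' already fits perfectly it is returned directly.
#'
#' @param x numeric vector of probe signal, ordered by genomic position
#'   (>= 2 probes).
#' @param K_max largest number of segments considered; default
#'   `min(floor(m/2), 40)`. Must not exceed the number of probes.
#' @param S slope-change threshold; default 0.7.
#' @param K optional fixed number of segments, bypassing model
#'   selection.
#' @return Object of class `corrseg_cnvseg`: list with `breakpoints`
#'   (tau_0 = 0 < ... < tau_K = m, probe indices), `means`, `lengths`,
#'   `sigma2` (residual variance), `K`, `fitted` (per-probe fitted
#'   mean).
#' @export
segment_snp_profile <- function(x, K_max = NULL, S = 0.7, K = NULL) {
  x <- as.numeric(x)
  m <- length(x)
  if (m < 2) stop("need at least 2 probes")
  if (is.null(K_max)) K_max <- default_K_max(m)
  if (K_max > m) stop("K_max (", K_max, ") exceeds the number of probes (", m, ")")
  if (!is.null(K) && (K < 1 || K > K_max)) stop("K must be in 1..K_max")
  cost <- ls_cost_matrix(x)
  dp <- dp_fill(cost, K_max)
  rss <- dp[, m]
  if (is.null(K)) {
    if (rss[1] < 1e-12 * max(1, sum(x^2))) {
      K <- 1L  # a single segment fits exactly (e.g. constant profile)
    } else {
      loglik <- -(m / 2) * log(pmax(rss, 1e-300) / m)
      K <- select_K(loglik, m, S = S)$K_hat
    }
  }
  tau <- dp_backtrack(dp, cost, K)
  starts <- tau[-(K + 1)] + 1L
  ends <- tau[-1]
  means <- vapply(seq_len(K), function(k) mean(x[starts[k]:ends[k]]),
                  numeric(1))
  lens <- ends - starts + 1L
  structure(list(breakpoints = tau, means = means, lengths = lens,
                 sigma2 = rss[K] / m, K = K,
                 fitted = rep(means, lens)),
            class = "corrseg_cnvseg")
}

#' @export
print.corrseg_cnvseg <- function(x, ...) {
  cat(sprintf("SNP profile segmentation: %d segment(s), sigma2 = %.4g\n",
              x$K, x$sigma2))
  print(data.frame(start = x$breakpoints[-(x$K + 1)] + 1L,
                   end = x$breakpoints[-1], mean = x$means),
        row.names = FALSE)
  invisible(x)
}

#' Segment every patient profile of a SNP dataset
#'
#' Applies [segment_snp_profile()] per patient and per chromosome and
#' collects the fitted per-probe segment means.
#'
#' @param snp a list as returned by [read_snp()].
#' @param K_max,S passed to [segment_snp_profile()].
#' @return List with `fitted` (matrix, probes x patients, of fitted
#'   segment means, rows aligned with `snp$probes`) and `fits` (nested
#'   list, per chromosome then patient, of `corrseg_cnvseg`).
#' @export
segment_snp_matrix <- function(snp, K_max = NULL, S = 0.7) {
  fitted <- snp$signal
  fitted[] <- NA_real_
  fits <- list()
  for (chrom in unique(snp$probes$chrom)) {
    rows <- which(snp$probes$chrom == chrom)
    fits[[chrom]] <- lapply(seq_len(ncol(snp$signal)), function(i) {
      f <- segment_snp_profile(snp$signal[rows, i], K_max = K_max, S = S)
      fitted[rows, i] <<- f$fitted
      f
    })
    names(fits[[chrom]]) <- colnames(snp$signal)
  }
  list(fitted = fitted, fits = fits)
}

#' Map segmented probe means to a per-gene copy-number covariate
#'
#' Builds the covariate x_ij (patient i, gene j) from fitted SNP
#' segment means: a gene overlapped by one probe takes that probe's
#' fitted mean; several probes, the average of their fitted means; no
#' probe, linear interpolation of the flanking probes' fitted values at
#' the gene midpoint; genes beyond the outermost probe take the nearest
#' probe's value.
#'
#' @param fitted matrix of fitted per-probe segment means
#'   (probes x patients), e.g. `segment_snp_matrix()$fitted`.
#' @param probes data frame `probe_id`, `chrom`, `pos` aligned with the
#'   rows of `fitted` (positions 1-based).
#' @param annotation gene annotation data frame in chromosomal order
#'   (0-based half-open intervals).
#' @return Object of class `corrseg_cnv_covariate`: list with `x`
#'   (matrix, patients x genes, gene order as `annotation`) and
#'   `provenance` (per gene: `"averaged"`, `"interpolated"` or
#'   `"nearest"`).
#' @export
map_probes_to_genes <- function(fitted, probes, annotation) {
  annotation <- validate_annotation(annotation)
  n_pat <- ncol(fitted)
  p <- nrow(annotation)
  x <- matrix(NA_real_, n_pat, p)
  colnames(x) <- annotation$gene_id
  rownames(x) <- colnames(fitted)
  prov <- character(p)
  for (chrom in unique(annotation$chromosome)) {
    g_idx <- which(annotation$chromosome == chrom)
    pr <- which(probes$chrom == chrom)
    if (length(pr) == 0)
      stop("no SNP probes on chromosome '", chrom, "'")
    pos <- probes$pos[pr]
    Fc <- fitted[pr, , drop = FALSE]
    for (g in g_idx) {
      lo <- annotation$start[g]  # 0-based half-open: covers bp lo+1 .. hi
      hi <- annotation$end[g]
      inside <- which(pos > lo & pos <= hi)
      if (length(inside) >= 1) {
        x[, g] <- colMeans(Fc[inside, , drop = FALSE])
        prov[g] <- "averaged"
      } else {
        mid <- (lo + hi) / 2
        if (mid <= pos[1]) {
          x[, g] <- Fc[1, ]
          prov[g] <- "nearest"
        } else if (mid >= pos[length(pos)]) {
          x[, g] <- Fc[length(pos), ]
          prov[g] <- "nearest"
        } else {
          i <- findInterval(mid, pos)
          w <- (mid - pos[i]) / (pos[i + 1] - pos[i])
          x[, g] <- (1 - w) * Fc[i, ] + w * Fc[i + 1, ]
          prov[g] <- "interpolated"
        }
      }
    }
  }
  structure(list(x = x, provenance = prov, annotation = annotation),
            class = "corrseg_cnv_covariate")
}

#' Regress expression on a copy-number covariate
#'
#' Fits Y_ij = beta0 + beta1 x_ij + eps_ij by ordinary least squares
#' and returns the residuals as the corrected signal. The default
#' (`mode = "global"`) fits a single (beta0, beta1) over all patient ×
#' gene pairs of the chromosome, which is valid under independence
#' across patients only; `mode = "per-gene"` fits each gene column
#' separately. With `zero_policy = "drop-zero"`, exact zeros of Y
#' (typical of RNA-seq) are excluded from the fit and their residuals
#' set to 0 so they do not contribute to between-gene correlation.
#'
#' @param Y an unstandardized `expr_matrix` (typically log scale) or a
#'   numeric matrix, patients x genes.
#' @param x covariate: a `corrseg_cnv_covariate` or a numeric matrix of
#'   the same shape as `Y`.
#' @param mode `"global"` (default) or `"per-gene"`.
#' @param zero_policy `"keep"` (default: all values enter the fit) or
#'   `"drop-zero"`.
#' @return Same type as `Y`, holding the residuals (unstandardized),
#'   with attribute `"fit"` carrying `beta0`/`beta1` (scalars under
#'   `"global"`, per-gene vectors otherwise). A zero-variance covariate
#'   degenerates to centering, with a warning in global mode.
#' @export
correct_expression <- function(Y, x, mode = c("global", "per-gene"),
                               zero_policy = c("keep", "drop-zero")) {
  mode <- match.arg(mode)
  zero_policy <- match.arg(zero_policy)
  is_em <- inherits(Y, "expr_matrix")
  v <- if (is_em) Y$values else as.matrix(Y)
  if (inherits(x, "corrseg_cnv_covariate")) x <- x$x
  x <- as.matrix(x)
  if (!all(dim(x) == dim(v)))
    stop("covariate shape ", paste(dim(x), collapse = "x"),
         " does not match expression ", paste(dim(v), collapse = "x"))
  use <- if (zero_policy == "drop-zero") v != 0 else
    matrix(TRUE, nrow(v), ncol(v))
  ols <- function(yv, xv) {
    vx <- stats::var(xv)
    if (!is.finite(vx) || vx == 0) c(b0 = mean(yv), b1 = 0)
    else {
      b1 <- stats::cov(xv, yv) / vx
      c(b0 = mean(yv) - b1 * mean(xv), b1 = b1)
    }
  }
  if (mode == "global") {
    if (stats::var(as.vector(x[use])) == 0)
      warning("covariate has zero variance; falling back to beta1 = 0 (centering)")
    b <- ols(as.vector(v[use]), as.vector(x[use]))
    res <- v - b["b0"] - b["b1"] * x
    fit <- list(beta0 = unname(b["b0"]), beta1 = unname(b["b1"]), mode = mode)
  } else {
    b0 <- b1 <- numeric(ncol(v))
    res <- v
    for (j in seq_len(ncol(v))) {
      w <- use[, j]
      b <- ols(v[w, j], x[w, j])
      b0[j] <- b["b0"]; b1[j] <- b["b1"]
      res[, j] <- v[, j] - b["b0"] - b["b1"] * x[, j]
    }
    fit <- list(beta0 = b0, beta1 = b1, mode = mode)
  }
  res[!use] <- 0
  if (is_em) {
    Y$values <- res
    Y$standardized <- FALSE
    attr(Y, "fit") <- fit
    Y
  } else structure(res, fit = fit)
}

#' CNV-corrected, standardized expression ready for segmentation
#'
#' Full correction chain: log(1 + x) transform (optional), removal of
#' degenerate genes, per-patient per-chromosome SNP segmentation,
#' probe-to-gene covariate mapping, per-chromosome OLS correction, and
#' re-standardization of the residuals.
#'
#' @param Y a raw `expr_matrix` (non-negative values if
#'   `log = TRUE`).
#' @param snp SNP data as returned by [read_snp()]; patient columns
#'   must match the patient rows of `Y` (by name if both are named).
#' @param mode,zero_policy passed to [correct_expression()].
#' @param K_max,S passed to [segment_snp_profile()].
#' @param log apply [log_transform()] first; default `TRUE`.
#' @return A standardized `expr_matrix` of corrected expression, with
#'   the covariate attached as attribute `"cnv_covariate"`.
#' @export
corrected_pipeline <- function(Y, snp, mode = c("global", "per-gene"),
                               zero_policy = c("keep", "drop-zero"),
                               K_max = NULL, S = 0.7, log = TRUE) {
  mode <- match.arg(mode)
  zero_policy <- match.arg(zero_policy)
  stopifnot(inherits(Y, "expr_matrix"))
  pat <- rownames(Y$values)
  if (!is.null(pat) && !is.null(colnames(snp$signal))) {
    if (!all(pat %in% colnames(snp$signal)))
      stop("SNP data lacks patients: ",
           paste(setdiff(pat, colnames(snp$signal)), collapse = ", "))
    snp$signal <- snp$signal[, pat, drop = FALSE]
  } else if (ncol(snp$signal) != nrow(Y$values)) {
    stop("SNP patient columns do not match expression patients")
  }
  if (log) Y <- log_transform(Y)
  Y <- drop_degenerate_genes(Y)
  segs <- segment_snp_matrix(snp, K_max = K_max, S = S)
  cov <- map_probes_to_genes(segs$fitted, snp$probes, Y$annotation)
  corrected <- Y
  for (chrom in chromosomes(Y)) {
    cols <- which(Y$annotation$chromosome == chrom)
    res <- correct_expression(Y$values[, cols, drop = FALSE],
                              cov$x[, cols, drop = FALSE],
                              mode = mode, zero_policy = zero_policy)
    corrected$values[, cols] <- as.matrix(res)
  }
  corrected <- drop_degenerate_genes(corrected)
  out <- standardize(corrected)
  attr(out, "cnv_covariate") <- cov
  out
}
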