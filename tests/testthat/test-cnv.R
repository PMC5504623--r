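test_that("SNP profile segmentation: constant, stepped and brute-force cases", {
  f <- segment_snp_profile(rep(2.5, 50))
  expect_equal(f$K, 1L)
  expect_equal(f$means, 2.5)
  # clear step at probe 100 recovered within 2 probes across seeds
  hits <- 0L
  for (s in 1:20) {
    set.seed(600 + s)
    x <- c(rnorm(100, 0, 0.1), rnorm(100, 1, 0.1))
    f <- segment_snp_profile(x)
    hits <- hits + any(abs(f$breakpoints[-c(1, f$K + 1)] - 100) <= 2)
  }
  expect_gte(hits, 18L)
  # fixed K = 2 on 8 probes equals exhaustive search over the 7 cuts
  set.seed(61)
  for (r in 1:10) {
    x <- rnorm(8)
    f2 <- segment_snp_profile(x, K_max = 4, K = 2)
    rss <- sapply(1:7, function(cut)
      sum((x[1:cut] - mean(x[1:cut]))^2) +
      sum((x[(cut + 1):8] - mean(x[(cut + 1):8]))^2))
    expect_equal(f2$breakpoints[2], which.min(rss))
    expect_equal(f2$sigma2 * 8, min(rss), tolerance = 1e-10)
  }
  expect_error(segment_snp_profile(rnorm(5), K_max = 6), "exceeds")
})

test_that("SNP dynamic program equals enumeration on small profiles", {
  set.seed(71)
  for (r in 1:10) {
    m <- sample(6:10, 1)
    x <- rnorm(m)
    cost <- corrseg:::ls_cost_matrix(x)
    for (K in 1:3) {
      f <- segment_snp_profile(x, K_max = m, K = K)
      oracle <- enumerate_best(cost, K)
      expect_equal(sum((x - f$fitted)^2), oracle$cost, tolerance = 1e-10)
      expect_equal(f$breakpoints, oracle$tau)
    }
  }
})

test_that("probe-to-gene mapping averages, interpolates and extrapolates", {
  ann <- data.frame(gene_id = c("gA", "gB", "gC", "gD", "gE"),
                    chromosome = "chr1",
                    start = c(0, 1000, 2000, 3000, 4000),
                    end = c(500, 1500, 2500, 3500, 4500))
  probes <- data.frame(probe_id = c("p1", "p2", "p3", "p4"),
                       chrom = "chr1", pos = c(250, 1100, 1400, 2750))
  # one patient; fitted segment means chosen by hand
  fitted <- matrix(c(2.0, 1.0, 3.0, 8.0), 4, 1)
  cov <- map_probes_to_genes(fitted, probes, ann)
  expect_equal(unname(cov$x[1, "gA"]), 2.0)          # single probe
  expect_equal(unname(cov$x[1, "gB"]), 2.0)          # average of 1 and 3
  expect_equal(cov$provenance[1:2], c("averaged", "averaged"))
  # gC midpoint 2250 between p3 (1400 -> 3) and p4 (2750 -> 8):
  # weight (2250-1400)/(2750-1400) = 0.6296...
  w <- (2250 - 1400) / (2750 - 1400)
  expect_equal(unname(cov$x[1, "gC"]), (1 - w) * 3 + w * 8)
  expect_equal(cov$provenance[3], "interpolated")
  # gD, gE beyond the outermost probe: nearest value
  expect_equal(unname(cov$x[1, "gD"]), 8.0)
  expect_equal(cov$provenance[4], "nearest")
  # exact midpoint halfway between flanking probes -> mean of the two
  ann2 <- data.frame(gene_id = "g1", chromosome = "chr1",
                     start = 900, end = 1100)
  probes2 <- data.frame(probe_id = c("a", "b"), chrom = "chr1",
                        pos = c(500, 1500))
  cov2 <- map_probes_to_genes(matrix(c(0, 1), 2, 1), probes2, ann2)
  expect_equal(unname(cov2$x[1, 1]), 0.5)
  # chromosome without probes is an error
  expect_error(map_probes_to_genes(fitted, probes,
                                   transform(ann, chromosome = "chr9")),
               "no SNP probes")
})

test_that("expression correction reproduces OLS and its orthogonality", {
  set.seed(81)
  n <- 12; p <- 7
  x <- matrix(rnorm(n * p, 2, 1), n, p)
  # exact linear signal -> zero residuals
  Y0 <- 1.5 + 2 * x
  expect_lt(max(abs(correct_expression(Y0, x))), 1e-10)
  # random response: coefficients match lm on the pooled pairs
  Y <- 0.5 + 0.8 * x + matrix(rnorm(n * p), n, p)
  res <- correct_expression(Y, x)
  fit <- attr(res, "fit")
  ref <- lm(as.vector(Y) ~ as.vector(x))
  expect_equal(fit$beta0, unname(coef(ref)[1]), tolerance = 1e-10)
  expect_equal(fit$beta1, unname(coef(ref)[2]), tolerance = 1e-10)
  expect_lt(abs(sum(res)), 1e-8)
  expect_lt(abs(sum(res * x)), 1e-8)
  # per-gene mode matches column-wise lm
  resg <- correct_expression(Y, x, mode = "per-gene")
  fitg <- attr(resg, "fit")
  for (j in c(1, 4)) {
    refj <- lm(Y[, j] ~ x[, j])
    expect_equal(fitg$beta1[j], unname(coef(refj)[2]), tolerance = 1e-10)
  }
  # constant covariate: centering fallback with a warning
  expect_warning(resc <- correct_expression(Y, matrix(1, n, p)), "zero variance")
  expect_equal(as.vector(resc), as.vector(Y - mean(Y)), tolerance = 1e-12)
})

test_that("drop-zero policy excludes zeros from the fit and zeroes residuals", {
  set.seed(82)
  x <- matrix(rnorm(40, 2), 8, 5)
  Y <- 1 + 0.5 * x + matrix(rnorm(40, 0, .2), 8, 5)
  Y[1, 1] <- 0; Y[5, 3] <- 0
  res <- correct_expression(Y, x, zero_policy = "drop-zero")
  fit <- attr(res, "fit")
  keep <- Y != 0
  ref <- lm(Y[keep] ~ x[keep])
  expect_equal(fit$beta1, unname(coef(ref)[2]), tolerance = 1e-10)
  expect_equal(res[1, 1], 0)
  expect_equal(res[5, 3], 0)
})

test_that("CNV-driven correlation is removed by the corrected pipeline", {
  # expression correlation induced solely by a shared copy-number state:
  # patients carry a gain over genes 21-35 with patient-specific dosage
  n <- 60; p <- 60
  make_data <- function(seed) {
    set.seed(seed)
    ann <- data.frame(gene_id = sprintf("g%03d", 1:p), chromosome = "chr1",
                      start = (0:(p - 1)) * 1000, end = (1:p) * 1000 - 100)
    dosage <- rnorm(n, 0, 1)           # per-patient CNV level of the region
    xtrue <- matrix(0, n, p)
    xtrue[, 21:35] <- dosage
    # log-scale expression with a linear copy-number effect
    Y <- 5 + 1.2 * xtrue + matrix(rnorm(n * p, 0, 1), n, p)
    colnames(Y) <- ann$gene_id
    # SNP probes every other gene, signal = true dosage + noise
    probes <- data.frame(probe_id = sprintf("pr%03d", 1:(p / 2)),
                         chrom = "chr1", pos = seq(500, by = 2000,
                                                   length.out = p / 2))
    sig <- xtrue[, seq(1, p, by = 2)] + matrix(rnorm(n * p / 2, 0, 0.1),
                                               n, p / 2)
    snp <- list(probes = probes, signal = t(sig))
    rownames(snp$signal) <- probes$probe_id
    list(expr = expression_matrix(Y, ann), snp = snp)
  }
  sig_raw <- sig_cor <- rho0_raw <- rho0_cor <- numeric(0)
  for (s in 1:8) {
    d <- make_data(700 + s)
    raw <- standardize(drop_degenerate_genes(d$expr))
    rt_raw <- suppressWarnings(detect_correlated_regions(raw))
    corr <- suppressMessages(corrected_pipeline(d$expr, d$snp, log = FALSE))
    rt_cor <- suppressWarnings(detect_correlated_regions(corr))
    in_region <- function(rt) any(rt$significant & rt$start <= 35 & rt$end >= 21)
    sig_raw <- c(sig_raw, in_region(rt_raw))
    sig_cor <- c(sig_cor, in_region(rt_cor))
    rho0_raw <- c(rho0_raw, estimate_rho0(raw)$rho0)
    rho0_cor <- c(rho0_cor, estimate_rho0(corr)$rho0)
  }
  expect_gte(sum(sig_raw), 7)        # CNV region detected on the raw signal
  expect_lte(sum(sig_cor), 1)        # and gone after correction
  expect_lt(mean(rho0_cor), mean(rho0_raw))
})

test_that("an all-zero covariate leaves the standardized signal unchanged", {
  set.seed(91)
  ann <- data.frame(gene_id = sprintf("g%02d", 1:10), chromosome = "chr1",
                    start = (0:9) * 100, end = (1:10) * 100 - 10)
  Y <- expression_matrix(matrix(abs(rnorm(80, 3)), 8, 10,
                                dimnames = list(NULL, ann$gene_id)), ann)
  probes <- data.frame(probe_id = c("a", "b"), chrom = "chr1", pos = c(50, 850))
  snp <- list(probes = probes,
              signal = matrix(0, 2, 8, dimnames = list(c("a", "b"), NULL)))
  out <- suppressWarnings(corrected_pipeline(Y, snp, log = TRUE))
  ref <- standardize(log_transform(Y))
  expect_equal(out$values, ref$values, tolerance = 1e-10)
})
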