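test_that("generated data match their own correlation specification", {
  # no regions, rho0 = 0: empirical correlations inside the null envelope
  sim0 <- simulate_expression(sim_spec(scenario1_design(
    p = 30, region_starts = integer(0), region_lengths = integer(0),
    rho0 = 0), n = 200), seed = 10)
  C <- cor(sim0$expr$values)
  expect_lt(max(abs(C[upper.tri(C)])), 6 / sqrt(200))
  # planted regions at rho1 = 0.9: empirical within-region mean close
  off_mean <- function(M) mean(M[upper.tri(M)])
  within <- sapply(1:10, function(s) {
    sim <- simulate_expression(sim_spec(scenario1_design(rho0 = 0.08),
                                        n = 100, rho1 = 0.9), seed = s)
    regs <- sim$truth$regions
    mean(sapply(seq_len(nrow(regs)), function(r)
      off_mean(cor(sim$expr$values[, regs$start[r]:regs$end[r]]))))
  })
  expect_lt(abs(mean(within) - 0.9), 0.05)
  # background adjacent-pair correlation matches rho0 at large n
  simb <- simulate_expression(sim_spec(scenario1_design(
    p = 80, region_starts = integer(0), region_lengths = integer(0),
    rho0 = 0.18), n = 1000), seed = 3)
  expect_lt(abs(estimate_rho0(simb$expr)$rho0 - 0.18), 0.05)
  # truth labels are consistent with the stated boundaries
  sim <- simulate_expression(sim_spec(scenario1_design(rho0 = 0.08),
                                      n = 20, rho1 = 0.5), seed = 1)
  h1 <- rep(FALSE, 500)
  for (r in seq_len(nrow(sim$truth$regions)))
    h1[sim$truth$regions$start[r]:sim$truth$regions$end[r]] <- TRUE
  expect_identical(sim$truth$genes$h1, h1)
})

test_that("Wishart block draws concentrate around the scale as beta grows", {
  set.seed(17)
  maxdev <- sapply(c(1, 3, 5), function(beta) {
    devs <- replicate(40, {
      R <- corrseg:::draw_wishart_correlation(10, 0.5, 10 * 2^beta)
      max(abs(R[upper.tri(R)] - 0.5))
    })
    mean(devs)
  })
  expect_true(all(diff(maxdev) < 0))
  # scenario 3 end to end: simulated blocks carry elevated correlation
  d <- scenario1_design(p = 100, region_starts = 41, region_lengths = 20,
                        rho0 = 0.18)
  sim3 <- simulate_expression(sim_spec(d, n = 300, scenario = 3, beta = 3),
                              seed = 21)
  C <- cor(sim3$expr$values[, 41:60])
  expect_gt(mean(C[upper.tri(C)]), 0.35)
  expect_equal(sim3$truth$regions$rho, 0.5, tolerance = 0.15)
})

test_that("gene-level evaluation: perfect, empty and hand-counted cases", {
  truth <- structure(list(genes = data.frame(
    chrom = "chr1", index = 1:10, gene_id = sprintf("g%02d", 1:10),
    h1 = c(rep(FALSE, 3), rep(TRUE, 4), rep(FALSE, 3)),
    rho = 0.1)), class = "corrseg_sim_truth")
  perfect <- data.frame(chromosome = "chr1", start = c(1, 4, 8),
                        end = c(3, 7, 10), p_adj = c(1, 1e-9, 1))
  ev <- evaluate_gene_level(truth, perfect)
  expect_equal(ev$auc, 1)
  expect_equal(ev$curve$TPR[ev$curve$alpha >= 1e-8], rep(1, sum(ev$curve$alpha >= 1e-8)))
  nothing <- data.frame(chromosome = "chr1", start = 1, end = 10, p_adj = 1)
  # a single region covering everything, never called at alpha < 1:
  ev0 <- evaluate_gene_level(truth,
                             transform(nothing, p_adj = Inf)[0, , drop = FALSE])
  expect_equal(ev0$auc, 0.5)
  expect_true(all(ev0$curve$TPR == 0))
  # hand-built: region 4..8 called at 0.01 -> TP = 4, FP = 1
  part <- data.frame(chromosome = "chr1", start = c(1, 4, 9),
                     end = c(3, 8, 10), p_adj = c(0.9, 0.01, 0.9))
  ev2 <- evaluate_gene_level(truth, part, alpha_grid = 0.05)
  expect_equal(ev2$curve$TPR, 4 / 4)
  expect_equal(ev2$curve$FPR, 1 / 6)
})

test_that("region-level evaluation merges status runs and counts regions", {
  truth <- structure(list(genes = data.frame(
    chrom = "chr1", index = 1:20, gene_id = sprintf("g%02d", 1:20),
    h1 = c(rep(FALSE, 5), rep(TRUE, 6), rep(FALSE, 9)), rho = 0.1)),
    class = "corrseg_sim_truth")
  # exact segmentation, region called -> TP = 1, FN = 0, TPR = 1
  exact <- data.frame(chromosome = "chr1", start = c(1, 6, 12),
                      end = c(5, 11, 20), p_adj = c(1, 1e-6, 1))
  ev <- evaluate_region_level(truth, exact, alpha_grid = 0.05)
  expect_equal(ev$curve$TPR, 1)
  expect_equal(ev$curve$FPR, 0)
  # called region shifted by 2 on both sides (called genes 4..9):
  # statuses: TN(1-3), FP(4-5), TP(6-9), FN(10-11), TN(12-20)
  # -> TP=1, FN=1, FP=1, TN=2: TPR = 1/2, FPR = 1/3
  shifted <- data.frame(chromosome = "chr1", start = c(1, 4, 10),
                        end = c(3, 9, 20), p_adj = c(1, 1e-6, 1))
  ev2 <- evaluate_region_level(truth, shifted, alpha_grid = 0.05)
  expect_equal(ev2$curve$TPR, 1 / 2)
  expect_equal(ev2$curve$FPR, 1 / 3)
  # truth without any region: TPR undefined (NA), FPR = 0 when nothing called
  truth0 <- structure(list(genes = data.frame(
    chrom = "chr1", index = 1:8, gene_id = sprintf("g%02d", 1:8),
    h1 = FALSE, rho = 0.1)), class = "corrseg_sim_truth")
  none <- data.frame(chromosome = "chr1", start = 1, end = 8, p_adj = 1)
  ev3 <- evaluate_region_level(truth0, none, alpha_grid = 0.05)
  expect_true(is.na(ev3$curve$TPR))
  expect_equal(ev3$curve$FPR, 0)
})

test_that("AUC is invariant under monotone p-value transforms; metrics under relabeling", {
  sim <- simulate_expression(sim_spec(scenario1_design(
    p = 150, region_starts = c(31, 91), region_lengths = c(8, 15),
    rho0 = 0.1), n = 80, rho1 = 0.7), seed = 33)
  rt <- suppressWarnings(detect_correlated_regions(sim$expr))
  ev <- evaluate_gene_level(sim$truth, rt)
  rt2 <- rt
  rt2$p_adj <- rt$p_adj^2          # strictly monotone transform
  expect_equal(evaluate_gene_level(sim$truth, rt2)$auc, ev$auc)
  evr <- evaluate_region_level(sim$truth, rt)
  rt3 <- rt
  rt3$p_adj <- 1 - exp(-5 * rt$p_adj)
  expect_equal(evaluate_region_level(sim$truth, rt3)$auc, evr$auc)
  # shuffling patients or shifting genes before standardization changes nothing
  Yp <- sim$expr
  set.seed(1)
  Yp$values <- Yp$values[sample(nrow(Yp$values)), ]
  rtp <- suppressWarnings(detect_correlated_regions(Yp))
  expect_equal(evaluate_region_level(sim$truth, rtp)$curve,
               evr$curve)
})

test_that("benchmark is deterministic and region level is the stricter criterion", {
  spec <- sim_spec(scenario1_design(p = 120, region_starts = c(31, 71),
                                    region_lengths = c(10, 20), rho0 = 0.08),
                   n = 60, rho1 = 0.7)
  b1 <- run_benchmark(spec, replicates = 3, seed = 7)
  b2 <- run_benchmark(spec, replicates = 3, seed = 7)
  expect_identical(b1, b2)
  expect_true(all(b1$results$auc_region <= b1$results$auc_gene + 1e-12))
})

test_that("the packaged genome-shaped design is valid and simulable", {
  d <- scenario2_design()
  expect_equal(nrow(d$chromosomes), 22L)
  expect_true(all(d$chromosomes$rho0 >= 0.05 & d$chromosomes$rho0 <= 0.28))
  spec <- sim_spec(d, n = 10, rho1 = 0.6, scenario = 2)
  sim <- simulate_expression(spec, seed = 2)
  expect_equal(length(chromosomes(sim$expr)), 22L)
  expect_equal(ncol(sim$expr$values), sum(d$chromosomes$p))
  # per-chromosome region counts match the design
  tab <- table(sim$truth$regions$chrom)
  tab_d <- table(d$regions$chrom)
  expect_equal(as.vector(tab[names(tab_d)]), as.vector(tab_d))
})

test_that("infeasible simulation designs are refused", {
  expect_error(sim_spec(scenario1_design(p = 50, region_starts = 48,
                                         region_lengths = 10)),
               "does not fit")
  expect_error(sim_spec(scenario1_design(rho0 = 0.4), rho1 = 0.3),
               "rho1")
  expect_error(sim_spec(scenario1_design(), scenario = 3), "beta")
  expect_error(corrseg:::draw_wishart_correlation(10, 0.5, 5), "degrees")
})
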