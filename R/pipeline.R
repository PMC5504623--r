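#' Pipeline configuration
#'
#' Collects all tunable parameters of the end-to-end analysis, with the
#' package defaults (slope threshold S = 0.7, level alpha = 0.05, BH
#' adjustment, global CNV regression keeping zeros). Values can come
#' from a YAML file, from the `...` overrides, or both — explicit
#' overrides win over the file, which wins over the defaults.
#'
#' @param yaml optional path to a YAML file whose keys mirror the
#'   configuration fields.
#' @param ... named overrides of individual fields: `expression`,
#'   `annotation`, `snp`, `out`, `correct`, `log_transform`, `S`,
#'   `K_max`, `rule`, `alpha`, `adjust`, `mode`, `zero_policy`,
#'   `alpha_grid`, `seed`.
#' @return A named list of class `corrseg_config`.
#' @export
pipeline_config <- function(yaml = NULL, ...) {
  cfg <- list(expression = NULL, annotation = NULL, snp = NULL, out = NULL,
              correct = FALSE, log_transform = FALSE, S = 0.7, K_max = NULL,
              rule = "largest", alpha = 0.05, adjust = "BH", mode = "global",
              zero_policy = "keep", alpha_grid = NULL, seed = NULL)
  if (!is.null(yaml)) {
    from_file <- yaml::read_yaml(yaml)
    bad <- setdiff(names(from_file), names(cfg))
    if (length(bad)) stop("unknown configuration key(s): ",
                          paste(bad, collapse = ", "))
    cfg[names(from_file)] <- from_file
  }
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown configuration key(s): ",
                        paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  stopifnot(cfg$S > 0, cfg$alpha > 0, cfg$alpha < 1)
  cfg$adjust <- match.arg(cfg$adjust, c("BH", "bonferroni"))
  cfg$mode <- match.arg(cfg$mode, c("global", "per-gene"))
  cfg$zero_policy <- match.arg(cfg$zero_policy, c("keep", "drop-zero"))
  cfg$rule <- match.arg(cfg$rule, c("largest", "smallest"))
  structure(cfg, class = "corrseg_config")
}

#' Run the full detection pipeline from files
#'
#' Reads annotation and expression (and, if correction is requested,
#' SNP data), applies the optional log(1+x) transform and CNV
#' correction, standardizes, then per chromosome segments, estimates
#' the background correlation and tests every region, adjusting
#' p-values genome-wide. Writes the region table as TSV, a BED export
#' of the significant regions, and a JSON run summary (per-chromosome
#' K-hat, rho0-hat and region counts) next to it.
#'
#' @param config a [pipeline_config()] with at least `expression`,
#'   `annotation` and `out` set.
#' @return The region table (see [detect_correlated_regions()]),
#'   invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "corrseg_config"))
  if (is.null(config$expression) || is.null(config$annotation))
    stop("config must provide 'expression' and 'annotation' paths")
  if (!is.null(config$seed)) set.seed(config$seed)
  ann <- read_annotation(config$annotation)
  Y <- read_expression(config$expression, ann)
  if (isTRUE(config$correct)) {
    if (is.null(config$snp)) stop("correction requested but no 'snp' path given")
    snp <- read_snp(config$snp)
    Y <- corrected_pipeline(Y, snp, mode = config$mode,
                            zero_policy = config$zero_policy,
                            K_max = config$K_max, S = config$S,
                            log = isTRUE(config$log_transform))
  } else {
    if (isTRUE(config$log_transform)) Y <- log_transform(Y)
    Y <- drop_degenerate_genes(Y)
    Y <- standardize(Y)
  }
  rt <- detect_correlated_regions(Y, S = config$S, K_max = config$K_max,
                                  rule = config$rule, alpha = config$alpha,
                                  method = config$adjust)
  if (!is.null(config$out)) {
    write_region_table(rt, config$out)
    bed <- sub("\\.tsv$", "", config$out)
    export_regions_bed(rt, paste0(bed, ".bed"), significant_only = TRUE)
    summary <- list(n_patients = nrow(Y$values), n_genes = ncol(Y$values),
                    chromosomes = chromosomes(Y),
                    K_hat = as.list(attr(rt, "K_hat")),
                    rho0 = as.list(attr(rt, "rho0")),
                    n_regions = nrow(rt),
                    n_significant = sum(rt$significant),
                    S = config$S, alpha = config$alpha,
                    adjust = config$adjust,
                    corrected = isTRUE(config$correct))
    jsonlite::write_json(summary, paste0(bed, "_summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(rt)
}

#' Write / read a region table as TSV
#'
#' @param rt region table from [detect_correlated_regions()].
#' @param path output (input) path.
#' @return `path` invisibly (`read_region_table` returns the table).
#' @export
write_region_table <- function(rt, path) {
  data.table::fwrite(as.data.frame(rt), path, sep = "\t")
  invisible(path)
}

#' @rdname write_region_table
#' @export
read_region_table <- function(path) {
  data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
}

#' Export regions to BED
#'
#' Writes one BED interval per region, spanning from the first gene's
#' start to the last gene's end, with the region's adjusted p-value as
#' score name.
#'
#' @param rt region table.
#' @param path output BED path.
#' @param significant_only keep only significant regions (default
#'   `TRUE`).
#' @return `path`, invisibly.
#' @export
export_regions_bed <- function(rt, path, significant_only = TRUE) {
  if (significant_only) rt <- rt[rt$significant %in% TRUE, , drop = FALSE]
  if (nrow(rt) == 0) {
    file.create(path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = rt$chromosome,
    ranges = IRanges::IRanges(start = rt$span_start + 1, end = rt$span_end),
    name = sprintf("%s:%s-%s|p_adj=%.3g", rt$chromosome, rt$first_gene,
                   rt$last_gene, rt$p_adj))
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Stability of the detections across the selection threshold S
#'
#' Re-runs model selection and region testing on a grid of slope
#' thresholds, reusing the dynamic program of each chromosome, and
#' reports the number of segments and of significant regions per S.
#' Smaller S never yields fewer segments.
#'
#' @param Y standardized `expr_matrix`.
#' @param S_grid numeric vector of thresholds.
#' @param K_max,rule passed to the segmentation.
#' @param alpha,method significance level and genome-wide adjustment.
#' @param rho0 optional known background correlation.
#' @return Data frame with one row per S: `S`, `n_segments`,
#'   `n_significant`, and `signature` (a string identifying the set of
#'   significant gene spans, for stability inspection).
#' @export
sensitivity_scan_S <- function(Y, S_grid, K_max = NULL,
                               rule = c("largest", "smallest"),
                               alpha = 0.05, method = "BH", rho0 = NULL) {
  stopifnot(inherits(Y, "expr_matrix"), Y$standardized)
  rule <- match.arg(rule)
  chroms <- chromosomes(Y)
  dps <- list(); r0s <- c()
  for (chrom in chroms) {
    Yc <- subset_chromosome(Y, chrom)
    dps[[chrom]] <- segment_dp(Yc$values, if (is.null(K_max))
      default_K_max(ncol(Yc$values)) else K_max)
    r0s[chrom] <- if (is.null(rho0)) estimate_rho0(Yc)$rho0 else rho0
  }
  out <- data.frame(S = sort(S_grid, decreasing = TRUE),
                    n_segments = NA_integer_, n_significant = NA_integer_,
                    signature = NA_character_)
  for (i in seq_len(nrow(out))) {
    S <- out$S[i]
    tabs <- list()
    nseg <- 0L
    for (chrom in chroms) {
      dp <- dps[[chrom]]
      Khat <- select_K(dp$loglik, dp$p, S = S, rule = rule)$K_hat
      seg <- dp$segmentations[[Khat]]
      nseg <- nseg + seg$K
      tst <- test_regions(seg, subset_chromosome(Y, chrom),
                          rho0 = r0s[chrom], method = "none")
      tst$chromosome <- chrom
      tabs[[chrom]] <- tst
    }
    rt <- do.call(rbind, tabs)
    rt$p_adj <- adjust_pvalues(rt$p_value, method)
    sig <- rt[rt$p_adj <= alpha, , drop = FALSE]
    out$n_segments[i] <- nseg
    out$n_significant[i] <- nrow(sig)
    out$signature[i] <- paste(sprintf("%s:%d-%d", sig$chromosome, sig$start,
                                      sig$end), collapse = ";")
  }
  out[order(out$S), , drop = FALSE]
}

#' Write simulated data to pipeline-ready files
#'
#' Companion to [simulate_expression()] for command-line use: writes
#' the expression TSV, the BED annotation and a gene-level truth TSV.
#'
#' @param sim result of [simulate_expression()].
#' @param prefix path prefix; files `<prefix>_expr.tsv`,
#'   `<prefix>_genes.bed`, `<prefix>_truth.tsv` are created.
#' @return The three paths, invisibly.
#' @export
write_simulation <- function(sim, prefix) {
  expr_path <- paste0(prefix, "_expr.tsv")
  bed_path <- paste0(prefix, "_genes.bed")
  truth_path <- paste0(prefix, "_truth.tsv")
  write_expression(sim$expr, expr_path)
  ann <- sim$expr$annotation
  gr <- GenomicRanges::GRanges(seqnames = ann$chromosome,
                               ranges = IRanges::IRanges(start = ann$start + 1,
                                                         end = ann$end),
                               name = ann$gene_id)
  rtracklayer::export(gr, bed_path, format = "BED")
  data.table::fwrite(sim$truth$genes, truth_path, sep = "\t")
  invisible(c(expr_path, bed_path, truth_path))
}
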