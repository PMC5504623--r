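#' Expression matrix with chromosomal gene order
#'
#' Container used throughout the package: a numeric matrix of expression
#' values with patients in rows and genes in columns, together with the
#' gene annotation that fixes the chromosomal order of the columns.
#' Columns are sorted by chromosome, then genomic start coordinate, with
#' ties broken by gene id.
#'
#' @param values numeric matrix, n patients x p genes. Column names must
#'   match `annotation$gene_id`.
#' @param annotation data frame with columns `gene_id`, `chromosome`,
#'   `start`, `end` (0-based half-open, BED convention) and optionally
#'   `strand`.
#' @param standardized logical; `TRUE` once every gene column has mean 0
#'   and variance 1 under the 1/n convention.
#'
#' @return An object of class `expr_matrix`.
#' @export
expression_matrix <- function(values, annotation, standardized = FALSE) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix (patients x genes)")
  annotation <- validate_annotation(annotation)
  if (ncol(values) != nrow(annotation))
    stop("number of gene columns (", ncol(values),
         ") does not match annotation rows (", nrow(annotation), ")")
  if (anyNA(values))
    stop("missing expression values are not supported")
  ord <- gene_order(annotation)
  annotation <- annotation[ord, , drop = FALSE]
  rownames(annotation) <- NULL
  if (is.null(colnames(values))) {
    colnames(values) <- annotation$gene_id
  } else {
    if (!setequal(colnames(values), annotation$gene_id))
      stop("column names of 'values' do not match annotation gene ids")
    values <- values[, annotation$gene_id, drop = FALSE]
  }
  structure(list(values = values, annotation = annotation,
                 standardized = standardized),
            class = "expr_matrix")
}

validate_annotation <- function(annotation) {
  annotation <- as.data.frame(annotation)
  need <- c("gene_id", "chromosome", "start", "end")
  miss <- setdiff(need, names(annotation))
  if (length(miss))
    stop("annotation is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(annotation$gene_id))
    stop("duplicated gene ids in annotation: ",
         paste(unique(annotation$gene_id[duplicated(annotation$gene_id)]),
               collapse = ", "))
  bad <- which(annotation$start >= annotation$end)
  if (length(bad))
    stop("annotation intervals must have start < end (0-based half-open); ",
         "offending gene(s): ",
         paste(annotation$gene_id[utils::head(bad, 5)], collapse = ", "))
  annotation$gene_id <- as.character(annotation$gene_id)
  annotation$chromosome <- as.character(annotation$chromosome)
  annotation
}

# order genes by chromosome, start, then gene id (deterministic tie-break)
gene_order <- function(annotation) {
  order(annotation$chromosome, annotation$start, annotation$gene_id,
        method = "radix")
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' @export
as.matrix.expr_matrix <- function(x, ...) x$values

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d patients x %d genes on %d chromosome(s)%s\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$annotation$chromosome)),
              if (x$standardized) " (standardized)" else ""))
  invisible(x)
}

#' Chromosomes present in an expression matrix
#' @param x an `expr_matrix`.
#' @return Character vector of chromosome labels, in gene order.
#' @export
chromosomes <- function(x) unique(x$annotation$chromosome)

#' Extract the genes of a single chromosome
#' @param x an `expr_matrix`.
#' @param chrom chromosome label.
#' @return An `expr_matrix` restricted to `chrom`.
#' @export
subset_chromosome <- function(x, chrom) {
  keep <- x$annotation$chromosome == chrom
  if (!any(keep)) stop("no genes on chromosome '", chrom, "'")
  structure(list(values = x$values[, keep, drop = FALSE],
                 annotation = x$annotation[keep, , drop = FALSE],
                 standardized = x$standardized),
            class = "expr_matrix")
}

#' Read a gene annotation from a BED file
#'
#' Reads a BED file (chrom, start, end, name\[, score, strand\]) whose
#' `name` column carries the gene id, keeping the 0-based half-open
#' coordinate convention.
#'
#' @param path path to a BED file.
#' @return Annotation data frame with columns `gene_id`, `chromosome`,
#'   `start`, `end`, `strand`, sorted in chromosomal gene order.
#' @export
read_annotation <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  nm <- gr$name
  if (is.null(nm)) stop("BED file must have a name column with gene ids")
  ann <- data.frame(gene_id = as.character(nm),
                    chromosome = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1L,
                    end = GenomicRanges::end(gr),
                    strand = as.character(GenomicRanges::strand(gr)),
                    stringsAsFactors = FALSE)
  ann <- validate_annotation(ann)
  ann[gene_order(ann), , drop = FALSE]
}

#' Read an expression matrix from a TSV file
#'
#' Expects a tab-separated file with one row per gene: first column the
#' gene id, remaining columns one per sample (header row of sample ids).
#' Genes are reordered to the chromosomal order given by `annotation`;
#' genes absent from the annotation are dropped with a warning.
#'
#' @param path path to the expression TSV.
#' @param annotation annotation data frame (see [read_annotation()]),
#'   covering a superset of the gene ids in the file.
#' @return A raw (unstandardized) [expression_matrix()].
#' @export
read_expression <- function(path, annotation) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE, colClasses = list(character = 1))
  if (ncol(dt) < 2) stop("expression file must have at least one sample column")
  ids <- as.character(dt[[1]])
  if (anyDuplicated(ids))
    stop("duplicated gene ids in expression file: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  for (j in 2:ncol(dt)) {
    col <- dt[[j]]
    if (!is.numeric(col)) {
      val <- suppressWarnings(as.numeric(col))
      bad <- which(is.na(val) & !is.na(col))
      if (length(bad))
        stop("non-numeric expression value '", col[bad[1]], "' at row ",
             bad[1], " (gene ", ids[bad[1]], "), column ", names(dt)[j])
      dt[[j]] <- val
    }
  }
  mat <- as.matrix(dt[, -1, drop = FALSE])
  if (anyNA(mat)) stop("missing expression values are not supported")
  rownames(mat) <- ids
  annotation <- validate_annotation(annotation)
  known <- ids %in% annotation$gene_id
  if (!all(known)) {
    warning(sum(!known), " gene(s) absent from the annotation dropped: ",
            paste(utils::head(ids[!known], 5), collapse = ", "),
            if (sum(!known) > 5) ", ..." else "")
    mat <- mat[known, , drop = FALSE]
    ids <- ids[known]
  }
  if (nrow(mat) == 0) stop("no genes shared between expression file and annotation")
  ann <- annotation[match(ids, annotation$gene_id), , drop = FALSE]
  expression_matrix(t(mat), ann, standardized = FALSE)
}

#' Write an expression matrix to a TSV file
#'
#' Inverse of [read_expression()]: genes in rows (current chromosomal
#' order), samples in columns, gene id in the first column.
#'
#' @param x an `expr_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  stopifnot(inherits(x, "expr_matrix"))
  out <- data.table::data.table(gene_id = colnames(x$values))
  samp <- rownames(x$values)
  if (is.null(samp)) samp <- paste0("sample_", seq_len(nrow(x$values)))
  m <- t(x$values)
  colnames(m) <- samp
  out <- cbind(out, data.table::as.data.table(m))
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' log(1 + x) transform of expression values
#'
#' Natural-log transform used to bring RNA-seq counts (or normalized
#' counts) to a scale where the Gaussian segmentation model is adequate.
#'
#' @param x an `expr_matrix` with non-negative values.
#' @return The transformed `expr_matrix` (unstandardized).
#' @export
log_transform <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  if (any(x$values < 0))
    stop("log_transform requires non-negative values")
  x$values <- log1p(x$values)
  x$standardized <- FALSE
  x
}

#' Remove non-expressed and non-varying genes
#'
#' Genes that are zero in all samples, or constant across samples, carry
#' no correlation information and would make standardization degenerate;
#' they are removed before analysis.
#'
#' @param x an `expr_matrix`.
#' @return The filtered `expr_matrix`. Emits a message naming how many
#'   genes were removed, and a warning if none remain.
#' @export
drop_degenerate_genes <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  v <- x$values
  cmax <- apply(v, 2, max)
  cmin <- apply(v, 2, min)
  degenerate <- cmax == cmin
  if (any(degenerate)) {
    message("removing ", sum(degenerate), " degenerate gene(s): ",
            paste(utils::head(colnames(v)[degenerate], 5), collapse = ", "),
            if (sum(degenerate) > 5) ", ..." else "")
    x$values <- v[, !degenerate, drop = FALSE]
    x$annotation <- x$annotation[!degenerate, , drop = FALSE]
  }
  if (ncol(x$values) == 0) warning("all genes were degenerate; empty matrix")
  x
}

#' Center and scale every gene to unit 1/n variance
#'
#' Each gene column gets mean 0 and variance 1 with denominator n (not
#' n - 1), so that the empirical Gram matrix \eqn{\hat G = Y^\top Y / n}
#' has exact unit diagonal. This convention makes the closed-form
#' compound-symmetry likelihood and the identity
#' \eqn{T_k = n\,\lambda(p_k, \hat\rho_k)} hold exactly.
#'
#' @param x an `expr_matrix` without zero-variance columns (drop them
#'   first with [drop_degenerate_genes()]).
#' @return The standardized `expr_matrix`.
#' @export
standardize <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  v <- x$values
  n <- nrow(v)
  if (n < 2) stop("standardization requires at least 2 patients")
  ctr <- sweep(v, 2, colMeans(v))
  s <- sqrt(colMeans(ctr^2))
  if (any(s == 0))
    stop("zero-variance gene column(s): ",
         paste(utils::head(colnames(v)[s == 0], 5), collapse = ", "),
         "; drop them with drop_degenerate_genes() first")
  x$values <- sweep(ctr, 2, s, "/")
  x$standardized <- TRUE
  x
}

# internal: check that a plain block of columns is standardized (1/n)
assert_standardized <- function(block, tol = 1e-6) {
  if (max(abs(colMeans(block))) > tol ||
      max(abs(colMeans(block^2) - 1)) > tol)
    stop("input block must be standardized (mean 0, 1/n variance 1 per column)")
  invisible(TRUE)
}
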