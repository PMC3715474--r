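# Subject-level technical covariates: sequencing depth, per-subject GC bias,
# per-subject gene-length bias, plus RPKM values. These three covariates form
# the known-covariate matrix F used by the residual normalizers.

#' Per-subject sequencing depth
#'
#' Total number of mapped reads per subject (row sums of the count matrix).
#'
#' @param counts Subjects-by-genes count matrix.
#' @return Named numeric vector, one entry per subject, in reads.
#' @export
sequencing_depth <- function(counts) {
  check_matrix_labels(counts, "count matrix")
  if (nrow(counts) == 0 || ncol(counts) == 0) stop("empty count matrix", call. = FALSE)
  rowSums(counts)
}

# Pearson correlation between each subject's per-gene log expression and a
# per-gene property (GC fraction or length). The correlation is unitless and
# invariant to per-subject additive shifts of the log counts.
bias_covariate <- function(expr, annotation, property) {
  check_matrix_labels(expr, "expression matrix")
  miss <- setdiff(colnames(expr), annotation$gene_id)
  if (length(miss) > 0) {
    stop(sprintf("gene(s) missing from annotation: %s",
                 paste(head(miss, 5), collapse = ", ")), call. = FALSE)
  }
  x <- annotation[[property]][match(colnames(expr), annotation$gene_id)]
  if (sd(x) < .Machine$double.eps^0.5) {
    stop(sprintf("constant regressor: per-gene %s has no variation", property),
         call. = FALSE)
  }
  apply(expr, 1, function(y) cor(y, x))
}

#' Per-subject GC-content bias covariate
#'
#' For each subject, the Pearson correlation between that subject's per-gene
#' log read counts and the genes' GC content: the share of per-subject
#' variation in log counts explainable by GC. GC bias varies with sequencing
#' lane, so this is treated as a subject-specific covariate.
#'
#' @param expr Subjects-by-genes log-scale expression matrix (unstandardized;
#'   per-subject vectors are used as-is).
#' @param annotation Gene annotation tibble with a `gc_fraction` column
#'   covering every gene in `expr`.
#' @return Named numeric vector of correlations, one per subject.
#' @export
gc_bias_covariate <- function(expr, annotation) {
  bias_covariate(expr, annotation, "gc_fraction")
}

#' Per-subject gene-length bias covariate
#'
#' As [gc_bias_covariate()] with gene length (bp) in place of GC content;
#' length bias can reflect differences in initial RNA quality.
#'
#' @inheritParams gc_bias_covariate
#' @return Named numeric vector of correlations, one per subject.
#' @export
length_bias_covariate <- function(expr, annotation) {
  bias_covariate(expr, annotation, "length_bp")
}

#' Log2 RPKM expression values
#'
#' Reads per kilobase of gene length per million mapped reads:
#' `log2((count + pseudocount) / (depth/1e6) / (length_bp/1e3))`, i.e.
#' `log2(count + pc) - log2(depth/1e6) - log2(length/1e3)`. Scaling by depth
#' and length preserves the per-subject ranking of genes when lengths are
#' equal.
#'
#' @param counts Subjects-by-genes count matrix.
#' @param annotation Gene annotation tibble with `length_bp` covering every
#'   gene.
#' @param pseudocount Added to counts before the log (default 1); set 0 only
#'   when no zero counts remain.
#' @param depth Optional per-subject depths; defaults to
#'   [sequencing_depth()] of `counts`.
#' @return Expression matrix of log2 RPKM values (`standardized = FALSE`).
#' @export
rpkm <- function(counts, annotation, pseudocount = 1, depth = NULL) {
  check_matrix_labels(counts, "count matrix")
  if (is.null(depth)) depth <- sequencing_depth(counts)
  if (any(depth <= 0)) {
    stop(sprintf("zero sequencing depth for subject(s): %s",
                 paste(head(rownames(counts)[depth <= 0], 5), collapse = ", ")),
         call. = FALSE)
  }
  miss <- setdiff(colnames(counts), annotation$gene_id)
  if (length(miss) > 0) {
    stop(sprintf("gene(s) missing from annotation: %s",
                 paste(head(miss, 5), collapse = ", ")), call. = FALSE)
  }
  len <- annotation$length_bp[match(colnames(counts), annotation$gene_id)]
  if (any(len <= 0)) stop("gene lengths must be positive", call. = FALSE)
  if (pseudocount == 0 && any(counts == 0)) {
    stop("log of zero: zero counts present with pseudocount = 0", call. = FALSE)
  }
  out <- log2(counts + pseudocount)
  out <- sweep(out, 1, log2(depth / 1e6), "-")
  out <- sweep(out, 2, log2(len / 1e3), "-")
  attr(out, "standardized") <- FALSE
  out
}

#' Assemble named covariate vectors into a known-covariate matrix
#'
#' Column-binds subject-level covariates into the matrix F (subjects x m).
#' All vectors must carry identical subject names in identical order; by
#' default each column is standardized to zero mean and unit SD so that
#' ridge/HCP penalties act on comparable scales.
#'
#' @param ... Named numeric vectors of equal length with matching subject
#'   names (e.g. `depth = `, `gc = `, `length = `), or a single named list.
#' @param standardize Standardize columns (default `TRUE`).
#' @return Subjects-by-m numeric matrix with a `standardized` attribute.
#' @export
assemble_covariates <- function(..., standardize = TRUE) {
  cols <- list(...)
  if (length(cols) == 1 && is.list(cols[[1]]) && !is.numeric(cols[[1]])) {
    cols <- cols[[1]]
  }
  if (length(cols) == 0) stop("no covariates supplied", call. = FALSE)
  if (is.null(names(cols)) || any(names(cols) == "")) {
    stop("covariates must be named", call. = FALSE)
  }
  n <- length(cols[[1]])
  subj <- names(cols[[1]])
  if (is.null(subj)) stop("covariate vectors must carry subject names", call. = FALSE)
  for (nm in names(cols)) {
    v <- cols[[nm]]
    if (length(v) != n) stop("covariate lengths differ", call. = FALSE)
    if (!identical(names(v), subj)) {
      stop(sprintf("subject order mismatch in covariate '%s'", nm), call. = FALSE)
    }
  }
  f <- do.call(cbind, cols)
  rownames(f) <- subj
  if (standardize) {
    s <- apply(f, 2, sd)
    if (any(s < .Machine$double.eps^0.5)) {
      stop("constant covariate column cannot be standardized", call. = FALSE)
    }
    f <- scale(f)
    attr(f, "scaled:center") <- NULL
    attr(f, "scaled:scale") <- NULL
  }
  attr(f, "standardized") <- isTRUE(standardize)
  f
}

#' Build the standard three-covariate matrix from counts and annotation
#'
#' Convenience wrapper constructing sequencing depth, GC bias and length
#' bias (computed on `log2(count + pseudocount)` values) and assembling them
#' with [assemble_covariates()].
#'
#' @param counts Subjects-by-genes count matrix (typically after
#'   [filter_expressed()]).
#' @param annotation Gene annotation tibble.
#' @param pseudocount Pseudocount for the internal log transform (default 1).
#' @param standardize Standardize the columns (default `TRUE`).
#' @return Subjects-by-3 covariate matrix with columns `depth`, `gc_bias`,
#'   `length_bias`.
#' @export
technical_covariates <- function(counts, annotation, pseudocount = 1,
                                 standardize = TRUE) {
  logc <- log_transform(counts, pseudocount = pseudocount)
  assemble_covariates(
    depth = sequencing_depth(counts),
    gc_bias = gc_bias_covariate(logc, annotation),
    length_bias = length_bias_covariate(logc, annotation),
    standardize = standardize)
}
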