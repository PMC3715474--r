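#' @importFrom rlang .data
#' @importFrom stats cor pnorm pt qnorm rbinom rnorm rpois runif sd var setNames
#' @importFrom utils combn head
NULL

# ---- internal validation helpers --------------------------------------------

check_unique <- function(x, what) {
  dup <- unique(x[duplicated(x)])
  if (length(dup) > 0) {
    stop(sprintf("duplicate %s: %s", what, paste(head(dup, 5), collapse = ", ")),
         call. = FALSE)
  }
  invisible(x)
}

check_matrix_labels <- function(m, what = "matrix") {
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop(sprintf("%s must carry subject row names and gene/covariate column names", what),
         call. = FALSE)
  }
  check_unique(rownames(m), paste(what, "subject id"))
  check_unique(colnames(m), paste(what, "column id"))
  invisible(m)
}

#' Test whether an expression matrix is flagged as gene-standardized
#'
#' @param expr A numeric subjects-by-genes matrix.
#' @return `TRUE` if the matrix carries a `standardized = TRUE` attribute.
#' @seealso [standardize_genes()]
#' @export
is_standardized <- function(expr) {
  isTRUE(attr(expr, "standardized"))
}

# ---- TSV readers / writers --------------------------------------------------

read_labeled_matrix <- function(path, what, integer_only = FALSE,
                                nonnegative = FALSE) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()),
                         name_repair = "minimal")
  if (ncol(tab) < 2) stop(sprintf("%s: expected a subject id column plus data columns", path),
                          call. = FALSE)
  subjects <- tab[[1]]
  check_unique(subjects, "subject id")
  check_unique(names(tab)[-1], sprintf("%s id", what))
  m <- matrix(NA_real_, nrow = nrow(tab), ncol = ncol(tab) - 1L,
              dimnames = list(subjects, names(tab)[-1]))
  for (j in seq_len(ncol(m))) {
    raw <- tab[[j + 1L]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val))
    if (length(bad) > 0) {
      stop(sprintf("non-numeric or missing cell at row %d (subject %s), column %s",
                   bad[1], subjects[bad[1]], colnames(m)[j]), call. = FALSE)
    }
    m[, j] <- val
  }
  if (nonnegative && any(m < 0)) {
    idx <- which(m < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative cell at row %d (subject %s), column %s",
                 idx[1], rownames(m)[idx[1]], colnames(m)[idx[2]]), call. = FALSE)
  }
  if (integer_only) {
    if (any(abs(m - round(m)) > 1e-8)) {
      idx <- which(abs(m - round(m)) > 1e-8, arr.ind = TRUE)[1, ]
      stop(sprintf("non-integer count at row %d (subject %s), column %s",
                   idx[1], rownames(m)[idx[1]], colnames(m)[idx[2]]), call. = FALSE)
    }
    m <- round(m)
  }
  m
}

#' Read a subjects-by-genes read-count matrix from TSV
#'
#' The file layout is one header row of gene ids, a first column of subject
#' ids, and whole-number read counts (reads aggregated per gene). Counts are
#' validated to be non-negative integers; duplicate subject or gene ids and
#' missing or non-numeric cells are errors that name the offending label or
#' cell.
#'
#' @param path Path to a TSV file.
#' @return A numeric matrix (subjects in rows, genes in columns) of counts,
#'   with subject ids as row names and gene ids as column names.
#' @export
read_count_matrix <- function(path) {
  read_labeled_matrix(path, "gene", integer_only = TRUE, nonnegative = TRUE)
}

#' Read a subjects-by-genes expression matrix from TSV
#'
#' Same layout as [read_count_matrix()] but cells may be any finite real
#' (log-scale expression values).
#'
#' @inheritParams read_count_matrix
#' @param standardized Flag to attach; set `TRUE` when the file holds
#'   gene-standardized values.
#' @return A numeric subjects-by-genes matrix with a `standardized` attribute.
#' @export
read_expression_matrix <- function(path, standardized = FALSE) {
  m <- read_labeled_matrix(path, "gene")
  if (any(!is.finite(m))) stop("expression matrix contains non-finite values", call. = FALSE)
  attr(m, "standardized") <- isTRUE(standardized)
  m
}

#' Read a subjects-by-covariates matrix from TSV
#'
#' @inheritParams read_count_matrix
#' @return A numeric subjects-by-m matrix of known covariates.
#' @export
read_covariate_matrix <- function(path) {
  m <- read_labeled_matrix(path, "covariate")
  if (any(!is.finite(m))) stop("covariate matrix contains non-finite values", call. = FALSE)
  m
}

#' Write a labeled matrix to TSV
#'
#' Inverse of the matrix readers: header row of column ids, first column
#' `subject_id`, full double precision so read/write round-trips are
#' bit-identical for count matrices.
#'
#' @param m A matrix with row and column names.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path) {
  check_matrix_labels(m)
  df <- tibble::as_tibble(m, rownames = "subject_id")
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read a gene annotation table
#'
#' Two layouts are accepted. `format = "tsv"`: a header-full TSV with columns
#' `gene_id`, `chrom`, `tss` (1-based), `strand` (+/-), `length_bp`,
#' `gc_fraction`. `format = "bed"`: header-less BED6 plus two extra columns
#' (`length_bp`, `gc_fraction`); the 0-based `start` is converted to a
#' 1-based TSS honoring strand (plus strand: start + 1; minus strand: end).
#'
#' @param path Path to the annotation file.
#' @param format `"tsv"` or `"bed"`.
#' @return A tibble with columns `gene_id`, `chrom`, `tss`, `strand`,
#'   `length_bp`, `gc_fraction`.
#' @export
read_gene_annotation <- function(path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (format == "tsv") {
    ann <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    need <- c("gene_id", "chrom", "tss", "strand", "length_bp", "gc_fraction")
    miss <- setdiff(need, names(ann))
    if (length(miss) > 0) stop("annotation missing columns: ", paste(miss, collapse = ", "),
                               call. = FALSE)
    ann <- dplyr::select(ann, dplyr::all_of(need))
  } else {
    bed <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "gene_id",
                                               "score", "strand", "length_bp",
                                               "gc_fraction"),
                           show_col_types = FALSE, progress = FALSE)
    ann <- dplyr::transmute(bed,
      gene_id = .data$gene_id,
      chrom = .data$chrom,
      tss = ifelse(.data$strand == "-", .data$end, .data$start + 1L),
      strand = .data$strand,
      length_bp = .data$length_bp,
      gc_fraction = .data$gc_fraction)
  }
  validate_annotation(ann)
}

validate_annotation <- function(ann) {
  check_unique(ann$gene_id, "gene id")
  if (any(ann$tss < 1)) stop("annotation: tss must be >= 1", call. = FALSE)
  if (any(ann$length_bp < 1)) stop("annotation: length_bp must be >= 1", call. = FALSE)
  if (any(ann$gc_fraction < 0 | ann$gc_fraction > 1)) {
    stop("annotation: gc_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (!all(ann$strand %in% c("+", "-"))) {
    stop("annotation: strand must be '+' or '-'", call. = FALSE)
  }
  tibble::as_tibble(ann)
}

#' Write a gene annotation tibble to TSV
#'
#' @param ann Annotation tibble as returned by [read_gene_annotation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_annotation <- function(ann, path) {
  readr::write_tsv(validate_annotation(ann), path, progress = FALSE)
  invisible(path)
}

# ---- genotypes --------------------------------------------------------------

#' Construct a genotype object from a dosage matrix and SNP map
#'
#' @param dosages Subjects-by-SNPs matrix with entries in \{0, 1, 2\} or `NA`
#'   for missing genotypes.
#' @param snp_map Tibble with columns `snp_id`, `chrom`, `pos` (1-based bp).
#' @return An object of class `genotypes`: a list with elements `dosages`
#'   and `snp_map` (sorted by chromosome then position).
#' @export
genotypes <- function(dosages, snp_map) {
  check_matrix_labels(dosages, "dosage matrix")
  snp_map <- tibble::as_tibble(snp_map)
  need <- c("snp_id", "chrom", "pos")
  if (!all(need %in% names(snp_map))) {
    stop("snp_map needs columns snp_id, chrom, pos", call. = FALSE)
  }
  check_unique(snp_map$snp_id, "snp id")
  if (!setequal(snp_map$snp_id, colnames(dosages))) {
    stop("snp_map ids do not match dosage matrix columns", call. = FALSE)
  }
  ok <- is.na(dosages) | dosages %in% c(0, 1, 2)
  if (!all(ok)) stop("dosages must be 0, 1, 2 or NA", call. = FALSE)
  snp_map <- dplyr::arrange(snp_map, .data$chrom, .data$pos)
  structure(list(dosages = dosages[, snp_map$snp_id, drop = FALSE],
                 snp_map = snp_map),
            class = "genotypes")
}

#' Read genotypes from a dosage TSV and a SNP map TSV
#'
#' The dosage file has the labeled-matrix layout (subjects in rows, SNP ids
#' in the header); the map is a 3-column TSV (`snp_id`, `chrom`, `pos`).
#'
#' @param dosage_path Path to the dosage TSV.
#' @param map_path Path to the SNP map TSV.
#' @return A `genotypes` object.
#' @export
read_genotypes <- function(dosage_path, map_path) {
  dos <- read_labeled_matrix(dosage_path, "snp")
  map <- readr::read_tsv(map_path, show_col_types = FALSE, progress = FALSE)
  genotypes(dos, map)
}

#' Read genotypes from a minimal VCF
#'
#' Converts diploid GT fields to 0/1/2 alternate-allele dosages (missing
#' genotypes become `NA`). Requires the vcfR package.
#'
#' @param path Path to an uncompressed VCF.
#' @return A `genotypes` object.
#' @export
read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the vcfR package", call. = FALSE)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  ids <- as.character(v@fix[, "ID"])
  ids[is.na(ids) | ids == "."] <- paste0(v@fix[, "CHROM"], "_", v@fix[, "POS"])[is.na(ids) | ids == "."]
  count_alt <- function(x) {
    ifelse(is.na(x) | x %in% c(".", "./.", ".|."),
           NA_real_,
           vapply(strsplit(x, "[/|]"), function(a) sum(a == "1"), numeric(1)))
  }
  flat <- count_alt(as.vector(gt))
  dos <- t(matrix(flat, nrow = nrow(gt), ncol = ncol(gt)))  # subjects x snps
  colnames(dos) <- ids
  rownames(dos) <- colnames(gt)
  map <- tibble::tibble(snp_id = ids,
                        chrom = as.character(v@fix[, "CHROM"]),
                        pos = as.integer(v@fix[, "POS"]))
  genotypes(dos, map)
}

#' @export
print.genotypes <- function(x, ...) {
  cat(sprintf("genotypes: %d subjects x %d SNPs on %d chromosome(s)\n",
              nrow(x$dosages), ncol(x$dosages),
              dplyr::n_distinct(x$snp_map$chrom)))
  invisible(x)
}

# ---- preprocessing ----------------------------------------------------------

#' Keep genes expressed above a read-count threshold in enough subjects
#'
#' A gene is retained when it has at least `min_reads` reads in at least
#' `min_subjects` subjects (default 30 reads in 10 subjects). The subject set
#' and the relative order of the surviving genes are unchanged.
#'
#' @param counts Subjects-by-genes count matrix.
#' @param min_reads Minimum read count per subject (default 30).
#' @param min_subjects Minimum number of subjects reaching `min_reads`
#'   (default 10).
#' @return The count matrix restricted to expressed genes.
#' @export
filter_expressed <- function(counts, min_reads = 30, min_subjects = 10) {
  check_matrix_labels(counts, "count matrix")
  if (min_reads < 0) stop("min_reads must be >= 0", call. = FALSE)
  if (min_subjects < 1) stop("min_subjects must be >= 1", call. = FALSE)
  if (min_subjects > nrow(counts)) {
    stop(sprintf("min_subjects (%d) exceeds the number of subjects (%d)",
                 min_subjects, nrow(counts)), call. = FALSE)
  }
  keep <- colSums(counts >= min_reads) >= min_subjects
  counts[, keep, drop = FALSE]
}

#' Log-transform read counts
#'
#' Computes `log_base(count + pseudocount)`. With zeros present a positive
#' pseudocount is required.
#'
#' @param counts Subjects-by-genes count matrix.
#' @param pseudocount Added before the log (default 1).
#' @param base Logarithm base: 2 (default), `exp(1)`, or 10.
#' @return An expression matrix (log scale, `standardized = FALSE`).
#' @export
log_transform <- function(counts, pseudocount = 1, base = 2) {
  check_matrix_labels(counts, "count matrix")
  if (pseudocount < 0) stop("pseudocount must be >= 0", call. = FALSE)
  if (pseudocount == 0 && any(counts == 0)) {
    stop("log of zero: zero counts present with pseudocount = 0", call. = FALSE)
  }
  out <- log(counts + pseudocount, base = base)
  attr(out, "standardized") <- FALSE
  out
}

#' Standardize each gene to zero mean and unit variance
#'
#' Gene columns are centred and scaled to sample standard deviation 1.
#' Constant genes cannot be scaled; they are set to all-zero (kept, so gene
#' indices stay aligned across normalization methods) and reported via a
#' warning and the `constant_genes` attribute. Subject ranks within each
#' gene are unchanged, so Spearman statistics downstream are unaffected.
#'
#' @param expr Subjects-by-genes expression matrix (log scale).
#' @return The standardized matrix (`standardized = TRUE`), with attribute
#'   `constant_genes` naming any zeroed columns.
#' @export
standardize_genes <- function(expr) {
  check_matrix_labels(expr, "expression matrix")
  if (nrow(expr) < 2) stop("standardization needs at least 2 subjects", call. = FALSE)
  mu <- colMeans(expr)
  s <- apply(expr, 2, sd)
  const <- s < .Machine$double.eps^0.5
  s[const] <- 1
  out <- sweep(sweep(expr, 2, mu, "-"), 2, s, "/")
  if (any(const)) {
    out[, const] <- 0
    warning(sprintf("%d constant gene(s) set to zero: %s",
                    sum(const), paste(head(colnames(expr)[const], 5), collapse = ", ")),
            call. = FALSE)
  }
  attr(out, "standardized") <- TRUE
  attr(out, "constant_genes") <- colnames(expr)[const]
  out
}
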