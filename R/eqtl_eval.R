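# cis-eQTL evaluation: pair each SNP with the gene whose transcription
# start site is closest (within a window, default 100 Kb), test each pair
# with Spearman rank correlation, and control the false discovery rate with
# Benjamini-Hochberg across all tested pairs. Working on ranks makes the
# scan invariant to any strictly monotone per-gene transform of expression.

#' Pair SNPs with genes within a TSS window
#'
#' A pair (gene, SNP) is formed when the SNP lies on the same chromosome
#' with `|pos - tss| <= window` (boundary inclusive). A SNP falling in the
#' window of several genes is assigned only to the closest gene; equidistant
#' ties are broken by lower TSS coordinate, then lexicographic gene id, so
#' pairing is deterministic.
#'
#' @param annotation Gene annotation tibble (`gene_id`, `chrom`, `tss`).
#' @param geno A `genotypes` object.
#' @param window Window half-width in bp (default 100000).
#' @return A tibble `gene_id`, `snp_id`, `distance_bp` (signed, pos - tss);
#'   each SNP appears at most once.
#' @export
pair_cis <- function(annotation, geno, window = 100000) {
  stopifnot(inherits(geno, "genotypes"))
  snp <- geno$snp_map
  shared <- intersect(unique(annotation$chrom), unique(snp$chrom))
  if (length(shared) == 0) {
    warning(sprintf("no shared chromosomes (%d gene vs %d SNP chromosomes)",
                    dplyr::n_distinct(annotation$chrom),
                    dplyr::n_distinct(snp$chrom)), call. = FALSE)
    return(tibble::tibble(gene_id = character(), snp_id = character(),
                          distance_bp = numeric()))
  }
  pairs <- dplyr::inner_join(
    dplyr::select(snp, "snp_id", "chrom", "pos"),
    dplyr::select(annotation, "gene_id", "chrom", "tss"),
    by = "chrom", relationship = "many-to-many") |>
    dplyr::mutate(distance_bp = .data$pos - .data$tss) |>
    dplyr::filter(abs(.data$distance_bp) <= window)
  pairs |>
    dplyr::group_by(.data$snp_id) |>
    dplyr::arrange(abs(.data$distance_bp), .data$tss, .data$gene_id,
                   .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$gene_id, .data$snp_id) |>
    dplyr::select("gene_id", "snp_id", "distance_bp")
}

# Spearman rho with mid-rank ties, plus a two-sided p-value: exact
# permutation null for n < 8 (the t approximation is poor there), t
# approximation on n - 2 df otherwise.
spearman_test <- function(x, y) {
  n <- length(x)
  rx <- rank(x)
  ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) return(c(rho = NA_real_, p = NA_real_))
  rho <- cor(rx, ry)
  if (n < 8) {
    perms <- all_permutations(n)
    rho_null <- apply(perms, 1, function(idx) cor(rx, ry[idx]))
    p <- mean(abs(rho_null) >= abs(rho) - 1e-12)
  } else {
    r2 <- min(rho^2, 1 - 1e-15)
    tstat <- rho * sqrt((n - 2) / (1 - r2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  }
  c(rho = rho, p = max(p, .Machine$double.xmin))
}

# permutation matrices cached per n (n <= 7 -> at most 5040 rows)
perm_cache <- new.env(parent = emptyenv())
all_permutations <- function(n) {
  key <- as.character(n)
  if (!is.null(perm_cache[[key]])) return(perm_cache[[key]])
  res <- if (n == 1) matrix(1, 1, 1) else {
    sub <- all_permutations(n - 1)
    do.call(rbind, lapply(seq_len(n), function(i) {
      cbind(i, sub + (sub >= i))
    }))
  }
  perm_cache[[key]] <- res
  res
}

#' Spearman scan of cis pairs against residual expression
#'
#' For each (gene, SNP) pair, Spearman correlation between the gene's
#' residual expression and the SNP dosage over the subjects shared by both
#' matrices, using pairwise-complete subjects when dosages are missing.
#' Pairs with fewer than 3 informative subjects or a monomorphic dosage
#' (after removing missing values) are dropped. Benjamini-Hochberg q-values
#' are computed across all tested pairs.
#'
#' @param residual Subjects-by-genes (residual) expression matrix.
#' @param geno A `genotypes` object.
#' @param pairs Pair table from [pair_cis()].
#' @return A tibble `gene_id`, `snp_id`, `distance_bp`, `n` (informative
#'   subjects), `rho`, `p`, `q`, ordered by `p`.
#' @export
spearman_scan <- function(residual, geno, pairs) {
  stopifnot(inherits(geno, "genotypes"))
  if (nrow(pairs) == 0) stop("no cis pairs to test", call. = FALSE)
  subjects <- intersect(rownames(residual), rownames(geno$dosages))
  if (length(subjects) < 3) stop("fewer than 3 shared subjects", call. = FALSE)
  expr <- residual[subjects, , drop = FALSE]
  dos <- geno$dosages[subjects, , drop = FALSE]
  keep_gene <- pairs$gene_id %in% colnames(expr)
  keep_snp <- pairs$snp_id %in% colnames(dos)
  pairs <- pairs[keep_gene & keep_snp, , drop = FALSE]
  n_out <- rho_out <- p_out <- numeric(nrow(pairs))
  ok <- logical(nrow(pairs))
  dropped <- 0L
  for (i in seq_len(nrow(pairs))) {
    y <- expr[, pairs$gene_id[i]]
    d <- dos[, pairs$snp_id[i]]
    use <- !is.na(d)
    if (sum(use) < 3 || length(unique(d[use])) < 2) {
      dropped <- dropped + 1L
      next
    }
    st <- spearman_test(y[use], d[use])
    if (is.na(st[["rho"]])) {
      dropped <- dropped + 1L
      next
    }
    n_out[i] <- sum(use)
    rho_out[i] <- st[["rho"]]
    p_out[i] <- st[["p"]]
    ok[i] <- TRUE
  }
  if (dropped > 0) {
    message(sprintf("dropped %d pair(s): monomorphic SNP, constant expression or < 3 informative subjects",
                    dropped))
  }
  out <- tibble::tibble(gene_id = pairs$gene_id[ok], snp_id = pairs$snp_id[ok],
                        distance_bp = pairs$distance_bp[ok],
                        n = as.integer(n_out[ok]),
                        rho = rho_out[ok], p = p_out[ok])
  out$q <- bh_fdr(out$p)
  dplyr::arrange(out, .data$p)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Standard step-up adjustment `q_(i) = min_{j >= i} m p_(j) / j`, clipped
#' at 1 (delegated to [stats::p.adjust()]).
#'
#' @param pvalues Numeric vector of p-values in (0, 1].
#' @return Vector of q-values in the original order.
#' @export
bh_fdr <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  if (any(!is.finite(pvalues)) || any(pvalues <= 0) || any(pvalues > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Count discoveries at FDR levels
#'
#' @param result Scan result from [spearman_scan()] (needs `q` and
#'   `gene_id`).
#' @param levels FDR levels (default 1%, 5%, 10%).
#' @return A tibble `level`, `n_pairs` (pairs with `q <= level`), `n_genes`
#'   (distinct genes among them).
#' @export
count_discoveries <- function(result, levels = c(0.01, 0.05, 0.10)) {
  purrr::map_dfr(levels, function(lv) {
    hit <- result$q <= lv
    tibble::tibble(level = lv, n_pairs = sum(hit),
                   n_genes = dplyr::n_distinct(result$gene_id[hit]))
  })
}

#' Gene-level p-values from a scan result
#'
#' The gene-level p-value is the minimum over the gene's tested cis SNPs.
#'
#' @param result Scan result from [spearman_scan()].
#' @return Named numeric vector, one minimum p per gene.
#' @export
gene_level_pvalues <- function(result) {
  agg <- result |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(p = min(.data$p), .groups = "drop")
  setNames(agg$p, agg$gene_id)
}

#' Cross-dataset consistency of p-value vectors
#'
#' Spearman correlation between two named p-value vectors over their shared
#' keys (SNP ids or gene ids), with a 90% confidence interval from the
#' Fisher z-transform (standard error `1/sqrt(n_shared - 3)`).
#'
#' @param pvals_a,pvals_b Named numeric p-value vectors.
#' @param conf Confidence level (default 0.90).
#' @return A tibble with `rho`, `ci_lower`, `ci_upper`, `n_shared`.
#' @export
consistency <- function(pvals_a, pvals_b, conf = 0.90) {
  keys <- intersect(names(pvals_a), names(pvals_b))
  if (length(keys) < 10) stop("fewer than 10 shared keys", call. = FALSE)
  rho <- cor(rank(pvals_a[keys]), rank(pvals_b[keys]))
  z <- atanh(min(max(rho, -1 + 1e-12), 1 - 1e-12))
  se <- 1 / sqrt(length(keys) - 3)
  half <- qnorm(1 - (1 - conf) / 2) * se
  tibble::tibble(rho = rho,
                 ci_lower = tanh(z - half), ci_upper = tanh(z + half),
                 n_shared = length(keys))
}

#' Pairwise overlap of discovery sets across normalization methods
#'
#' Entry (i, j) is the fraction of pairs discovered at `level` under method
#' i that are also discovered under method j: `|D_i intersect D_j| / |D_i|`.
#' Rows with an empty discovery set are `NA`.
#'
#' @param results Named list of scan results over the same pair universe.
#' @param level FDR level (default 0.10).
#' @return A square numeric matrix of fractions with method names on both
#'   dimensions.
#' @export
pairwise_overlap <- function(results, level = 0.10) {
  if (length(results) < 2) stop("need at least 2 results", call. = FALSE)
  nm <- names(results)
  if (is.null(nm)) nm <- paste0("method", seq_along(results))
  disc <- lapply(results, function(r) {
    paste(r$gene_id[r$q <= level], r$snp_id[r$q <= level], sep = "|")
  })
  out <- matrix(NA_real_, length(results), length(results), dimnames = list(nm, nm))
  for (i in seq_along(disc)) {
    if (length(disc[[i]]) == 0) next
    for (j in seq_along(disc)) {
      out[i, j] <- length(intersect(disc[[i]], disc[[j]])) / length(disc[[i]])
    }
  }
  out
}
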