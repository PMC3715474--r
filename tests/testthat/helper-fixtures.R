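# Shared fixture builders. Everything is generated in code under a fixed
# seed; no binary fixtures.

random_counts <- function(n = 8, g = 12, lambda = 40, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(rpois(n * g, lambda), n, g,
                dimnames = list(sprintf("S%02d", seq_len(n)),
                                sprintf("G%03d", seq_len(g))))
    m
  })
}

random_expression <- function(n = 10, g = 15, seed = 1, standardized = FALSE) {
  withr::with_seed(seed, {
    m <- matrix(rnorm(n * g), n, g,
                dimnames = list(sprintf("S%02d", seq_len(n)),
                                sprintf("G%03d", seq_len(g))))
    attr(m, "standardized") <- FALSE
    if (standardized) m <- standardize_genes(m)
    m
  })
}

toy_annotation <- function(gene_ids, tss = NULL, chrom = "chr1",
                           length_bp = NULL, gc = NULL) {
  g <- length(gene_ids)
  tibble::tibble(
    gene_id = gene_ids,
    chrom = rep_len(chrom, g),
    tss = if (is.null(tss)) as.integer(seq_len(g) * 250000) else as.integer(tss),
    strand = rep_len("+", g),
    length_bp = if (is.null(length_bp)) as.integer(500 + seq_len(g) * 37) else as.integer(length_bp),
    gc_fraction = if (is.null(gc)) seq(0.3, 0.7, length.out = g) else gc)
}

# expression whose centered gene columns are exactly orthogonal to the
# columns of F (and standardized), so the ridge coefficients vanish
expression_orthogonal_to <- function(F_known, g = 6, seed = 3) {
  n <- nrow(F_known)
  withr::with_seed(seed, {
    basis <- cbind(1, F_known)
    q <- qr.Q(qr(basis), complete = TRUE)[, (ncol(basis) + 1):n, drop = FALSE]
    raw <- q %*% matrix(rnorm(ncol(q) * g), ncol(q), g)
    dimnames(raw) <- list(rownames(F_known) %||% sprintf("S%02d", seq_len(n)),
                          sprintf("G%03d", seq_len(g)))
    attr(raw, "standardized") <- FALSE
    standardize_genes(raw)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force Pearson correlation from the textbook formula (independent of
# stats::cor)
pearson_formula <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# brute-force BH step-up from the definition
bh_brute <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(sapply(i:m, function(j) m * p[ord][j] / j), 1)
  }
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}
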