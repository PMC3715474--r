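# Seeded generators producing data with the statistical structure the
# residual framework assumes: log-scale expression built from known-
# covariate effects, hidden factors correlated with the known covariates,
# optional co-expressed gene modules, planted cis-eQTL effects, and
# Gaussian noise — together with the planted truth, so estimators can be
# tested for recovery without external downloads. Each generator draws
# from its own seeded stream, so regenerating one component leaves the
# others untouched.

with_seed <- function(seed, expr) {
  old_seed <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  force(expr)
}

pad_ids <- function(prefix, n) {
  sprintf(paste0(prefix, "%0", max(2, nchar(n)), "d"), seq_len(n))
}

#' Generate a synthetic gene annotation
#'
#' Genes are laid out consecutively along synthetic chromosomes with a
#' fixed TSS spacing (wide enough that cis windows do not overlap by
#' default), with lengths and GC fractions drawn uniformly.
#'
#' @param g Number of genes.
#' @param n_chrom Number of chromosomes (default 2).
#' @param spacing TSS spacing in bp (default 250000).
#' @param length_range Gene length range in bp (default 500-10000).
#' @param gc_range GC fraction range (default 0.3-0.7).
#' @param seed Seed.
#' @return Annotation tibble (`gene_id`, `chrom`, `tss`, `strand`,
#'   `length_bp`, `gc_fraction`).
#' @export
generate_gene_annotation <- function(g, n_chrom = 2, spacing = 250000,
                                     length_range = c(500, 10000),
                                     gc_range = c(0.3, 0.7), seed = 1) {
  with_seed(seed, {
    chrom <- paste0("chr", rep_len(seq_len(n_chrom), g))
    idx <- stats::ave(seq_len(g), chrom, FUN = seq_along)
    tibble::tibble(
      gene_id = pad_ids("G", g),
      chrom = chrom,
      tss = as.integer(idx * spacing),
      strand = sample(c("+", "-"), g, replace = TRUE),
      length_bp = as.integer(round(runif(g, length_range[1], length_range[2]))),
      gc_fraction = runif(g, gc_range[1], gc_range[2]))
  })
}

#' Generate synthetic log-scale expression with known and hidden structure
#'
#' Draws `Y = F beta + Z B + M L + noise` on the log scale, where `F`
#' (subjects x m, standard normal) are known covariates with direct gene
#' effects `beta`; hidden factors `Z = F U + factor noise` are correlated
#' with the known covariates (the regime the covariate prior assumes);
#' `B` are hidden-factor loadings affecting every gene (a broad
#' confounder); and `M L` is optional module structure — non-overlapping
#' gene modules sharing a module-specific subject factor, emulating
#' co-regulated gene sets. Default scales put the hidden confounder at
#' roughly 55-65% of per-gene variance, the broad-trend regime in which
#' confounder correction matters.
#'
#' @param n,g Numbers of subjects and genes.
#' @param m Number of known covariates (default 3).
#' @param k Number of hidden factors (default 4).
#' @param beta_sd SD of direct known-covariate gene effects (default 0.3).
#' @param loading_sd SD of hidden-factor loadings (default 0.6).
#' @param factor_noise_sd SD of the hidden-factor noise around `F U`
#'   (default 0.5); larger values decouple hidden factors from the known
#'   covariates.
#' @param noise_sd SD of the i.i.d. Gaussian noise (default 1).
#' @param n_modules Number of co-expressed gene modules (default 0).
#' @param module_size Genes per module.
#' @param module_sd SD of within-module loadings (default 1).
#' @param seed Seed.
#' @return A list: `expression` (subjects x genes, log scale, not
#'   standardized), `covariates` (`F`, subjects x m), and `truth` (list
#'   with `F`, `U`, `Z`, `B`, `beta`, `module_assignments` named by gene,
#'   `module_factors`, `module_loadings`, the noise SDs and the seed).
#' @export
generate_expression <- function(n, g, m = 3, k = 4,
                                beta_sd = 0.3, loading_sd = 0.6,
                                factor_noise_sd = 0.5, noise_sd = 1,
                                n_modules = 0, module_size = 30,
                                module_sd = 1, seed = 1) {
  if (k > min(n, g)) stop("k must be <= min(n, g)", call. = FALSE)
  if (m < 1) stop("m must be >= 1", call. = FALSE)
  if (n_modules * module_size > g) stop("modules exceed the number of genes", call. = FALSE)
  with_seed(seed, {
    subj <- pad_ids("S", n)
    genes <- pad_ids("G", g)
    F_known <- matrix(rnorm(n * m), n, m, dimnames = list(subj, paste0("cov", seq_len(m))))
    U <- matrix(rnorm(m * k) / sqrt(m), m, k)
    Z <- F_known %*% U + matrix(rnorm(n * k, sd = factor_noise_sd), n, k)
    B <- matrix(rnorm(k * g, sd = loading_sd), k, g)
    beta <- matrix(rnorm(m * g, sd = beta_sd), m, g)
    Y <- F_known %*% beta + Z %*% B +
      matrix(rnorm(n * g, sd = noise_sd), n, g)
    module_assignments <- setNames(rep(NA_integer_, g), genes)
    module_factors <- NULL
    module_loadings <- NULL
    if (n_modules > 0) {
      member <- sample(g, n_modules * module_size)
      module_assignments[member] <- rep(seq_len(n_modules), each = module_size)
      module_factors <- matrix(rnorm(n * n_modules), n, n_modules)
      module_loadings <- matrix(0, n_modules, g)
      for (md in seq_len(n_modules)) {
        in_md <- which(module_assignments == md)
        module_loadings[md, in_md] <- rnorm(length(in_md), mean = 0, sd = module_sd) +
          sample(c(-1, 1), 1) * module_sd  # coherent sign so the module co-expresses
      }
      Y <- Y + module_factors %*% module_loadings
    }
    dimnames(Y) <- list(subj, genes)
    attr(Y, "standardized") <- FALSE
    list(expression = Y,
         covariates = F_known,
         truth = list(F = F_known, U = U, Z = Z, B = B, beta = beta,
                      module_assignments = module_assignments,
                      module_factors = module_factors,
                      module_loadings = module_loadings,
                      factor_noise_sd = factor_noise_sd,
                      noise_sd = noise_sd, seed = seed))
  })
}

#' Generate synthetic genotype dosages with cis SNPs per gene
#'
#' Each gene receives `snps_per_gene` SNPs placed uniformly within
#' `window` bp of its TSS (so every gene has cis SNPs by construction);
#' dosages are Binomial(2, maf) draws with per-SNP minor-allele
#' frequencies uniform in `maf_range`.
#'
#' @param n Number of subjects (subject ids match
#'   [generate_expression()]).
#' @param annotation Gene annotation tibble giving TSS positions.
#' @param snps_per_gene SNPs per gene (default 2).
#' @param maf_range Minor-allele frequency range, a sub-interval of
#'   (0, 0.5] (default 0.1-0.5).
#' @param window Placement half-window in bp (default 100000).
#' @param seed Seed.
#' @return A `genotypes` object.
#' @export
generate_genotypes <- function(n, annotation, snps_per_gene = 2,
                               maf_range = c(0.1, 0.5), window = 100000,
                               seed = 1) {
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2]) {
    stop("maf_range must lie within (0, 0.5]", call. = FALSE)
  }
  with_seed(seed, {
    s <- nrow(annotation) * snps_per_gene
    subj <- pad_ids("S", n)
    snp_id <- pad_ids("rs", s)
    gene_idx <- rep(seq_len(nrow(annotation)), each = snps_per_gene)
    pos <- pmax(1L, as.integer(annotation$tss[gene_idx] +
                                 round(runif(s, -window, window))))
    maf <- runif(s, maf_range[1], maf_range[2])
    dos <- vapply(maf, function(p) rbinom(n, 2, p), numeric(n))
    dimnames(dos) <- list(subj, snp_id)
    genotypes(dos, tibble::tibble(snp_id = snp_id,
                                  chrom = annotation$chrom[gene_idx],
                                  pos = pos))
  })
}

#' Plant cis-eQTL effects into an expression matrix
#'
#' For a random fraction of genes, adds `effect_size * dosage` of one
#' randomly chosen cis SNP (within `window` of the gene's TSS) to the
#' gene's expression column. Genes without any cis SNP are skipped with a
#' message.
#'
#' @param Y Subjects-by-genes expression matrix.
#' @param geno A `genotypes` object over the same subjects.
#' @param annotation Gene annotation tibble.
#' @param fraction_of_genes Fraction of genes receiving an effect
#'   (default 0.2).
#' @param effect_size Additive effect per dosage unit (default 1).
#' @param window cis window in bp (default 100000).
#' @param seed Seed.
#' @return A list: `expression` (with effects added) and `truth` (tibble
#'   `gene_id`, `snp_id`, `effect`).
#' @export
plant_eqtls <- function(Y, geno, annotation, fraction_of_genes = 0.2,
                        effect_size = 1, window = 100000, seed = 1) {
  stopifnot(inherits(geno, "genotypes"))
  if (!identical(rownames(Y), rownames(geno$dosages))) {
    stop("expression and genotype subjects must match", call. = FALSE)
  }
  with_seed(seed, {
    n_target <- floor(fraction_of_genes * ncol(Y))
    chosen <- sample(colnames(Y), n_target)
    rows <- list()
    skipped <- 0L
    for (gid in chosen) {
      a <- annotation[annotation$gene_id == gid, ]
      cis <- geno$snp_map$snp_id[geno$snp_map$chrom == a$chrom &
                                   abs(geno$snp_map$pos - a$tss) <= window]
      if (length(cis) == 0) {
        skipped <- skipped + 1L
        next
      }
      snp <- if (length(cis) == 1) cis else sample(cis, 1)
      d <- geno$dosages[, snp]
      d[is.na(d)] <- 0
      Y[, gid] <- Y[, gid] + effect_size * d
      rows[[gid]] <- tibble::tibble(gene_id = gid, snp_id = snp,
                                    effect = effect_size)
    }
    if (skipped > 0) message(sprintf("skipped %d gene(s) without cis SNPs", skipped))
    list(expression = Y, truth = dplyr::bind_rows(rows))
  })
}

#' Generate function-term labels aligned with planted modules
#'
#' Each term draws `round(purity * size)` of its genes from one module and
#' the rest from the remaining genes, emulating GO-style gene sets whose
#' members co-express.
#'
#' @param module_assignments Named integer vector (gene -> module, `NA`
#'   for background), as produced by [generate_expression()].
#' @param terms_per_module Terms generated per module (default 2).
#' @param size_range Inclusive term-size range (default `c(30, 60)`).
#' @param purity Fraction of each term drawn from its module (default
#'   0.9).
#' @param seed Seed.
#' @return A `function_labels` list (term -> gene ids); term names encode
#'   the source module.
#' @export
generate_function_labels <- function(module_assignments, terms_per_module = 2,
                                     size_range = c(30, 60), purity = 0.9,
                                     seed = 1) {
  mods <- sort(unique(module_assignments[!is.na(module_assignments)]))
  if (length(mods) == 0) stop("no modules present", call. = FALSE)
  genes <- names(module_assignments)
  with_seed(seed, {
    sets <- list()
    for (md in mods) {
      in_md <- genes[!is.na(module_assignments) & module_assignments == md]
      out_md <- setdiff(genes, in_md)
      sizes <- seq(size_range[1], size_range[2])
      for (t in seq_len(terms_per_module)) {
        size <- if (length(sizes) == 1) sizes else sample(sizes, 1)
        n_in <- round(purity * size)
        n_out <- size - n_in
        if (n_in > length(in_md) || n_out > length(out_md)) {
          stop(sprintf("infeasible term size %d for module %d (module has %d genes)",
                       size, md, length(in_md)), call. = FALSE)
        }
        sets[[sprintf("term_m%d_%d", md, t)]] <-
          c(sample(in_md, n_in), sample(out_md, n_out))
      }
    }
    structure(sets, class = "function_labels")
  })
}

#' Convert log2 expression to Poisson read counts
#'
#' Optional count-emission layer for exercising the count-based
#' preprocessing path: expected counts are `2^expression` scaled per
#' subject by a log-normal depth factor, and observed counts are Poisson
#' draws around them.
#'
#' @param expression Subjects-by-genes log2-scale expression matrix.
#' @param depth_log_sd SD of per-subject log2 depth factors (default 0.5).
#' @param mean_count Target mean count scale (default 50).
#' @param seed Seed.
#' @return A count matrix (subjects x genes).
#' @export
expression_to_counts <- function(expression, depth_log_sd = 0.5,
                                 mean_count = 50, seed = 1) {
  with_seed(seed, {
    lam <- 2^expression
    lam <- lam * (mean_count / mean(lam))
    depth_factor <- 2^rnorm(nrow(expression), sd = depth_log_sd)
    lam <- lam * depth_factor
    counts <- matrix(rpois(length(lam), lam), nrow(lam), ncol(lam),
                     dimnames = dimnames(expression))
    counts
  })
}
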