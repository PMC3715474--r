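toy_genotypes <- function(pos, chrom = "chr1", n = 4, seed = 61) {
  s <- length(pos)
  dos <- withr::with_seed(seed,
    matrix(sample(0:2, n * s, replace = TRUE), n, s,
           dimnames = list(sprintf("S%02d", seq_len(n)),
                           sprintf("rs%02d", seq_len(s)))))
  genotypes(dos, tibble::tibble(snp_id = colnames(dos),
                                chrom = rep_len(chrom, s), pos = pos))
}

test_that("cis pairing is boundary-inclusive and assigns SNPs to the closest gene", {
  ann <- toy_annotation(c("gA", "gB"), tss = c(1000000, 1200000))
  geno <- toy_genotypes(c(1100000, 1100001, 1040000, 900000 - 1, 1250000))
  pairs <- pair_cis(ann, geno, window = 100000)

  # rs01 at exactly 100 kb of gA (and of gB): tie broken by lower TSS
  expect_equal(pairs$gene_id[pairs$snp_id == "rs01"], "gA")
  # rs02 at 100001 bp from gA, 99999 of gB -> paired with gB only
  expect_equal(pairs$gene_id[pairs$snp_id == "rs02"], "gB")
  # rs03: 40 kb from gA, 160 kb from gB -> closest gene gA
  expect_equal(pairs$gene_id[pairs$snp_id == "rs03"], "gA")
  # rs04 beyond the window of both genes
  expect_false("rs04" %in% pairs$snp_id)
  # each SNP at most once
  expect_false(any(duplicated(pairs$snp_id)))
  # signed distances
  expect_equal(pairs$distance_bp[pairs$snp_id == "rs03"], 40000)

  geno2 <- toy_genotypes(5000, chrom = "chrX")
  expect_warning(p2 <- pair_cis(ann, geno2), "no shared chromosomes")
  expect_equal(nrow(p2), 0)
})

test_that("spearman scan recovers perfect association and matches rank formulas", {
  n <- 10
  dos <- matrix(rep(c(0, 1, 2, 1, 0), 2), n, 1,
                dimnames = list(sprintf("S%02d", 1:n), "rs01"))
  dos[c(2, 7), 1] <- c(2, 0)
  geno <- genotypes(dos, tibble::tibble(snp_id = "rs01", chrom = "chr1", pos = 1000))
  expr <- matrix(as.numeric(dos[, 1]), n, 1,
                 dimnames = list(rownames(dos), "gA"))
  attr(expr, "standardized") <- FALSE
  pairs <- tibble::tibble(gene_id = "gA", snp_id = "rs01", distance_bp = 0)
  res <- spearman_scan(expr, geno, pairs)
  expect_equal(res$rho, 1)
  expect_equal(res$n, n)

  # 6-subject toy pair: rho equals brute-force Pearson on mid-ranks
  expr6 <- matrix(c(2.3, -1.1, 0.5, 0.5, 3.2, -0.7), 6, 1,
                  dimnames = list(sprintf("S%02d", 1:6), "gA"))
  attr(expr6, "standardized") <- FALSE
  dos6 <- matrix(c(0, 1, 2, 2, 1, 0), 6, 1,
                 dimnames = list(rownames(expr6), "rs01"))
  geno6 <- genotypes(dos6, tibble::tibble(snp_id = "rs01", chrom = "chr1", pos = 1))
  res6 <- spearman_scan(expr6, geno6, pairs)
  expect_equal(res6$rho, pearson_formula(rank(expr6[, 1]), rank(dos6[, 1])))
})

test_that("spearman p-values agree with cor.test and behave under the null", {
  # t-approximation path (n >= 8) against stats::cor.test
  withr::with_seed(62, {
    y <- rnorm(20)
    d <- sample(0:2, 20, replace = TRUE)
  })
  st <- hcpnorm:::spearman_test(y, d)
  ref <- suppressWarnings(cor.test(y, d, method = "spearman"))
  expect_equal(unname(st["rho"]), unname(ref$estimate), tolerance = 1e-10)
  tref <- unname(ref$estimate) * sqrt(18 / (1 - unname(ref$estimate)^2))
  expect_equal(unname(st["p"]), 2 * pt(-abs(tref), 18), tolerance = 1e-10)

  # exact-permutation path (n < 8) against cor.test's exact p (tie-free)
  withr::with_seed(63, {
    y7 <- rnorm(7)
    d7 <- sample(7)
  })
  st7 <- hcpnorm:::spearman_test(y7, d7)
  ref7 <- cor.test(y7, d7, method = "spearman", exact = TRUE)
  expect_equal(unname(st7["rho"]), unname(ref7$estimate), tolerance = 1e-10)
  expect_equal(unname(st7["p"]), ref7$p.value, tolerance = 1e-10)

  # independent permuted dosage: weak correlation, non-tiny p
  withr::with_seed(64, {
    y50 <- rnorm(50)
    d50 <- sample(rep(0:2, length.out = 50))
  })
  st50 <- hcpnorm:::spearman_test(y50, d50)
  expect_lt(abs(st50[["rho"]]), 0.35)
  expect_gt(st50[["p"]], 0.01)
})

test_that("the scan is invariant to strictly monotone per-gene transforms", {
  sim <- generate_expression(n = 20, g = 10, seed = 65)
  ann <- generate_gene_annotation(10, seed = 66)
  geno <- generate_genotypes(20, ann, snps_per_gene = 1, seed = 67)
  pairs <- pair_cis(ann, geno)
  Y <- sim$expression
  res1 <- suppressMessages(spearman_scan(Y, geno, pairs))
  Y2 <- exp(2 * Y) + 5  # strictly monotone transform per gene
  attr(Y2, "standardized") <- FALSE
  res2 <- suppressMessages(spearman_scan(Y2, geno, pairs))
  expect_equal(res1$rho, res2$rho, tolerance = 1e-12)
  expect_equal(res1$p, res2$p, tolerance = 1e-12)
})

test_that("missing and monomorphic dosages are handled pairwise-complete", {
  n <- 12
  expr <- random_expression(n, 2, seed = 68)
  colnames(expr) <- c("gA", "gB")
  dos <- matrix(c(rep(c(0, 1, 2), 4), rep(1, n)), n, 2,
                dimnames = list(rownames(expr), c("rs01", "rs02")))
  dos[1:3, 1] <- NA
  geno <- genotypes(dos, tibble::tibble(snp_id = c("rs01", "rs02"),
                                        chrom = "chr1", pos = c(1, 2)))
  pairs <- tibble::tibble(gene_id = c("gA", "gB"), snp_id = c("rs01", "rs02"),
                          distance_bp = c(0, 0))
  expect_message(res <- spearman_scan(expr, geno, pairs), "dropped 1 pair")
  expect_equal(nrow(res), 1)  # monomorphic rs02 dropped
  expect_equal(res$n, n - 3L) # missing dosages excluded pairwise
  ref <- cor(rank(expr[4:n, "gA"]), rank(dos[4:n, 1]))
  expect_equal(res$rho, ref, tolerance = 1e-12)
})

test_that("BH adjustment reproduces the step-up procedure", {
  p <- c(0.01, 0.02, 0.03, 0.5)
  expect_equal(bh_fdr(p), c(0.04, 0.04, 0.04, 0.5))

  withr::with_seed(69, pr <- runif(37))
  expect_equal(bh_fdr(pr), bh_brute(pr), tolerance = 1e-12)

  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_fdr(0.07), 0.07)
  expect_error(bh_fdr(c(0.5, 0)), "0, 1")
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("discovery counting is correct and monotone in the FDR level", {
  res <- tibble::tibble(gene_id = c("g1", "g1", "g2", "g3"),
                        snp_id = paste0("rs", 1:4),
                        p = c(0.01, 0.02, 0.03, 0.5),
                        q = bh_fdr(c(0.01, 0.02, 0.03, 0.5)))
  cts <- count_discoveries(res)
  expect_equal(cts$n_pairs[cts$level == 0.05], 3)
  expect_equal(cts$n_genes[cts$level == 0.05], 2)
  expect_true(all(diff(cts$n_pairs) >= 0))

  empty <- res[0, ]
  cts0 <- count_discoveries(empty)
  expect_true(all(cts0$n_pairs == 0))
})

test_that("gene-level p-values take the per-gene minimum", {
  res <- tibble::tibble(gene_id = c("g1", "g1", "g2"),
                        snp_id = paste0("rs", 1:3),
                        p = c(0.4, 0.1, 0.2))
  gp <- gene_level_pvalues(res)
  expect_equal(gp[["g1"]], 0.1)
  expect_equal(gp[["g2"]], 0.2)
})

test_that("cross-dataset consistency computes Spearman rho with a Fisher CI", {
  withr::with_seed(70, pa <- setNames(runif(40), paste0("k", 1:40)))
  expect_equal(consistency(pa, pa)$rho, 1)
  rev_ranked <- setNames(1 - pa, names(pa))
  expect_equal(consistency(pa, rev_ranked)$rho, -1)

  withr::with_seed(71, pb <- setNames(runif(40), paste0("k", 1:40)))
  got <- consistency(pa, pb)
  expect_equal(got$rho, pearson_formula(rank(pa), rank(pb)), tolerance = 1e-12)
  expect_lt(got$ci_lower, got$rho)
  expect_gt(got$ci_upper, got$rho)
  expect_equal(got$n_shared, 40)
  expect_error(consistency(pa[1:5], pb[1:5]), "fewer than 10")
})

test_that("pairwise overlap fractions follow set arithmetic", {
  mk <- function(genes, snps, q) tibble::tibble(gene_id = genes, snp_id = snps, q = q)
  a <- mk(c("g1", "g2", "g3"), c("r1", "r2", "r3"), c(0.01, 0.05, 0.5))
  b <- mk(c("g1", "g2", "g3"), c("r1", "r2", "r3"), c(0.01, 0.05, 0.05))
  ov <- pairwise_overlap(list(a = a, b = b), level = 0.10)
  expect_equal(ov["a", "a"], 1)
  # a discovers {1,2}, b discovers {1,2,3}: nested sets
  expect_equal(ov["a", "b"], 1)
  expect_equal(ov["b", "a"], 2 / 3)

  disjoint <- mk(c("g9"), c("r9"), 0.01)
  ov2 <- pairwise_overlap(list(a = a, d = disjoint), level = 0.10)
  expect_equal(ov2["a", "d"], 0)

  none <- mk("g1", "r1", 0.9)
  ov3 <- pairwise_overlap(list(a = a, n = none), level = 0.10)
  expect_true(is.na(ov3["n", "a"]))
})
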