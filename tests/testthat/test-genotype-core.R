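test_that("variant filtering applies strict MAF and call-rate cuts", {
  gm <- toy_geno_with_mafs(c(0.01, 0.05, 0.06, 0.3, 0.5))
  kept <- filter_variants(gm, maf_min = 0.05, call_rate_min = 0)
  expect_equal(nrow(kept$variants), 3) # strict >: 0.05 itself is dropped
  expect_setequal(kept$variants$maf, c(0.06, 0.3, 0.5))

  # 94% call rate fails a strict 95% cut
  gm2 <- toy_geno_with_mafs(c(0.3, 0.3))
  gm2$dosages[1:6, 2] <- NA
  gm2 <- geno_matrix(gm2$dosages, gm2$variants[, 1:5], gm2$donors)
  kept2 <- filter_variants(gm2, maf_min = 0, call_rate_min = 0.95)
  expect_equal(kept2$variants$id, "v1")

  # vacuous filter keeps everything; filtering is idempotent
  expect_equal(nrow(filter_variants(gm, 0, 0)$variants), 5)
  once <- filter_variants(gm, 0.05, 0.9)
  twice <- filter_variants(once, 0.05, 0.9)
  expect_identical(once$dosages, twice$dosages)
})

test_that("malformed dosage values are rejected", {
  expect_error(
    geno_matrix(matrix(c(0, 3), 1), tibble::tibble(
      chrom = "c", pos = 1:2, id = c("a", "b"), ref = "A", alt = "G")),
    "dosages")
})

test_that("PCA agrees with an independent eigendecomposition", {
  set.seed(11)
  gm <- sim_genotypes(sim_config(n_donors = 40, n_variants = 150,
                                 related_pairs = c(), seed = 8))
  pca <- genotype_pca(gm, k = 4)
  # oracle: eigen-decompose the standardized genotype crossproduct
  X <- gm$dosages
  p <- colMeans(X) / 2
  keep <- p > 0 & p < 1
  Z <- sweep(X[, keep], 2, 2 * p[keep], "-")
  Z <- sweep(Z, 2, sqrt(2 * p[keep] * (1 - p[keep])), "/")
  eg <- eigen(tcrossprod(Z), symmetric = TRUE)
  for (j in 1:4) {
    ref <- eg$vectors[, j] * sqrt(eg$values[j])
    expect_equal(abs(ref), abs(unname(pca$scores[, j])), tolerance = 1e-8)
  }
  expect_equal(pca$variance_fraction,
               (eg$values / sum(eg$values))[1:4], tolerance = 1e-10)
})

test_that("PCA output satisfies its structural contracts", {
  gm <- sim_genotypes(sim_config(n_donors = 50, n_variants = 300,
                                 n_populations = 2, fst = 0.1,
                                 population_weights = c(a = 0.5, b = 0.5),
                                 related_pairs = c(), seed = 4))
  pca <- genotype_pca(gm, k = 5)
  expect_true(all(diff(pca$variance_fraction) <= 1e-12))
  expect_lte(sum(pca$variance_fraction), 1)
  expect_lt(max(abs(colMeans(pca$scores))), 1e-8)
  expect_true(all(colSums(pca$loadings) >= 0)) # deterministic sign
  # distinct populations separate on the leading components
  expect_gt(silhouette_mean(pca$scores[, 1:2], gm$populations), 0)
})

test_that("degenerate PCA inputs are rejected", {
  D <- matrix(1, 5, 4) # identical donors: no variation after centering
  gm <- geno_matrix(D, tibble::tibble(chrom = "c", pos = 1:4,
                                      id = paste0("v", 1:4),
                                      ref = "A", alt = "G"))
  expect_error(genotype_pca(gm, k = 2), "variation|rank")
  gm2 <- sim_genotypes(sim_config(n_donors = 5, n_variants = 50,
                                  related_pairs = c(), seed = 1))
  expect_error(genotype_pca(gm2, k = 6), "exceeds")
})

test_that("kinship estimator reproduces hand-counted contingency examples", {
  # duplicate genotypes give exactly 0.5
  g <- c(0, 1, 2, 1, 0, 1)
  expect_equal(king_kinship(g, g)$phi, 0.5)
  # four-site hand count: 2 shared hets, 2 opposite homozygotes
  res <- king_kinship(c(0, 1, 2, 1), c(2, 1, 0, 1))
  expect_equal(res$phi, -0.5)
  expect_equal(res$n_used, 4L)
  # no heterozygous sites: undefined
  expect_warning(res0 <- king_kinship(c(0, 2, 0), c(2, 0, 2)), "undefined")
  expect_true(is.na(res0$phi))
})

test_that("pairwise kinship matches the brute-force contingency oracle", {
  set.seed(21)
  n <- 8
  D <- matrix(rbinom(n * 500, 2, 0.4), n)
  D[sample(length(D), 100)] <- NA
  gm <- geno_matrix(D, tibble::tibble(chrom = "c", pos = seq_len(500),
                                      id = paste0("v", 1:500),
                                      ref = "A", alt = "G"),
                    donors = paste0("d", 1:n))
  kin <- kinship_pairs(gm, filter = FALSE)
  for (r in sample(nrow(kin), 10)) {
    i <- match(kin$donor_i[r], gm$donors)
    j <- match(kin$donor_j[r], gm$donors)
    expect_equal(kin$phi[r], kinship_bruteforce(D[i, ], D[j, ]))
    expect_equal(kin$phi[r], king_kinship(D[i, ], D[j, ])$phi)
  }
})

test_that("relatedness degrees map phi through the half-open intervals", {
  expect_equal(as.character(classify_relatedness(0.2)), "first")
  expect_equal(as.character(classify_relatedness(0.0442)), "third")
  expect_equal(as.character(classify_relatedness(-0.1)), "unrelated")
  expect_equal(as.character(classify_relatedness(0.0884)), "second")
  expect_equal(as.character(classify_relatedness(0.177)), "first")
  expect_equal(as.character(classify_relatedness(0.354)), "twin")
  expect_equal(as.character(classify_relatedness(0.5)), "twin")
  expect_true(is.na(classify_relatedness(NA_real_)))
})

test_that("unrelated pairs from one population have near-zero kinship", {
  freqs <- runif(10000, 0.05, 0.95)
  phis <- vapply(1:20, function(s) {
    set.seed(s)
    king_kinship(rbinom(10000, 2, freqs), rbinom(10000, 2, freqs))$phi
  }, numeric(1))
  expect_true(all(abs(phis) < 0.0442))
  expect_lt(abs(mean(phis)), 0.02)
})
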