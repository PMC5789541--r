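test_that("variance explained is exact for perfect fits and calibrated nulls", {
  set.seed(31)
  pcs <- matrix(rnorm(200 * 5), 200, 5)
  # perfect linear combination of the PCs
  y <- pcs %*% c(1, -2, 0.5, 0, 3)
  expect_equal(variance_explained(y, pcs), 1, tolerance = 1e-12)
  # null expectation E[R2] = k / (n - 1) with k = 5 regressors
  r2s <- replicate(400, variance_explained(rnorm(200), pcs))
  expect_lt(abs(mean(r2s) - 5 / 199), 0.005)
  # signal at matched noise: R2 -> 0.5
  n <- 5000
  pcs_big <- matrix(rnorm(n * 5), n, 5)
  y_sig <- pcs_big[, 1] + rnorm(n, 0, 1)
  expect_lt(abs(variance_explained(y_sig, pcs_big) - 0.5), 0.05)
  # degenerate inputs
  expect_warning(r <- variance_explained(rep(1, 200), pcs), "constant")
  expect_true(is.na(r))
  expect_warning(variance_explained(c(1, 2, NA, NA, NA, NA, NA, NA,
                                      rep(NA, 192)), pcs), "complete cases")
})

test_that("empirical p-values follow the add-one counting rule", {
  set.seed(32)
  Y <- matrix(rnorm(60 * 6), 60, 6,
              dimnames = list(NULL, paste0("f", 1:6)))
  tab <- toy_transformed_table(Y)
  pcs <- matrix(rnorm(60 * 5), 60, 5)
  res <- permutation_test(tab, pcs, B = 200, seed = 7, keep_perms = TRUE)
  # recompute each p from the stored permutation draws
  for (f in rownames(res$r2_perm)) {
    obs <- res$features$r2_obs[res$features$feature == f]
    expect_equal(res$features$p_emp[res$features$feature == f],
                 (1 + sum(res$r2_perm[f, ] >= obs)) / 201)
  }
  expect_true(all(res$features$p_emp >= 1 / 201))
  # site-level p follows the same rule on the permutation means
  expect_equal(res$p_site,
               (1 + sum(res$perm_mean_r2 >= res$mean_r2_obs)) / 201)
  # z is the standardized site mean
  expect_equal(res$z, (res$mean_r2_obs - mean(res$perm_mean_r2)) /
                 sd(res$perm_mean_r2))
})

test_that("permutation results are reproducible under a fixed seed", {
  set.seed(33)
  Y <- matrix(rnorm(40 * 4), 40, 4, dimnames = list(NULL, paste0("f", 1:4)))
  tab <- toy_transformed_table(Y)
  pcs <- matrix(rnorm(40 * 5), 40, 5)
  a <- permutation_test(tab, pcs, B = 150, seed = 5)
  b <- permutation_test(tab, pcs, B = 150, seed = 5)
  expect_identical(a$features, b$features)
  expect_identical(a$perm_mean_r2, b$perm_mean_r2)
  c <- permutation_test(tab, pcs, B = 150, seed = 6)
  expect_false(identical(a$perm_mean_r2, c$perm_mean_r2))
})

test_that("a dominant planted signal hits the empirical p floor", {
  set.seed(34)
  pcs <- matrix(rnorm(100 * 5), 100, 5)
  rownames(pcs) <- sprintf("d%03d", 1:100)
  Y <- cbind(hit = pcs[, 1] * 3 + rnorm(100, 0, 0.1),
             miss = rnorm(100))
  rownames(Y) <- rownames(pcs)
  res <- permutation_test(toy_transformed_table(Y), pcs, B = 100, seed = 1)
  expect_equal(res$features$p_emp[res$features$feature == "hit"], 1 / 101)
})

test_that("missing pathway values are excluded feature-wise", {
  set.seed(35)
  Y <- matrix(rnorm(50 * 3), 50, 3, dimnames = list(NULL, paste0("p", 1:3)))
  Y[sample(50, 10), 2] <- NA
  tab <- toy_transformed_table(Y, kind = "pathway")
  pcs <- matrix(rnorm(50 * 5), 50, 5)
  res <- permutation_test(tab, pcs, B = 100, seed = 2)
  expect_equal(nrow(res$features), 3)
  expect_true(all(is.finite(res$features$r2_obs)))
  # complete-feature R2 agrees with the dense code path
  dense <- permutation_test(toy_transformed_table(Y[, c(1, 3)]), pcs,
                            B = 100, seed = 2)
  expect_equal(res$features$r2_obs[c(1, 3)], dense$features$r2_obs,
               tolerance = 1e-12)
})

test_that("BH adjustment matches the hand-computed step-up", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_equal(bh_fdr(numeric(0)), numeric(0))
  expect_error(bh_fdr(c(0.5, 0)), "0, 1")
  # ordering consistency: q >= p and monotone in rank
  p <- sort(runif(20))
  q <- bh_fdr(p)
  expect_true(all(q >= p - 1e-12))
  expect_true(all(diff(q) >= -1e-12))
})

test_that("rank enrichment scores skewed classes by Beta order statistics", {
  ranking <- paste0("pwy", 1:100)
  # single member at the very top: p = Beta(1,1) CDF at 0.01, times k = 1
  single <- rank_enrichment(ranking,
                            tibble::tibble(feature = "pwy1",
                                           superclass = "solo"))
  expect_equal(single$p, 0.01)
  # three members occupying the top three ranks
  top3 <- rank_enrichment(ranking,
                          tibble::tibble(feature = paste0("pwy", 1:3),
                                         superclass = "top"))
  # brute-force evaluation of the minimum tail over j = 1..3
  tails <- c(pbeta(0.01, 1, 3), pbeta(0.02, 2, 2), pbeta(0.03, 3, 1))
  expect_equal(top3$score, min(tails))
  expect_equal(top3$p, min(1, 3 * min(tails)))
  expect_lt(top3$p, 1e-3)
  # scattered class: corrected minimum is not small
  scattered <- rank_enrichment(ranking,
                               tibble::tibble(feature = paste0("pwy", c(20, 50, 80)),
                                              superclass = "mid"))
  expect_gt(scattered$p, 0.3)
  expect_warning(
    rank_enrichment(ranking, tibble::tibble(feature = "absent",
                                            superclass = "ghost")),
    "no ranked members")
})

test_that("rank enrichment p-values are super-uniform under random rankings", {
  set.seed(36)
  ps <- replicate(200, {
    ranking <- sample(paste0("f", 1:100))
    rank_enrichment(ranking,
                    tibble::tibble(feature = paste0("f", 1:5),
                                   superclass = "c"))$p
  })
  expect_lte(mean(ps < 0.05), 0.08)
  expect_gt(mean(ps), 0.4)
})

test_that("the Wilcoxon alternative flags the same extreme class", {
  ranking <- paste0("f", 1:50)
  cls <- tibble::tibble(feature = paste0("f", 1:5), superclass = "top")
  beta_p <- rank_enrichment(ranking, cls)$p
  wil_p <- rank_enrichment(ranking, cls, method = "wilcoxon")$p
  expect_lt(beta_p, 0.01)
  expect_lt(wil_p, 0.01)
})
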