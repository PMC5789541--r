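#' Robust pairwise kinship coefficient from dosage vectors
#'
#' Estimates the kinship coefficient phi between two donors from
#' heterozygote sharing and opposite-homozygote counts, in the style of the
#' KING-robust estimator. With `N_AaAa` the number of sites heterozygous in
#' both donors, `N_AAaa` the number of sites with opposite homozygotes, and
#' `N_Aa_i`, `N_Aa_j` the per-donor heterozygote counts (over the shared
#' non-missing sites):
#'
#' \deqn{\phi = \frac{N_{Aa,Aa} - 2 N_{AA,aa}}{N_{Aa}^{(i)} + N_{Aa}^{(j)}}}
#'
#' The sum-denominator form has expectation equal to the kinship
#' coefficient for non-inbred pairs and returns exactly 0.5 for duplicate
#' genotypes. Sites missing in either donor are excluded.
#'
#' @param g_i,g_j Equal-length dosage vectors (0/1/2/NA).
#' @return A one-row tibble with `phi`, `n_used` (sites non-missing in
#'   both), and `degree` from [classify_relatedness()]. If neither donor
#'   has a heterozygous site the estimator is undefined and `phi` is `NA`
#'   with a warning.
#' @examples
#' king_kinship(c(0, 1, 2, 1), c(2, 1, 0, 1)) # phi = -0.5
#' @export
king_kinship <- function(g_i, g_j) {
  if (length(g_i) != length(g_j)) stop("genotype vectors differ in length")
  ok <- !is.na(g_i) & !is.na(g_j)
  gi <- g_i[ok]
  gj <- g_j[ok]
  n_het_both <- sum(gi == 1 & gj == 1)
  n_opp_hom <- sum((gi == 0 & gj == 2) | (gi == 2 & gj == 0))
  denom <- sum(gi == 1) + sum(gj == 1)
  if (denom == 0) {
    warning("no heterozygous sites in either donor; phi undefined")
    phi <- NA_real_
  } else {
    phi <- (n_het_both - 2 * n_opp_hom) / denom
  }
  tibble::tibble(phi = phi, n_used = sum(ok),
                 degree = classify_relatedness(phi))
}

#' All-pairs kinship for a genotype matrix
#'
#' Computes the robust kinship coefficient for every unordered donor pair.
#' By default the matrix is first restricted to common, well-called
#' variants (the same filter used before PCA).
#'
#' @param gm A [geno_matrix()].
#' @param maf_min,call_rate_min Passed to [filter_variants()]; set
#'   `filter = FALSE` to skip filtering.
#' @param filter Apply the MAF/call-rate filter first? Default `TRUE`.
#' @return A tibble with one row per unordered pair: `donor_i`, `donor_j`,
#'   `phi`, `n_used`, `degree`.
#' @examples
#' gm <- sim_genotypes(sim_config(n_donors = 10, n_variants = 2000, seed = 1))
#' kin <- kinship_pairs(gm)
#' table(kin$degree)
#' @export
kinship_pairs <- function(gm, maf_min = 0.05, call_rate_min = 0.95,
                          filter = TRUE) {
  stopifnot(inherits(gm, "geno_matrix"))
  if (filter) gm <- filter_variants(gm, maf_min, call_rate_min)
  D <- gm$dosages
  M <- !is.na(D)
  H <- (D == 1) & M
  A0 <- (D == 0) & M
  A2 <- (D == 2) & M
  storage.mode(M) <- storage.mode(H) <- "double"
  storage.mode(A0) <- storage.mode(A2) <- "double"
  n_het_both <- tcrossprod(H)
  n_opp <- tcrossprod(A0, A2)
  n_opp <- n_opp + t(n_opp)
  # per-pair heterozygote counts restricted to jointly non-missing sites
  het_on_shared <- tcrossprod(H, M)
  denom <- het_on_shared + t(het_on_shared)
  n_used <- tcrossprod(M)
  phi <- ifelse(denom > 0, (n_het_both - 2 * n_opp) / denom, NA_real_)
  idx <- which(upper.tri(phi), arr.ind = TRUE)
  out <- tibble::tibble(
    donor_i = gm$donors[idx[, 1]],
    donor_j = gm$donors[idx[, 2]],
    phi = phi[idx],
    n_used = as.integer(n_used[idx])
  )
  if (anyNA(out$phi)) {
    warning(sum(is.na(out$phi)),
            " pair(s) with no heterozygous sites; phi undefined")
  }
  out$degree <- classify_relatedness(out$phi)
  out
}

#' Classify a kinship coefficient into a relatedness degree
#'
#' Maps phi onto the conventional half-open classification intervals:
#' below 0.0442 unrelated; \[0.0442, 0.0884) third degree; \[0.0884, 0.177)
#' second degree; \[0.177, 0.354) first degree; 0.354 and above twin
#' (the published ranges leave exactly 0.354 unassigned; this
#' measure-zero boundary is assigned to twin).
#'
#' @param phi Numeric vector of kinship coefficients.
#' @return A factor with levels `unrelated`, `third`, `second`, `first`,
#'   `twin`; `NA` phi maps to `NA`.
#' @examples
#' classify_relatedness(c(0.2, 0.0442, -0.1, 0.5))
#' @export
classify_relatedness <- function(phi) {
  cut(phi,
      breaks = c(-Inf, 0.0442, 0.0884, 0.177, 0.354, Inf),
      labels = c("unrelated", "third", "second", "first", "twin"),
      right = FALSE)
}
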