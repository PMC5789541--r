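#' Principal component analysis of genotype dosages
#'
#' Computes leading principal components of population structure from a
#' donor x variant dosage matrix, following the standard GWAS convention:
#' missing dosages are mean-imputed per variant, each variant column is
#' centered by twice its allele frequency estimate and scaled by
#' `sqrt(2 p (1 - p))` (the binomial standard deviation under
#' Hardy-Weinberg equilibrium), monomorphic columns are dropped, and the
#' top `k` left singular directions are returned. Apply
#' [filter_variants()] first to restrict to common, well-called variants.
#'
#' Component signs are fixed so that each loading vector has a nonnegative
#' sum, making output deterministic across platforms.
#'
#' @param gm A [geno_matrix()].
#' @param k Number of components (default 5).
#' @return An object of class `geno_pca` with elements `scores` (donor x k
#'   matrix, column means zero), `loadings` (variant x k), and
#'   `variance_fraction` (length-k eigenvalue shares, nonincreasing).
#' @examples
#' gm <- sim_genotypes(sim_config(n_donors = 60, n_variants = 500,
#'                                n_populations = 2, fst = 0.1, seed = 1))
#' pca <- genotype_pca(gm, k = 2)
#' glance(pca)
#' @export
genotype_pca <- function(gm, k = 5) {
  stopifnot(inherits(gm, "geno_matrix"))
  X <- gm$dosages
  if (k > nrow(X) || k > ncol(X)) {
    stop("k = ", k, " exceeds the matrix dimensions")
  }
  p <- colMeans(X, na.rm = TRUE) / 2
  all_missing <- is.nan(p)
  if (any(all_missing)) {
    warning(sum(all_missing), " all-missing variant(s) dropped")
  }
  mono <- !all_missing & (p <= 0 | p >= 1)
  keep <- !all_missing & !mono
  X <- X[, keep, drop = FALSE]
  p <- p[keep]
  # mean imputation, then standardization to unit HWE variance
  for (j in which(colSums(is.na(X)) > 0)) {
    X[is.na(X[, j]), j] <- 2 * p[j]
  }
  Z <- sweep(X, 2, 2 * p, "-")
  Z <- sweep(Z, 2, sqrt(2 * p * (1 - p)), "/")
  sv <- svd(Z)
  tol <- max(dim(Z)) * .Machine$double.eps * sv$d[1]
  rank_z <- sum(sv$d > tol)
  if (rank_z == 0) stop("genotype matrix has no variation (identical donors)")
  if (k > rank_z) {
    stop("k = ", k, " exceeds the rank (", rank_z, ") of the genotype matrix")
  }
  flip <- ifelse(colSums(sv$v[, seq_len(k), drop = FALSE]) < 0, -1, 1)
  scores <- sweep(sv$u[, seq_len(k), drop = FALSE] %*%
                    diag(sv$d[seq_len(k)], k), 2, flip, "*")
  loadings <- sweep(sv$v[, seq_len(k), drop = FALSE], 2, flip, "*")
  rownames(scores) <- gm$donors
  colnames(scores) <- paste0("PC", seq_len(k))
  rownames(loadings) <- gm$variants$id[keep]
  colnames(loadings) <- colnames(scores)
  structure(
    list(scores = scores, loadings = loadings,
         variance_fraction = sv$d[seq_len(k)]^2 / sum(sv$d^2),
         n_variants_used = ncol(Z)),
    class = "geno_pca"
  )
}

#' @export
print.geno_pca <- function(x, ...) {
  cat("<geno_pca> ", nrow(x$scores), " donors, ", ncol(x$scores),
      " components (", x$n_variants_used, " variants)\n", sep = "")
  cat("  variance fractions:",
      paste(signif(x$variance_fraction, 3), collapse = ", "), "\n")
  invisible(x)
}

#' Tidy donor scores from a genotype PCA
#'
#' @param x A `geno_pca` object.
#' @param ... Ignored.
#' @return A tibble with `donor` and one column per component (`PC1`, ...).
#' @method tidy geno_pca
#' @export
tidy.geno_pca <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(donor = rownames(x$scores)),
                   tibble::as_tibble(x$scores))
}

#' @method glance geno_pca
#' @export
glance.geno_pca <- function(x, ...) {
  tibble::tibble(
    component = colnames(x$scores),
    variance_fraction = x$variance_fraction
  )
}

#' Plot donor coordinates on the first two genetic principal components
#'
#' @param object A `geno_pca` object.
#' @param group Optional factor/character vector (one value per donor, in
#'   donor order) used to color points, e.g. self-reported ethnicity.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot geno_pca
#' @export
autoplot.geno_pca <- function(object, group = NULL, ...) {
  df <- tidy(object)
  lab <- function(i) {
    sprintf("PC%d (%.1f%%)", i, 100 * object$variance_fraction[i])
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2))
  if (!is.null(group)) {
    df$group <- group
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2,
                                          colour = .data$group)) +
      ggplot2::labs(colour = "group")
  }
  p + ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = lab(1), y = lab(2)) +
    ggplot2::theme_minimal()
}
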