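#' Variance in a feature explained by genetic principal components
#'
#' Ordinary least squares of a (log-transformed) microbial feature on an
#' intercept plus the leading principal component scores;
#' `r2 = 1 - SS_res / SS_tot`. Missing feature values are excluded
#' pairwise.
#'
#' @param y Numeric feature vector, aligned with the rows of `pcs`.
#' @param pcs Numeric donor x k score matrix (typically k = 5).
#' @param min_cases Minimum complete cases required (default 8).
#' @return The R-squared, or `NA` (with a warning) if `y` is constant or
#'   has fewer than `min_cases` complete observations.
#' @examples
#' pcs <- matrix(rnorm(500), 100, 5)
#' variance_explained(pcs[, 1] + rnorm(100), pcs)
#' @export
variance_explained <- function(y, pcs, min_cases = 8) {
  pcs <- as.matrix(pcs)
  if (length(y) != nrow(pcs)) stop("y and pcs are not aligned")
  ok <- !is.na(y) & stats::complete.cases(pcs)
  if (sum(ok) < min_cases) {
    warning("fewer than ", min_cases, " complete cases; r2 undefined")
    return(NA_real_)
  }
  yy <- y[ok]
  if (stats::var(yy) == 0) {
    warning("constant feature; r2 undefined")
    return(NA_real_)
  }
  fit <- stats::lm.fit(cbind(1, pcs[ok, , drop = FALSE]), yy)
  1 - sum(fit$residuals^2) / sum((yy - mean(yy))^2)
}

#' Permutation-null test of PC-microbiome association
#'
#' For every feature of a transformed abundance table, computes the
#' variance explained by the genetic principal components, then builds a
#' permutation null by shuffling the donor labels `B` times. Each
#' permutation applies ONE shared donor shuffle to all features, which
#' preserves the correlation structure between features and makes the
#' site-level mean statistic exchangeable under the null.
#'
#' Per feature, the empirical p-value is the add-one proportion of
#' permuted R-squared values at least as large as the observed one,
#' `(1 + #\{r2_perm >= r2_obs\}) / (B + 1)`, bounded below by `1/(B+1)`.
#' At the site level the per-permutation mean R-squared over features
#' yields a Z-score, `(mean_r2_obs - mean(perm)) / sd(perm)`, and an
#' empirical p-value of the same add-one form. Benjamini-Hochberg
#' q-values are attached across features.
#'
#' @param table A transformed [abundance_table()], one row per donor
#'   (apply [average_replicates()], [prevalence_filter()] and
#'   [log_transform()] first).
#' @param pcs A donor x k score matrix with donor rownames, or a
#'   `geno_pca` object.
#' @param B Number of permutations (>= 100; 10000 for production runs).
#' @param seed Integer seed controlling the shuffles.
#' @param keep_perms Keep the full feature x B matrix of permuted
#'   R-squared values (element `r2_perm`)? Default `FALSE` to save memory.
#' @return An object of class `perm_assoc`: `features` tibble (`feature`,
#'   `r2_obs`, `p_emp`, `q`), and site-level fields `mean_r2_obs`,
#'   `perm_mean_r2` (length B), `z`, `p_site`, `B`, `seed`.
#' @export
permutation_test <- function(table, pcs, B = 10000, seed = 1,
                             keep_perms = FALSE) {
  stopifnot(inherits(table, "abundance_tbl"))
  if (!is_transformed(table)) {
    stop("permutation_test expects a log-transformed table")
  }
  if (B < 100) stop("B must be at least 100")
  if (inherits(pcs, "geno_pca")) pcs <- pcs$scores
  pcs <- as.matrix(pcs)
  if (!is.null(rownames(pcs))) {
    idx <- match(table$donor, rownames(pcs))
    if (anyNA(idx)) {
      stop("donors absent from the PC scores: ",
           paste(table$donor[is.na(idx)], collapse = ", "))
    }
    pcs <- pcs[idx, , drop = FALSE]
  } else if (nrow(pcs) != nrow(table)) {
    stop("pcs rows do not align with the table")
  }
  Y <- feature_matrix(table)
  n <- nrow(Y)
  keep <- apply(Y, 2, function(y) {
    sum(!is.na(y)) >= 8 && stats::var(y, na.rm = TRUE) > 0
  })
  if (!all(keep)) {
    warning(sum(!keep), " constant or near-empty feature(s) skipped")
    Y <- Y[, keep, drop = FALSE]
  }
  perms <- with_seed(seed, {
    replicate(B, sample.int(n), simplify = FALSE)
  })
  if (!anyNA(Y)) {
    X <- cbind(1, pcs)
    Q <- qr.Q(qr(X))
    ss_tot <- colSums(sweep(Y, 2, colMeans(Y))^2)
    r2_of <- function(Ym) {
      1 - colSums((Ym - Q %*% crossprod(Q, Ym))^2) / ss_tot
    }
    r2_obs <- r2_of(Y)
    r2_perm <- vapply(perms, function(p) r2_of(Y[p, , drop = FALSE]),
                      numeric(ncol(Y)))
  } else {
    r2_one <- function(y, idx_perm = seq_len(n)) {
      yp <- y[idx_perm]
      ok <- !is.na(yp)
      fit <- stats::lm.fit(cbind(1, pcs[ok, , drop = FALSE]), yp[ok])
      1 - sum(fit$residuals^2) / sum((yp[ok] - mean(yp[ok]))^2)
    }
    r2_obs <- apply(Y, 2, r2_one)
    r2_perm <- vapply(perms, function(p) apply(Y, 2, r2_one, idx_perm = p),
                      numeric(ncol(Y)))
  }
  r2_perm <- matrix(r2_perm, nrow = ncol(Y)) # features x B
  p_emp <- (1 + rowSums(r2_perm >= r2_obs)) / (B + 1)
  mean_obs <- mean(r2_obs)
  perm_means <- colMeans(r2_perm)
  sd_perm <- stats::sd(perm_means)
  if (sd_perm == 0) {
    warning("permutation means are constant; Z undefined")
    z <- NA_real_
  } else {
    z <- (mean_obs - mean(perm_means)) / sd_perm
  }
  out <- structure(
    list(
      features = tibble::tibble(
        feature = colnames(Y), r2_obs = r2_obs, p_emp = p_emp,
        q = bh_fdr(p_emp)),
      mean_r2_obs = mean_obs,
      perm_mean_r2 = perm_means,
      z = z,
      p_site = (1 + sum(perm_means >= mean_obs)) / (B + 1),
      B = B, seed = seed,
      body_site = unique(table$body_site)
    ),
    class = "perm_assoc"
  )
  if (keep_perms) {
    out$r2_perm <- r2_perm
    rownames(out$r2_perm) <- colnames(Y)
  }
  out
}

#' @export
print.perm_assoc <- function(x, ...) {
  cat("<perm_assoc> ", nrow(x$features), " features, B = ", x$B,
      " permutations (", x$body_site, ")\n", sep = "")
  cat(sprintf("  mean R2 = %.4f, Z = %.2f, site empirical p = %.4g\n",
              x$mean_r2_obs, x$z, x$p_site))
  cat("  features with q < 0.05: ", sum(x$features$q < 0.05), "\n", sep = "")
  invisible(x)
}

#' Per-feature results of a permutation association test
#' @param x A `perm_assoc` object.
#' @param ... Ignored.
#' @return Tibble with `feature`, `r2_obs`, `p_emp`, `q`, sorted by
#'   decreasing `r2_obs`.
#' @method tidy perm_assoc
#' @export
tidy.perm_assoc <- function(x, ...) {
  dplyr::arrange(x$features, dplyr::desc(.data$r2_obs), .data$feature)
}

#' @method glance perm_assoc
#' @export
glance.perm_assoc <- function(x, ...) {
  tibble::tibble(
    body_site = x$body_site,
    n_features = nrow(x$features),
    mean_r2_obs = x$mean_r2_obs,
    z = x$z,
    p_site = x$p_site,
    B = x$B
  )
}

#' Plot the site-level permutation null against the observed mean R2
#'
#' @param object A `perm_assoc` object.
#' @param ... Ignored.
#' @return A ggplot: histogram of permuted mean R-squared values with the
#'   observed value as a vertical line.
#' @method autoplot perm_assoc
#' @export
autoplot.perm_assoc <- function(object, ...) {
  df <- tibble::tibble(perm_mean_r2 = object$perm_mean_r2)
  ggplot2::ggplot(df, ggplot2::aes(.data$perm_mean_r2)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$mean_r2_obs, colour = "red") +
    ggplot2::labs(
      x = "permuted mean R2", y = "permutations",
      title = sprintf("%s: Z = %.2f, empirical p = %.4g",
                      object$body_site, object$z, object$p_site)) +
    ggplot2::theme_minimal()
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment (a thin wrapper over
#' [stats::p.adjust()] with input validation).
#'
#' @param pvals Numeric vector of p-values in (0, 1].
#' @return Adjusted q-values, monotone in rank and capped at 1.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_fdr <- function(pvals) {
  if (length(pvals) == 0) return(numeric(0))
  if (any(pvals <= 0 | pvals > 1, na.rm = TRUE)) {
    stop("p-values must lie in (0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Rank-based superclass enrichment
#'
#' Given features ranked by decreasing association strength (e.g. by
#' observed R-squared from [permutation_test()]), asks for each feature
#' class whether its members are skewed towards the top of the ranking.
#' The default score is the robust-rank-aggregation construction: with
#' normalized member ranks `r_(1) <= ... <= r_(k)` out of `n` features,
#' the score is the minimum Beta order-statistic tail probability
#' `rho = min_j P(Beta(j, k - j + 1) <= r_(j))`, Bonferroni-corrected to
#' `p = min(1, k * rho)`. A Wilcoxon rank-sum alternative (members vs
#' non-members, one-sided towards low ranks) is available for sensitivity
#' checks.
#'
#' @param feature_ranking Character vector of feature names ordered by
#'   decreasing association strength (ties pre-broken deterministically).
#' @param class_map Data frame with columns `feature`, `superclass` (or a
#'   named character vector, names = features).
#' @param method `"beta"` (default) or `"wilcoxon"`.
#' @return A tibble with one row per superclass: `superclass`, `k`
#'   (members found in the ranking), `score` (the minimum order-statistic
#'   tail, or the Wilcoxon statistic), `p`, and `ranks` (list-column of
#'   normalized member ranks, ascending).
#' @examples
#' ranking <- paste0("pwy", 1:100)
#' cls <- tibble::tibble(feature = ranking,
#'                       superclass = rep(c("A", "B"), each = 50))
#' rank_enrichment(ranking, cls)
#' @export
rank_enrichment <- function(feature_ranking, class_map,
                            method = c("beta", "wilcoxon")) {
  method <- match.arg(method)
  if (is.character(class_map) && !is.null(names(class_map))) {
    class_map <- tibble::tibble(feature = names(class_map),
                                superclass = unname(class_map))
  }
  class_map <- tibble::as_tibble(class_map)
  stopifnot(all(c("feature", "superclass") %in% names(class_map)))
  n <- length(feature_ranking)
  purrr::map_dfr(split(class_map$feature, class_map$superclass),
                 .id = "superclass", function(members) {
    ranks <- sort(match(members, feature_ranking))
    ranks <- ranks[!is.na(ranks)]
    k <- length(ranks)
    if (k == 0) {
      warning("class with no ranked members skipped")
      return(tibble::tibble(k = 0L, score = NA_real_, p = NA_real_,
                            ranks = list(numeric(0))))
    }
    r <- ranks / n
    if (method == "beta") {
      tails <- stats::pbeta(r, seq_len(k), k - seq_len(k) + 1)
      score <- min(tails)
      p <- min(1, k * score)
    } else {
      others <- setdiff(seq_len(n), ranks)
      wt <- stats::wilcox.test(ranks, others, alternative = "less",
                               exact = FALSE)
      score <- unname(wt$statistic)
      p <- wt$p.value
    }
    tibble::tibble(k = k, score = score, p = p, ranks = list(r))
  }) |>
    dplyr::arrange(.data$p)
}
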