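#' Encode a genotype dosage under a genetic model
#'
#' @param dosage Numeric vector of alternate-allele dosages (0/1/2/NA).
#' @param model `"additive"` (dosage passes through as 0/1/2) or
#'   `"recessive"` (1 if homozygous alternate, else 0). Missing dosages
#'   propagate.
#' @return Numeric vector of encoded genotypes.
#' @examples
#' encode_genotype(c(0, 1, 2, NA), "recessive")
#' @export
encode_genotype <- function(dosage, model = c("additive", "recessive")) {
  model <- match.arg(model)
  bad <- !is.na(dosage) & !(dosage %in% c(0, 1, 2))
  if (any(bad)) {
    stop("invalid dosage value(s): ",
         paste(unique(dosage[bad]), collapse = ", "))
  }
  if (model == "additive") as.numeric(dosage) else as.numeric(dosage == 2)
}

# Build a full-rank covariate design matrix (intercept + one-hot factors
# with first-level reference). Errors name the collinear columns.
covariate_design <- function(covars, n) {
  if (is.null(covars)) return(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  covars <- as.data.frame(covars, stringsAsFactors = TRUE)
  covars[] <- lapply(covars, function(x) if (is.character(x)) factor(x) else x)
  C <- stats::model.matrix(~ ., data = covars)
  qrC <- qr(C)
  if (qrC$rank < ncol(C)) {
    drop_cols <- colnames(C)[qrC$pivot[(qrC$rank + 1):ncol(C)]]
    stop("rank-deficient covariates; collinear column(s): ",
         paste(drop_cols, collapse = ", "))
  }
  C
}

#' Covariate-adjusted linear association of one variant with one feature
#'
#' Fits the ordinary linear model `y ~ genotype + covariates` via
#' residualization: `y` and the encoded genotype are both residualized on
#' the covariate design (intercept plus one-hot categorical covariates),
#' the Pearson correlation `r` of the residuals gives
#' `t = r * sqrt(df / (1 - r^2))` with `df = n - rank(design) - 1`, and
#' the slope is recovered as `cov(res_y, res_g) / var(res_g)`. This is
#' exactly the OLS coefficient t-test for the genotype term in the full
#' model (the Matrix-eQTL computation), at a fraction of the cost.
#' Complete-case deletion is applied over `y`, `g` and the covariates.
#'
#' @param y Numeric (transformed) feature values.
#' @param g Encoded genotype vector (see [encode_genotype()]).
#' @param covars Optional data frame of covariates (e.g. sex, ethnicity,
#'   collection site); character columns are treated as factors.
#' @return A one-row tibble: `beta`, `t_stat`, `p` (two-sided), `n`
#'   (complete cases), `df`, `note` (`NA` or the reason the test was
#'   skipped). A genotype that is constant after case deletion is skipped
#'   (`note = "constant genotype"`); a genotype collinear with the
#'   covariates is an error.
#' @export
linear_assoc <- function(y, g, covars = NULL) {
  if (length(y) != length(g)) stop("y and g are not aligned")
  ok <- !is.na(y) & !is.na(g)
  if (!is.null(covars)) ok <- ok & stats::complete.cases(covars)
  C <- covariate_design(if (is.null(covars)) NULL else
    as.data.frame(covars)[ok, , drop = FALSE], sum(ok))
  n <- sum(ok)
  skipped <- function(note) {
    tibble::tibble(beta = NA_real_, t_stat = NA_real_, p = NA_real_,
                   n = n, df = NA_integer_, note = note)
  }
  if (n < ncol(C) + 3) return(skipped("too few complete cases"))
  yy <- y[ok]
  gg <- g[ok]
  if (stats::var(gg) == 0) return(skipped("constant genotype"))
  qrC <- qr(C)
  res_y <- qr.resid(qrC, yy)
  res_g <- qr.resid(qrC, gg)
  if (sum(res_g^2) < 1e-12 * sum(gg^2)) {
    stop("genotype is collinear with the covariates")
  }
  df <- n - qrC$rank - 1
  r <- sum(res_y * res_g) / sqrt(sum(res_y^2) * sum(res_g^2))
  if (!is.finite(r)) return(skipped("constant feature"))
  r <- max(min(r, 1), -1)
  t_stat <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  tibble::tibble(
    beta = sum(res_y * res_g) / sum(res_g^2),
    t_stat = t_stat,
    p = 2 * stats::pt(-abs(t_stat), df),
    n = n, df = as.integer(df), note = NA_character_
  )
}

#' Targeted screen of one genotype against every feature of a table
#'
#' Runs either a dosage regression ([linear_assoc()]) or a two-sample
#' t-test (for recessive-coded 0/1 genotypes) of each feature against a
#' single genotype, and attaches Benjamini-Hochberg q-values across the
#' screen. This is the workhorse for candidate-variant questions such as
#' secretor-status (additive dosage) or hypolactasia (recessive, t-test)
#' effects on individual taxa.
#'
#' @param table A transformed [abundance_table()], one row per donor.
#' @param g Encoded genotype vector named by donor, or aligned with the
#'   table rows.
#' @param covars Optional covariate data frame (regression mode only).
#' @param test `"regression"` or `"t_test"`.
#' @param welch In t-test mode, use the Welch (unequal variance) form?
#'   Default `FALSE` (pooled-variance Student's t).
#' @return A tibble with one row per feature: `feature`, `beta` (slope,
#'   or group mean difference in t-test mode), `t_stat`, `p`, `n`, `q`,
#'   `note`.
#' @export
targeted_screen <- function(table, g, covars = NULL,
                            test = c("regression", "t_test"),
                            welch = FALSE) {
  stopifnot(inherits(table, "abundance_tbl"))
  if (!is_transformed(table)) stop("targeted_screen expects a transformed table")
  test <- match.arg(test)
  if (!is.null(names(g))) {
    idx <- match(table$donor, names(g))
    if (anyNA(idx)) {
      stop("donors absent from the genotype vector: ",
           paste(table$donor[is.na(idx)], collapse = ", "))
    }
    g <- g[idx]
  } else if (length(g) != nrow(table)) {
    stop("genotype vector does not align with the table")
  }
  Y <- feature_matrix(table)
  res <- purrr::map_dfr(colnames(Y), function(f) {
    y <- Y[, f]
    if (test == "regression") {
      rec <- linear_assoc(y, g, covars)
    } else {
      ok <- !is.na(y) & !is.na(g)
      g1 <- y[ok & g == 1]
      g0 <- y[ok & g == 0]
      if (length(g1) < 2 || length(g0) < 2) {
        rec <- tibble::tibble(beta = NA_real_, t_stat = NA_real_,
                              p = NA_real_, n = sum(ok), df = NA_integer_,
                              note = "group with fewer than 2 members")
      } else if (stats::sd(g1) == 0 && stats::sd(g0) == 0 &&
                 mean(g1) == mean(g0)) {
        rec <- tibble::tibble(beta = 0, t_stat = 0, p = 1,
                              n = sum(ok),
                              df = as.integer(length(g1) + length(g0) - 2),
                              note = NA_character_)
      } else {
        tt <- stats::t.test(g1, g0, var.equal = !welch)
        rec <- tibble::tibble(beta = mean(g1) - mean(g0),
                              t_stat = unname(tt$statistic),
                              p = tt$p.value, n = sum(ok),
                              df = as.integer(round(unname(tt$parameter))),
                              note = NA_character_)
      }
    }
    dplyr::bind_cols(tibble::tibble(feature = f), rec)
  })
  res$q <- NA_real_
  tested <- !is.na(res$p)
  res$q[tested] <- bh_fdr(res$p[tested])
  res
}

#' Genome-wide association scan of variants against microbiome features
#'
#' Applies the covariate-adjusted linear model of [linear_assoc()] to
#' every (variant, feature) pair, after restricting the genotype matrix
#' to the donors present in the abundance table and to variants with
#' minor allele frequency above `maf_min` (computed on those donors).
#' The total number of tests performed is recorded in the `n_tests`
#' attribute for exact Bonferroni bookkeeping.
#'
#' @param gm A [geno_matrix()].
#' @param table A transformed [abundance_table()], one row per donor.
#' @param covars Optional covariate data frame aligned with the table
#'   rows (sex, ethnicity, collection site).
#' @param maf_min Strict lower MAF bound (default 0.1).
#' @param variant_subset Optional character vector of variant ids
#'   restricting the scan (e.g. a GWAS-catalog-style list).
#' @param model Genetic model passed to [encode_genotype()].
#' @return A tibble with one row per test: `chrom`, `pos`, `id`,
#'   `feature`, `body_site`, `beta`, `t_stat`, `p`, `n`, `df`, `note`;
#'   attribute `n_tests` holds the test count.
#' @export
gwas_scan <- function(gm, table, covars = NULL, maf_min = 0.1,
                      variant_subset = NULL,
                      model = c("additive", "recessive")) {
  stopifnot(inherits(gm, "geno_matrix"), inherits(table, "abundance_tbl"))
  if (!is_transformed(table)) stop("gwas_scan expects a transformed table")
  model <- match.arg(model)
  idx <- match(table$donor, gm$donors)
  if (anyNA(idx)) {
    stop("donors absent from the genotype matrix: ",
         paste(table$donor[is.na(idx)], collapse = ", "))
  }
  gm <- gm[idx, ] # recomputes maf/call_rate on the analysis donors
  if (!is.null(variant_subset)) {
    gm <- gm[, gm$variants$id %in% variant_subset]
  }
  gm <- filter_variants(gm, maf_min = maf_min, call_rate_min = 0)
  Y <- feature_matrix(table)
  G <- apply(gm$dosages, 2, encode_genotype, model = model)
  body_site <- unique(table$body_site)
  vinfo <- gm$variants
  fast <- !anyNA(Y) && !anyNA(G) && is.null(covars) ||
    (!anyNA(Y) && !anyNA(G) && !is.null(covars) &&
       all(stats::complete.cases(covars)))
  if (fast) {
    C <- covariate_design(covars, nrow(Y))
    qrC <- qr(C)
    df <- nrow(Y) - qrC$rank - 1
    res_Y <- qr.resid(qrC, Y)
    res_G <- qr.resid(qrC, G)
    ss_y <- colSums(res_Y^2)
    ss_g <- colSums(res_G^2)
    keep_g <- ss_g > 1e-12
    cross <- crossprod(res_G[, keep_g, drop = FALSE], res_Y) # V x F
    r <- cross / sqrt(outer(ss_g[keep_g], ss_y))
    r <- pmax(pmin(r, 1), -1)
    t_stat <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
    beta <- cross / ss_g[keep_g]
    vi <- vinfo[keep_g, ]
    V <- sum(keep_g)
    F_n <- ncol(Y)
    out <- tibble::tibble(
      chrom = rep(vi$chrom, times = F_n),
      pos = rep(vi$pos, times = F_n),
      id = rep(vi$id, times = F_n),
      feature = rep(colnames(Y), each = V),
      body_site = body_site,
      beta = as.vector(beta),
      t_stat = as.vector(t_stat),
      p = as.vector(2 * stats::pt(-abs(t_stat), df)),
      n = nrow(Y), df = as.integer(df), note = NA_character_
    )
  } else {
    out <- purrr::map_dfr(seq_len(ncol(G)), function(v) {
      purrr::map_dfr(colnames(Y), function(f) {
        rec <- linear_assoc(Y[, f], G[, v], covars)
        dplyr::bind_cols(
          tibble::tibble(chrom = vinfo$chrom[v], pos = vinfo$pos[v],
                         id = vinfo$id[v], feature = f,
                         body_site = body_site),
          rec)
      })
    })
  }
  attr(out, "n_tests") <- sum(!is.na(out$p))
  out
}

#' Bonferroni-corrected significance threshold
#'
#' @param n_tests Total number of tests performed (>= 1).
#' @param alpha Family-wise error rate (default 0.05).
#' @return `alpha / n_tests`.
#' @examples
#' bonferroni_threshold(1.66e10) # ~ 3e-12
#' @export
bonferroni_threshold <- function(n_tests, alpha = 0.05) {
  if (n_tests < 1) stop("n_tests must be at least 1")
  alpha / n_tests
}

#' Clump nearby associations for one feature into groups
#'
#' Greedy single-pass positional clumping: records (one feature, one
#' contig, sorted by position) are split into groups wherever the gap to
#' the previous record exceeds `max_gap` base pairs; a gap of exactly
#' `max_gap` stays in the same group. Each group is represented by its
#' smallest-p member (ties broken by smaller position).
#'
#' @param records A tibble of association records for a single feature
#'   and contig, sorted ascending by `pos`, with columns `pos` and `p`
#'   (other columns are carried along).
#' @param max_gap Maximum within-group gap in bp (default 10000).
#' @return A tibble with one row per clump: the representative record's
#'   columns plus `clump` (index), `span_start`, `span_end`, `n_members`,
#'   and a `members` list-column of the full group.
#' @export
clump_associations <- function(records, max_gap = 10000) {
  records <- tibble::as_tibble(records)
  stopifnot(all(c("pos", "p") %in% names(records)))
  if ("feature" %in% names(records) &&
      length(unique(records$feature)) > 1) {
    stop("clump_associations expects records for a single feature")
  }
  if ("chrom" %in% names(records) && length(unique(records$chrom)) > 1) {
    stop("clump_associations expects records for a single contig")
  }
  if (is.unsorted(records$pos)) {
    stop("records must be sorted ascending by position")
  }
  gap <- c(0, diff(records$pos))
  records$clump <- cumsum(gap > max_gap) + 1L
  records |>
    dplyr::group_by(.data$clump) |>
    dplyr::group_map(function(g, key) {
      rep_row <- g[order(g$p, g$pos), ][1, ]
      rep_row$clump <- key$clump
      rep_row$span_start <- min(g$pos)
      rep_row$span_end <- max(g$pos)
      rep_row$n_members <- nrow(g)
      rep_row$members <- list(g)
      rep_row
    }) |>
    dplyr::bind_rows()
}

#' Annotate variants with genes within a window
#'
#' A variant is annotated with every gene whose interval, expanded by
#' `window` bp on both sides, contains the variant position; a variant
#' inside a gene has distance 0.
#'
#' @param variants A tibble with columns `chrom`, `pos` and (optionally)
#'   `id`.
#' @param genes A tibble of gene intervals: `gene`, `chrom`, `start`,
#'   `end` (1-based inclusive; see [read_gene_bed()]).
#' @param window Window in bp (default 50000).
#' @return A tibble with one row per (variant, gene) hit: variant
#'   columns, `gene`, and `distance` (bp from the variant to the nearest
#'   interval edge, 0 if inside). Variants with no gene in range are
#'   absent.
#' @export
annotate_genes <- function(variants, genes, window = 50000) {
  variants <- tibble::as_tibble(variants)
  genes <- tibble::as_tibble(genes)
  stopifnot(all(c("chrom", "pos") %in% names(variants)),
            all(c("gene", "chrom", "start", "end") %in% names(genes)))
  if (any(genes$start > genes$end)) stop("gene intervals must have start <= end")
  dplyr::inner_join(variants, genes, by = "chrom",
                    relationship = "many-to-many") |>
    dplyr::mutate(distance = pmax(.data$start - .data$pos,
                                  .data$pos - .data$end, 0)) |>
    dplyr::filter(.data$distance <= window) |>
    dplyr::select(-"start", -"end")
}

#' Quantile-quantile points for a set of p-values
#'
#' @param pvals Numeric p-values in (0, 1]; zeros are clipped to the
#'   smallest positive double with a warning.
#' @return A tibble of `expected` and `observed` -log10 p-values (both
#'   descending), using the plotting positions `(i - 0.5) / m`, with an
#'   attribute `slope`: the through-origin regression slope of observed
#'   on expected (near 1 for well-calibrated tests).
#' @export
qq_points <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  pvals <- pvals[!is.na(pvals)]
  if (any(pvals == 0)) {
    warning("zero p-value(s) clipped to the smallest positive double")
    pvals[pvals == 0] <- .Machine$double.xmin
  }
  m <- length(pvals)
  out <- tibble::tibble(
    expected = -log10((seq_len(m) - 0.5) / m),
    observed = sort(-log10(pvals), decreasing = TRUE)
  )
  attr(out, "slope") <- sum(out$expected * out$observed) /
    sum(out$expected^2)
  out
}

#' Quantile-quantile plot of association p-values
#'
#' @param pvals Numeric p-values in (0, 1].
#' @return A ggplot of observed vs expected -log10 p with the identity
#'   line; systematic departure above the line indicates inflation.
#' @export
plot_qq <- function(pvals) {
  pts <- qq_points(pvals)
  ggplot2::ggplot(pts, ggplot2::aes(.data$expected, .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = expression(Expected ~ -log[10](p)),
                  y = expression(Observed ~ -log[10](p)),
                  title = sprintf("QQ slope = %.2f", attr(pts, "slope"))) +
    ggplot2::theme_minimal()
}
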