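#' Construct a genotype matrix
#'
#' Bundles an allele-dosage matrix (donors in rows, variants in columns,
#' values in \{0, 1, 2, NA\} counting copies of the alternate allele) with a
#' per-variant annotation table. Minor allele frequency and call rate are
#' recomputed from the dosages so they are always consistent with the data.
#'
#' @param dosages Numeric matrix, donors x variants, entries 0/1/2 or `NA`.
#' @param variants A data frame with one row per variant and at least
#'   columns `chrom`, `pos`, `id`, `ref`, `alt`. `maf` and `call_rate`
#'   columns are (re)computed here.
#' @param donors Character vector of donor ids; defaults to the rownames of
#'   `dosages`.
#' @return An object of class `geno_matrix`: a list with elements `dosages`
#'   (numeric matrix), `variants` (tibble with `maf` and `call_rate`) and
#'   `donors` (character vector).
#' @examples
#' gm <- geno_matrix(
#'   matrix(c(0, 1, 2, 1), nrow = 2, dimnames = list(c("d1", "d2"), NULL)),
#'   variants = tibble::tibble(chrom = "chr1", pos = c(100L, 200L),
#'                             id = c("v1", "v2"), ref = "A", alt = "G")
#' )
#' gm$variants$maf
#' @export
geno_matrix <- function(dosages, variants, donors = rownames(dosages)) {
  if (!is.matrix(dosages)) dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  bad <- !is.na(dosages) & !(dosages %in% c(0, 1, 2))
  if (any(bad)) {
    stop("dosages must be 0, 1, 2 or NA; found ",
         paste(unique(dosages[bad]), collapse = ", "))
  }
  if (is.null(donors)) donors <- paste0("donor", seq_len(nrow(dosages)))
  if (length(donors) != nrow(dosages)) {
    stop("length(donors) must equal nrow(dosages)")
  }
  variants <- tibble::as_tibble(variants)
  required <- c("chrom", "pos", "id", "ref", "alt")
  missing_cols <- setdiff(required, names(variants))
  if (length(missing_cols) > 0) {
    stop("variants table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(variants) != ncol(dosages)) {
    stop("nrow(variants) must equal ncol(dosages)")
  }
  if (any(variants$pos < 1)) stop("variant positions must be >= 1")
  rownames(dosages) <- donors
  colnames(dosages) <- variants$id
  variants$maf <- variant_maf(dosages)
  variants$call_rate <- colMeans(!is.na(dosages))
  structure(
    list(dosages = dosages, variants = variants, donors = as.character(donors)),
    class = "geno_matrix"
  )
}

variant_maf <- function(dosages) {
  p <- colMeans(dosages, na.rm = TRUE) / 2
  p[is.nan(p)] <- NA_real_
  pmin(p, 1 - p)
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("<geno_matrix> ", length(x$donors), " donors x ",
      nrow(x$variants), " variants\n", sep = "")
  cat("  MAF range: ",
      paste(signif(range(x$variants$maf, na.rm = TRUE), 3), collapse = " - "),
      "; mean call rate: ", signif(mean(x$variants$call_rate), 3), "\n", sep = "")
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosages)

#' Subset a genotype matrix
#'
#' @param x A [geno_matrix()].
#' @param i Donor index (logical, integer or character).
#' @param j Variant index (logical, integer or character on variant ids).
#' @param ... Ignored.
#' @return A new `geno_matrix` with recomputed per-variant `maf`/`call_rate`.
#' @export
`[.geno_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_along(x$donors)
  if (missing(j)) j <- seq_len(nrow(x$variants))
  if (is.character(j)) j <- match(j, x$variants$id)
  geno_matrix(x$dosages[i, j, drop = FALSE], x$variants[j, , drop = FALSE],
              donors = x$donors[i])
}

#' Filter variants by minor allele frequency and call rate
#'
#' Keeps variants with `maf > maf_min` and `call_rate > call_rate_min`
#' (both strict inequalities). Donor order is unchanged. The operation is
#' idempotent: applying the same filter twice gives the same matrix.
#'
#' @param gm A [geno_matrix()].
#' @param maf_min Minimum (exclusive) minor allele frequency, in [0, 0.5].
#'   Default 0.05, the conventional common-variant cut.
#' @param call_rate_min Minimum (exclusive) call rate, in [0, 1].
#'   Default 0.95.
#' @return A new `geno_matrix` containing only the passing variants.
#' @examples
#' gm <- sim_genotypes(sim_config(n_donors = 30, n_variants = 100, seed = 1))
#' filter_variants(gm, maf_min = 0.05, call_rate_min = 0.95)
#' @export
filter_variants <- function(gm, maf_min = 0.05, call_rate_min = 0.95) {
  stopifnot(inherits(gm, "geno_matrix"))
  if (maf_min < 0 || maf_min > 0.5) stop("maf_min must be in [0, 0.5]")
  if (call_rate_min < 0 || call_rate_min > 1) {
    stop("call_rate_min must be in [0, 1]")
  }
  keep <- !is.na(gm$variants$maf) &
    gm$variants$maf > maf_min &
    gm$variants$call_rate > call_rate_min
  if (!any(keep)) warning("no variants pass the filter")
  gm[, which(keep)]
}

#' Tidy per-variant summary of a genotype matrix
#'
#' @param x A [geno_matrix()].
#' @param ... Ignored.
#' @return A tibble with one row per variant: `chrom`, `pos`, `id`, `ref`,
#'   `alt`, `maf`, `call_rate`.
#' @method tidy geno_matrix
#' @export
tidy.geno_matrix <- function(x, ...) x$variants

#' @method glance geno_matrix
#' @export
glance.geno_matrix <- function(x, ...) {
  tibble::tibble(
    n_donors = length(x$donors),
    n_variants = nrow(x$variants),
    mean_maf = mean(x$variants$maf, na.rm = TRUE),
    mean_call_rate = mean(x$variants$call_rate),
    missing_frac = mean(is.na(x$dosages))
  )
}
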