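# Reserved metadata columns of an abundance table; everything else is a
# feature column.
abund_meta_cols <- c("sample_id", "donor", "body_site")

#' Construct an abundance table
#'
#' An abundance table is a wide tibble with one row per sample: metadata
#' columns `sample_id`, `donor`, `body_site`, followed by one numeric
#' column per microbial feature. Species tables hold relative abundances
#' in [0, 1]; pathway tables hold reads-per-million-scale abundances.
#' The feature kind and whether values are on the log10 scale are carried
#' as attributes (`kind`, `transformed`) that the preparation verbs check
#' and maintain.
#'
#' @param x A data frame with the three metadata columns and numeric
#'   feature columns.
#' @param kind `"species"` or `"pathway"`.
#' @param transformed Are the values already log10-transformed? Default
#'   `FALSE`.
#' @return A tibble of class `abundance_tbl`.
#' @export
abundance_table <- function(x, kind = c("species", "pathway"),
                            transformed = FALSE) {
  kind <- match.arg(kind)
  x <- tibble::as_tibble(x)
  missing_cols <- setdiff(abund_meta_cols, names(x))
  if (length(missing_cols) > 0) {
    stop("abundance table lacks columns: ",
         paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(x$sample_id)) {
    dup <- unique(x$sample_id[duplicated(x$sample_id)])
    stop("duplicated sample id(s): ", paste(dup, collapse = ", "))
  }
  if (length(unique(x$body_site)) > 1) {
    stop("an abundance table holds one body site; found: ",
         paste(unique(x$body_site), collapse = ", "))
  }
  feats <- feature_cols(x)
  vals <- as.matrix(x[feats])
  if (length(feats) > 0 && !is.numeric(vals)) {
    stop("non-numeric abundance values")
  }
  if (!transformed && any(vals < 0, na.rm = TRUE)) {
    stop("untransformed abundances must be nonnegative")
  }
  x <- x[c(abund_meta_cols, feats)]
  attr(x, "kind") <- kind
  attr(x, "transformed") <- transformed
  class(x) <- c("abundance_tbl", class(x))
  x
}

#' Feature column names of an abundance table
#' @param x An abundance table (or any data frame using the same layout).
#' @return Character vector of feature column names.
#' @export
feature_cols <- function(x) setdiff(names(x), abund_meta_cols)

#' Extract the feature values of an abundance table as a matrix
#' @param x An abundance table.
#' @return Numeric matrix, samples x features, rownames = sample ids.
#' @export
feature_matrix <- function(x) {
  m <- as.matrix(x[feature_cols(x)])
  rownames(m) <- x$sample_id
  m
}

is_transformed <- function(x) isTRUE(attr(x, "transformed"))

abund_kind <- function(x) attr(x, "kind") %||% "species"

set_features <- function(x, m) {
  out <- dplyr::bind_cols(tibble::as_tibble(x)[abund_meta_cols],
                          tibble::as_tibble(m))
  attr(out, "kind") <- attr(x, "kind")
  attr(out, "transformed") <- attr(x, "transformed")
  class(out) <- c("abundance_tbl", class(out))
  out
}

#' @export
print.abundance_tbl <- function(x, ...) {
  cat("<abundance_tbl> ", nrow(x), " samples x ", length(feature_cols(x)),
      " ", abund_kind(x), " features (",
      if (is_transformed(x)) "log10" else "raw", " scale), body site: ",
      unique(x$body_site), "\n", sep = "")
  NextMethod()
}

#' Average replicate samples per donor
#'
#' When a donor contributed several samples at the same body site, their
#' abundance profiles are collapsed into one row per donor by taking the
#' arithmetic mean on the raw abundance scale. Averaging on the log scale
#' would answer a different question (a geometric mean), so transformed
#' tables are rejected.
#'
#' @param t An untransformed [abundance_table()].
#' @return An abundance table with one row per donor; `sample_id` is the
#'   donor id. Donors with a single sample pass through unchanged.
#' @examples
#' tab <- abundance_table(tibble::tibble(
#'   sample_id = c("a1", "a2"), donor = "a", body_site = "stool",
#'   sp1 = c(0.2, 0.4), sp2 = c(0.8, 0.6)))
#' average_replicates(tab)
#' @export
average_replicates <- function(t) {
  stopifnot(inherits(t, "abundance_tbl"))
  if (is_transformed(t)) {
    stop("average_replicates is defined on raw relative abundances; ",
         "got a transformed table")
  }
  out <- t |>
    tibble::as_tibble() |>
    dplyr::group_by(.data$donor, .data$body_site) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(feature_cols(t)),
                                   ~ mean(.x, na.rm = TRUE)),
                     .groups = "drop") |>
    dplyr::mutate(sample_id = .data$donor)
  abundance_table(out, kind = abund_kind(t), transformed = FALSE)
}

#' Filter features by prevalence
#'
#' Presence is defined as abundance strictly greater than zero. Species
#' screens conventionally keep features present in *at least* a fraction
#' of samples (non-strict, default threshold 0.25); pathway screens keep
#' features present in *more than* a fraction (strict, default 0.75).
#' The default strictness therefore follows the table's `kind`.
#'
#' @param t An untransformed [abundance_table()].
#' @param threshold Prevalence threshold in [0, 1]. Defaults to 0.25 for
#'   species tables and 0.75 for pathway tables.
#' @param strict If `TRUE` keep features with prevalence `> threshold`;
#'   if `FALSE` keep `>= threshold`. Defaults by kind as described.
#' @return The filtered abundance table.
#' @export
prevalence_filter <- function(t, threshold = NULL, strict = NULL) {
  stopifnot(inherits(t, "abundance_tbl"))
  if (is_transformed(t)) {
    stop("prevalence_filter expects raw abundances (presence = value > 0)")
  }
  kind <- abund_kind(t)
  if (is.null(threshold)) threshold <- if (kind == "species") 0.25 else 0.75
  if (is.null(strict)) strict <- kind == "pathway"
  m <- feature_matrix(t)
  prev <- colMeans(m > 0, na.rm = TRUE)
  keep <- if (strict) prev > threshold else prev >= threshold
  if (!any(keep)) warning("no features pass the prevalence filter")
  out <- t[c(abund_meta_cols, feature_cols(t)[keep])]
  abundance_table(out, kind = kind, transformed = FALSE)
}

#' Log10-transform abundance values
#'
#' Two conventions are supported. `add_pseudocount` (for species relative
#' abundances) computes `log10(x + pseudocount)` for every entry, so zeros
#' map to `log10(pseudocount)` (-5 at the default 1e-5). `present_only`
#' (for pathway abundances) computes `log10(x)` only where `x > 0` and
#' records zeros as missing (`NA`); downstream model fits drop those
#' samples feature-by-feature.
#'
#' @param t An untransformed [abundance_table()].
#' @param pseudocount Positive pseudocount for `add_pseudocount` mode;
#'   default `1e-5`.
#' @param mode `"add_pseudocount"` or `"present_only"`. Defaults to
#'   `add_pseudocount` for species tables and `present_only` for pathway
#'   tables.
#' @return The transformed abundance table (`transformed` attribute set).
#' @examples
#' tab <- abundance_table(tibble::tibble(
#'   sample_id = "s1", donor = "d1", body_site = "stool",
#'   sp1 = 0, sp2 = 0.1))
#' feature_matrix(log_transform(tab)) # -5 and log10(0.10001)
#' @export
log_transform <- function(t, pseudocount = 1e-5,
                          mode = NULL) {
  stopifnot(inherits(t, "abundance_tbl"))
  if (is_transformed(t)) stop("table is already transformed")
  if (is.null(mode)) {
    mode <- if (abund_kind(t) == "species") "add_pseudocount" else "present_only"
  }
  mode <- match.arg(mode, c("add_pseudocount", "present_only"))
  m <- feature_matrix(t)
  if (mode == "add_pseudocount") {
    if (!is.numeric(pseudocount) || pseudocount <= 0) {
      stop("pseudocount must be positive")
    }
    m <- log10(m + pseudocount)
  } else {
    m[m <= 0] <- NA_real_
    m <- log10(m)
  }
  out <- set_features(t, m)
  attr(out, "transformed") <- TRUE
  out
}

#' Bray-Curtis dissimilarity between two abundance profiles
#'
#' `BC(x, y) = sum(|x - y|) / sum(x + y)`, computed on raw (untransformed)
#' nonnegative abundances. 0 means identical profiles, 1 disjoint support.
#' Community-level comparisons typically report the similarity `1 - BC`.
#'
#' @param x,y Nonnegative numeric vectors of equal length, not both
#'   all-zero.
#' @return The dissimilarity, a number in [0, 1].
#' @examples
#' bray_curtis(c(0.5, 0.5, 0), c(0.25, 0.25, 0.5)) # 0.5
#' @export
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) stop("profiles differ in length")
  if (any(x < 0, na.rm = TRUE) || any(y < 0, na.rm = TRUE)) {
    stop("abundances must be nonnegative")
  }
  tot <- sum(x + y)
  if (tot == 0) stop("Bray-Curtis undefined: both profiles are all-zero")
  sum(abs(x - y)) / tot
}

#' Pairwise Bray-Curtis similarity for an abundance table
#'
#' Computes `1 - BC` for every unordered pair of rows, via
#' [vegan::vegdist()]. Intended for donor-level tables (after
#' [average_replicates()]), on untransformed relative abundances over all
#' profiled features (before any prevalence filter), so the distance
#' describes whole communities.
#'
#' @param t An untransformed [abundance_table()].
#' @return A tibble with `donor_i`, `donor_j`, `similarity`.
#' @export
similarity_pairs <- function(t) {
  stopifnot(inherits(t, "abundance_tbl"))
  if (is_transformed(t)) stop("similarity is computed on raw abundances")
  m <- feature_matrix(t)
  rownames(m) <- t$donor
  d <- as.matrix(vegan::vegdist(m, method = "bray"))
  idx <- which(upper.tri(d), arr.ind = TRUE)
  tibble::tibble(
    donor_i = rownames(d)[idx[, 1]],
    donor_j = rownames(d)[idx[, 2]],
    similarity = 1 - d[idx]
  )
}
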