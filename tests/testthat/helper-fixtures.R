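# Small in-code fixtures shared across test files.

# A dosage matrix whose columns have prescribed allele frequencies
# (all-heterozygote encoding keeps the frequency exact).
toy_geno_with_mafs <- function(mafs, n_donors = 100) {
  stopifnot(all(mafs <= 0.5))
  cols <- lapply(mafs, function(f) {
    n_het <- round(2 * f * n_donors)
    c(rep(1, n_het), rep(0, n_donors - n_het))
  })
  D <- do.call(cbind, cols)
  geno_matrix(D, tibble::tibble(
    chrom = "chr1", pos = seq_along(mafs) * 1000L,
    id = paste0("v", seq_along(mafs)), ref = "A", alt = "G"
  ), donors = sprintf("d%03d", seq_len(n_donors)))
}

# Donor-level transformed abundance table from a plain matrix.
toy_transformed_table <- function(Y, kind = "species", body_site = "stool") {
  df <- dplyr::bind_cols(
    tibble::tibble(sample_id = rownames(Y) %||% sprintf("d%03d", seq_len(nrow(Y))),
                   donor = rownames(Y) %||% sprintf("d%03d", seq_len(nrow(Y))),
                   body_site = body_site),
    tibble::as_tibble(Y))
  abundance_table(df, kind = kind, transformed = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Mean silhouette width of a 2-group labelling in a coordinate matrix
# (independent of any clustering package; brute-force distances).
silhouette_mean <- function(coords, labels) {
  d <- as.matrix(stats::dist(coords))
  vapply(seq_len(nrow(coords)), function(i) {
    own <- labels == labels[i]
    a <- mean(d[i, own & seq_len(nrow(coords)) != i])
    b <- min(vapply(unique(labels[!own]), function(l) {
      mean(d[i, labels == l])
    }, numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1)) |> mean()
}

# Brute-force KING-style kinship from an explicit genotype-pair
# contingency table (independent of the package's counting code).
kinship_bruteforce <- function(g1, g2) {
  ok <- !is.na(g1) & !is.na(g2)
  tab <- table(factor(g1[ok], levels = 0:2), factor(g2[ok], levels = 0:2))
  n_het_both <- tab["1", "1"]
  n_opp <- tab["0", "2"] + tab["2", "0"]
  denom <- sum(tab["1", ]) + sum(tab[, "1"])
  (n_het_both - 2 * n_opp) / denom
}
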