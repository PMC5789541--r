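# All writers go through a temp-file rename so a crashed run never leaves
# a half-written table behind.
write_atomic <- function(write_fn, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  write_fn(tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' Write a genotype matrix as a minimal VCFv4.2 file
#'
#' Emits one synthetic contig and GT-only genotype columns, the smallest
#' dialect that standard VCF tooling accepts.
#'
#' @param gm A [geno_matrix()].
#' @param path Output path (plain text, `.vcf`).
#' @return The path, invisibly.
#' @export
write_vcf <- function(gm, path) {
  stopifnot(inherits(gm, "geno_matrix"))
  gt_map <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  write_atomic(function(tmp) {
    con <- file(tmp, "w")
    on.exit(close(con))
    writeLines(c(
      "##fileformat=VCFv4.2",
      paste0("##contig=<ID=", unique(gm$variants$chrom), ",length=50000000>"),
      "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
      paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
              "INFO", "FORMAT", gm$donors), collapse = "\t")
    ), con)
    gt <- matrix(gt_map[as.character(t(gm$dosages))],
                 nrow = nrow(gm$variants))
    gt[is.na(gt)] <- "./."
    body <- cbind(gm$variants$chrom, gm$variants$pos, gm$variants$id,
                  gm$variants$ref, gm$variants$alt, ".", "PASS", ".", "GT",
                  gt)
    writeLines(apply(body, 1, paste, collapse = "\t"), con)
  }, path)
}

#' Read a VCF file into a genotype matrix
#'
#' Parses the GT field of a VCFv4.2 file (via \pkg{vcfR}) into alternate
#' allele dosages; `./.` and half-calls become missing. Multi-allelic
#' records are skipped with a warning. Donor order follows the header.
#'
#' @param path Path to a `.vcf` (optionally gzipped) file.
#' @return A [geno_matrix()].
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- tibble::as_tibble(as.data.frame(v@fix, stringsAsFactors = FALSE))
  multi <- grepl(",", fix$ALT %||% "")
  if (any(multi)) {
    warning(sum(multi), " multi-allelic record(s) skipped")
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[!multi, , drop = FALSE]
  fix <- fix[!multi, ]
  alleles <- gsub("\\|", "/", gt)
  dose <- matrix(NA_real_, nrow(alleles), ncol(alleles))
  dose[alleles == "0/0"] <- 0
  dose[alleles %in% c("0/1", "1/0")] <- 1
  dose[alleles == "1/1"] <- 2
  variants <- tibble::tibble(
    chrom = fix$CHROM, pos = as.integer(fix$POS),
    id = fix$ID, ref = fix$REF, alt = fix$ALT
  )
  geno_matrix(t(dose), variants, donors = colnames(gt))
}

#' Write an abundance table as a feature x sample TSV
#'
#' On disk the table is transposed to the profiler convention: rows are
#' features, columns are samples, and the first column (`feature`) holds
#' feature names. Missing values are written as `NA`.
#'
#' @param t An [abundance_table()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_abundance <- function(t, path) {
  stopifnot(inherits(t, "abundance_tbl"))
  m <- t(feature_matrix(t))
  out <- dplyr::bind_cols(tibble::tibble(feature = rownames(m)),
                          tibble::as_tibble(m))
  write_atomic(function(tmp) readr::write_tsv(out, tmp, na = "NA"), path)
}

#' Read a feature x sample TSV into an abundance table
#'
#' @param path Path to a TSV whose first column is the feature name and
#'   remaining columns are samples.
#' @param kind `"species"` or `"pathway"`.
#' @param metadata Optional sample metadata (see [read_metadata()]) used
#'   to attach donor and body-site labels; without it the donor id is the
#'   sample id with any `_r<k>` replicate suffix removed and the body
#'   site is `body_site`.
#' @param body_site Fallback body-site label.
#' @param transformed Are the stored values already log10 scale?
#' @return An [abundance_table()].
#' @export
read_abundance <- function(path, kind = c("species", "pathway"),
                           metadata = NULL, body_site = "stool",
                           transformed = FALSE) {
  kind <- match.arg(kind)
  raw <- readr::read_tsv(path, show_col_types = FALSE, na = "NA",
                         name_repair = "minimal")
  if (names(raw)[1] != "feature") {
    stop("first column must be named 'feature'")
  }
  sample_ids <- names(raw)[-1]
  if (anyDuplicated(sample_ids)) {
    stop("duplicated sample column(s): ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  m <- as.matrix(raw[-1])
  if (!is.numeric(m)) stop("non-numeric abundance cell(s) in ", path)
  vals <- t(m)
  colnames(vals) <- raw$feature
  if (!is.null(metadata)) {
    idx <- match(sample_ids, metadata$sample_id)
    if (anyNA(idx)) {
      stop("samples absent from metadata: ",
           paste(sample_ids[is.na(idx)], collapse = ", "))
    }
    samples <- tibble::tibble(sample_id = sample_ids,
                              donor = metadata$donor[idx],
                              body_site = metadata$body_site[idx])
  } else {
    samples <- tibble::tibble(sample_id = sample_ids,
                              donor = sub("_r\\d+$", "", sample_ids),
                              body_site = body_site)
  }
  abundance_table(dplyr::bind_cols(samples, tibble::as_tibble(vals)),
                  kind = kind, transformed = transformed)
}

#' Read sample-level metadata
#'
#' @param path TSV with columns `sample_id`, `donor`, `body_site`, `sex`,
#'   `ethnicity`, `collection_site`; an error names any missing column.
#' @return A tibble.
#' @export
read_metadata <- function(path) {
  md <- readr::read_tsv(path, show_col_types = FALSE)
  required <- c("sample_id", "donor", "body_site", "sex", "ethnicity",
                "collection_site")
  missing_cols <- setdiff(required, names(md))
  if (length(missing_cols) > 0) {
    stop("metadata lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  md
}

#' Read gene intervals from a BED file
#'
#' BED is 0-based half-open on disk; intervals are converted to 1-based
#' inclusive coordinates on read (`start + 1`, `end` unchanged).
#'
#' @param path Path to a BED file (columns chrom, start, end, name; no
#'   header).
#' @return A tibble `gene`, `chrom`, `start`, `end` (1-based inclusive).
#' @export
read_gene_bed <- function(path) {
  bed <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE)
  if (ncol(bed) < 4) stop("BED file needs at least 4 columns (incl. name)")
  tibble::tibble(
    gene = as.character(bed[[4]]),
    chrom = as.character(bed[[1]]),
    start = as.integer(bed[[2]]) + 1L,
    end = as.integer(bed[[3]])
  )
}

#' Read a pathway-to-superclass map
#'
#' @param path TSV with columns `feature` and `superclass`.
#' @return A tibble.
#' @export
read_class_map <- function(path) {
  cm <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("feature", "superclass") %in% names(cm))) {
    stop("class map needs columns feature, superclass")
  }
  cm
}

#' Write a synthetic cohort to disk
#'
#' Materializes a [sim_cohort()] result as the file set the pipeline
#' readers consume: `genotypes.vcf`, `species.tsv`, `pathways.tsv`,
#' `metadata.tsv` and `truth.json`.
#'
#' @param cohort A `synthetic_cohort`.
#' @param outdir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, outdir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_vcf(cohort$genotypes, file.path(outdir, "genotypes.vcf"))
  write_abundance(cohort$species, file.path(outdir, "species.tsv"))
  write_abundance(cohort$pathways, file.path(outdir, "pathways.tsv"))
  samples <- dplyr::bind_rows(
    cohort$species[abund_meta_cols],
    cohort$pathways[abund_meta_cols]) |>
    dplyr::distinct() |>
    dplyr::left_join(cohort$metadata, by = "donor")
  write_atomic(function(tmp) readr::write_tsv(samples, tmp),
               file.path(outdir, "metadata.tsv"))
  truth <- cohort$truth
  truth$config <- unclass(truth$config)
  write_atomic(function(tmp) {
    jsonlite::write_json(truth, tmp, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }, file.path(outdir, "truth.json"))
  invisible(outdir)
}
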