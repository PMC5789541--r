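#' Pipeline configuration with study-standard defaults
#'
#' Collects every fixed constant of the analysis in one place: the
#' common-variant filter for PCA and kinship (MAF > 0.05, call rate >
#' 95%), the scan filter (MAF > 0.1), the species and pathway prevalence
#' thresholds (at least 25% / more than 75% of samples), the log10
#' pseudocount (1e-5), the clumping gap (10 kb), the gene-annotation
#' window (50 kb), the permutation count (10000) and the family-wise
#' alpha (0.05). Values can be overridden by arguments or loaded from a
#' YAML file whose keys match the argument names (arguments win).
#'
#' @param path Optional YAML file of overrides.
#' @param ... Named overrides of individual thresholds.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(path = NULL, ...) {
  cfg <- list(
    maf_min_pca = 0.05, call_rate_min = 0.95, maf_min_gwas = 0.1,
    species_prevalence = 0.25, pathway_prevalence = 0.75,
    pseudocount = 1e-5, clump_gap = 10000, gene_window = 50000,
    B = 10000, alpha = 0.05, n_pcs = 5, seed = 1
  )
  if (!is.null(path)) {
    over <- yaml::read_yaml(path)
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown) > 0) {
      stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    }
    cfg[names(over)] <- over
  }
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(dots)] <- dots
  with(cfg, {
    stopifnot(maf_min_pca >= 0, maf_min_pca <= 0.5,
              call_rate_min >= 0, call_rate_min <= 1,
              maf_min_gwas >= 0, maf_min_gwas <= 0.5,
              species_prevalence >= 0, species_prevalence <= 1,
              pathway_prevalence >= 0, pathway_prevalence <= 1,
              pseudocount > 0, clump_gap > 0, gene_window >= 0,
              B >= 100, alpha > 0, alpha < 1, n_pcs >= 1)
  })
  structure(cfg, class = "pipeline_config")
}

#' Prepare a species or pathway table for association testing
#'
#' The standard preparation chain: replicate samples are averaged per
#' donor on the raw abundance scale, features are prevalence-filtered at
#' the donor level (species: at least `species_prevalence`; pathways:
#' more than `pathway_prevalence`), and values are log10-transformed
#' (species: with pseudocount; pathways: present values only, zeros
#' become missing).
#'
#' @param t An untransformed [abundance_table()].
#' @param config A [pipeline_config()].
#' @return A transformed, donor-level abundance table.
#' @export
prepare_features <- function(t, config = pipeline_config()) {
  kind <- abund_kind(t)
  t |>
    average_replicates() |>
    prevalence_filter(threshold = if (kind == "species") {
      config$species_prevalence
    } else {
      config$pathway_prevalence
    }) |>
    log_transform(pseudocount = config$pseudocount)
}

#' Run the full association pipeline on a cohort
#'
#' End-to-end orchestration over an in-memory cohort (typically from
#' [sim_cohort()], or assembled from [read_vcf()] / [read_abundance()] /
#' [read_metadata()] output): variant QC and PCA, all-pairs kinship,
#' feature preparation, the permutation variance-explained test for
#' species and pathways, optional pathway superclass enrichment,
#' relatives-vs-others similarity comparison, and (optionally) the
#' covariate-adjusted genome-wide scan on species.
#'
#' @param cohort A list with elements `genotypes` ([geno_matrix()]),
#'   `species`, `pathways` (untransformed [abundance_table()]s) and
#'   `metadata` (tibble with `donor`, `sex`, `ethnicity`,
#'   `collection_site`).
#' @param config A [pipeline_config()].
#' @param class_map Optional pathway superclass map (`feature`,
#'   `superclass`) for [rank_enrichment()].
#' @param genes Optional gene interval table for [annotate_genes()].
#' @param run_gwas Run the genome-wide scan? Default `TRUE`.
#' @return A list: `pca`, `kinship`, `species_prepared`,
#'   `pathways_prepared`, `species_assoc`, `pathway_assoc` (both
#'   `perm_assoc`), `enrichment` (or `NULL`), `pair_groups`,
#'   `relatedness`, `gwas` (records with `n_tests` attribute, or `NULL`),
#'   `bonferroni` (threshold, or `NULL`), `config`.
#' @export
run_pipeline <- function(cohort, config = pipeline_config(),
                         class_map = NULL, genes = NULL, run_gwas = TRUE) {
  gm_qc <- filter_variants(cohort$genotypes, config$maf_min_pca,
                           config$call_rate_min)
  pca <- genotype_pca(gm_qc, k = config$n_pcs)
  kin <- kinship_pairs(cohort$genotypes, config$maf_min_pca,
                       config$call_rate_min)
  sp <- prepare_features(cohort$species, config)
  pw <- prepare_features(cohort$pathways, config)
  sp_assoc <- permutation_test(sp, pca, B = config$B, seed = config$seed)
  pw_assoc <- permutation_test(pw, pca, B = config$B, seed = config$seed)
  enrichment <- if (!is.null(class_map)) {
    rank_enrichment(tidy(pw_assoc)$feature, class_map)
  }
  # whole-community similarity on raw, unfiltered relative abundances
  sim <- similarity_pairs(average_replicates(cohort$species))
  groups <- assign_pair_groups(sim, kin, cohort$metadata,
                               body_site = unique(cohort$species$body_site))
  relatedness <- compare_groups(groups)
  gwas <- NULL
  bonf <- NULL
  if (run_gwas) {
    covars <- cohort$metadata[match(sp$donor, cohort$metadata$donor),
                              c("sex", "ethnicity", "collection_site")]
    covars <- covars[vapply(covars, function(x) length(unique(x)) > 1,
                            logical(1))]
    if (ncol(covars) == 0) covars <- NULL
    gwas <- gwas_scan(cohort$genotypes, sp, covars = covars,
                      maf_min = config$maf_min_gwas)
    bonf <- bonferroni_threshold(attr(gwas, "n_tests"), config$alpha)
    if (!is.null(genes)) {
      hits <- gwas[!is.na(gwas$p) & gwas$p < bonf, ]
      gwas_genes <- annotate_genes(hits, genes,
                                   window = config$gene_window)
    }
  }
  out <- list(
    pca = pca, kinship = kin,
    species_prepared = sp, pathways_prepared = pw,
    species_assoc = sp_assoc, pathway_assoc = pw_assoc,
    enrichment = enrichment,
    pair_groups = groups, relatedness = relatedness,
    gwas = gwas, bonferroni = bonf,
    config = config
  )
  if (run_gwas && !is.null(genes)) out$gwas_genes <- gwas_genes
  out
}
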