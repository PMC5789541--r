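# Run code under a temporary RNG state so simulation calls do not disturb
# the caller's random stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# One global seed expands into per-stage child seeds by fixed offsets so
# each stage is independently reproducible. Kept below 2^31.
child_seed <- function(seed, stage) {
  offsets <- c(genotypes = 101L, pedigree = 211L, species = 307L,
               pathways = 401L, metadata = 503L)
  (as.integer(seed) %% 2000000000L) + offsets[[stage]]
}

#' Configuration for the synthetic cohort generator
#'
#' Collects every knob of the generator with defaults that emulate a
#' healthy human cohort profiled at one body site: a few hundred donors
#' drawn from several ancestral populations with continental-scale
#' divergence, a handful of cryptically related pairs, and zero-inflated
#' compositional species profiles plus reads-per-million pathway profiles.
#'
#' @param n_donors Number of donors (default 298).
#' @param n_variants Number of biallelic variants (default 5000).
#' @param n_populations Number of ancestral populations (default 4).
#' @param fst Divergence parameter of the Balding-Nichols model, in (0, 1)
#'   exclusive (default 0.1, continental-scale).
#' @param population_weights Population proportions summing to 1; default
#'   `c(0.73, 0.06, 0.09, 0.12)` (predominantly one ancestry plus three
#'   minorities). Names, if given, become ethnicity labels.
#' @param related_pairs Named integer vector of planted related pairs by
#'   degree, names among `twin`, `first`, `second`, `third`. Default
#'   `c(first = 11, third = 1)`.
#' @param n_species,n_pathways Number of species / pathway features
#'   (defaults 119 and 400).
#' @param prevalence_range Length-2 range in (0, 1]; each feature's
#'   presence probability is drawn uniformly from it (default
#'   `c(0.25, 0.95)`). Ignored when `zero_inflation` is given.
#' @param zero_inflation Optional scalar probability of zeroing any entry,
#'   overriding `prevalence_range` with a constant per-entry zero mask.
#' @param planted_pc_effects Data frame with columns `feature` (index),
#'   `pc` (index), `slope` (log10 abundance units per PC standard
#'   deviation), optional `table` ("species"/"pathway", default species).
#' @param planted_variant_effects Data frame with columns `variant`
#'   (index), `feature` (index), `model` ("additive"/"recessive"), `slope`
#'   (log10 units per encoded genotype unit), optional `table`.
#' @param replicates_per_donor Samples per donor at the body site
#'   (default 1).
#' @param sigma_rep Within-donor replicate standard deviation on the
#'   log10 scale (default 0.1; must be below `sigma_feature`).
#' @param sigma_feature Between-donor feature standard deviation on the
#'   log10 scale (default 1).
#' @param missing_rate Probability a dosage is missing (default 0).
#' @param body_site Body-site label for the abundance tables
#'   (default "stool").
#' @param seed Integer seed fixing the full cohort (default 1).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_donors = 298, n_variants = 5000,
                       n_populations = 4, fst = 0.1,
                       population_weights = NULL,
                       related_pairs = c(first = 11, third = 1),
                       n_species = 119, n_pathways = 400,
                       prevalence_range = c(0.25, 0.95),
                       zero_inflation = NULL,
                       planted_pc_effects = NULL,
                       planted_variant_effects = NULL,
                       replicates_per_donor = 1,
                       sigma_rep = 0.1, sigma_feature = 1,
                       missing_rate = 0, body_site = "stool",
                       seed = 1) {
  if (is.null(population_weights)) {
    population_weights <- if (n_populations == 4) {
      c(Caucasian = 0.73, African = 0.06, Asian = 0.09, Latino = 0.12)
    } else {
      stats::setNames(rep(1 / n_populations, n_populations),
                      paste0("pop", seq_len(n_populations)))
    }
  }
  counts <- c(n_donors = n_donors, n_variants = n_variants,
              n_populations = n_populations, n_species = n_species,
              n_pathways = n_pathways,
              replicates_per_donor = replicates_per_donor)
  if (any(counts <= 0)) {
    stop("counts must be positive: ",
         paste(names(counts)[counts <= 0], collapse = ", "))
  }
  if (fst <= 0 || fst >= 1) stop("fst must be in (0, 1) exclusive")
  if (length(population_weights) != n_populations) {
    stop("population_weights must have length n_populations")
  }
  if (abs(sum(population_weights) - 1) > 1e-9) {
    stop("population_weights must sum to 1")
  }
  if (is.null(names(population_weights))) {
    names(population_weights) <- paste0("pop", seq_len(n_populations))
  }
  if (length(related_pairs) > 0) {
    bad <- setdiff(names(related_pairs), c("twin", "first", "second", "third"))
    if (length(bad) > 0 || is.null(names(related_pairs))) {
      stop("related_pairs names must be among twin/first/second/third")
    }
  }
  if (!is.null(zero_inflation) &&
      (zero_inflation < 0 || zero_inflation >= 1)) {
    stop("zero_inflation must be a probability in [0, 1)")
  }
  if (length(prevalence_range) != 2 || any(prevalence_range <= 0) ||
      any(prevalence_range > 1) ||
      prevalence_range[1] > prevalence_range[2]) {
    stop("prevalence_range must be an increasing pair in (0, 1]")
  }
  if (sigma_rep >= sigma_feature) {
    stop("sigma_rep must be smaller than sigma_feature")
  }
  norm_effects <- function(x, cols) {
    if (is.null(x)) {
      return(tibble::tibble(!!!stats::setNames(rep(list(numeric(0)), length(cols)),
                                               cols),
                            table = character(0)))
    }
    x <- tibble::as_tibble(x)
    if (!all(cols %in% names(x))) {
      stop("planted effects need columns: ", paste(cols, collapse = ", "))
    }
    if (!"table" %in% names(x)) x$table <- "species"
    if (any(!is.finite(x$slope))) stop("planted slopes must be finite")
    x
  }
  cfg <- list(
    n_donors = as.integer(n_donors), n_variants = as.integer(n_variants),
    n_populations = as.integer(n_populations), fst = fst,
    population_weights = population_weights,
    related_pairs = related_pairs,
    n_species = as.integer(n_species), n_pathways = as.integer(n_pathways),
    prevalence_range = prevalence_range, zero_inflation = zero_inflation,
    planted_pc_effects = norm_effects(planted_pc_effects,
                                      c("feature", "pc", "slope")),
    planted_variant_effects = norm_effects(planted_variant_effects,
                                           c("variant", "feature", "model",
                                             "slope")),
    replicates_per_donor = as.integer(replicates_per_donor),
    sigma_rep = sigma_rep, sigma_feature = sigma_feature,
    missing_rate = missing_rate, body_site = body_site,
    seed = as.integer(seed)
  )
  pe <- cfg$planted_variant_effects
  if (nrow(pe) > 0 && !all(pe$model %in% c("additive", "recessive"))) {
    stop("planted variant models must be additive or recessive")
  }
  structure(cfg, class = "sim_config")
}

#' Simulate structured genotypes under the Balding-Nichols model
#'
#' Each variant draws an ancestral allele frequency `p0 ~ Uniform(0.05,
#' 0.95)`; each population perturbs it as `Beta(p0 (1 - F) / F,
#' (1 - p0) (1 - F) / F)` where `F` is the divergence (Fst) parameter; each
#' donor's dosage is `Binomial(2, p_pop)`. Donors are assigned to
#' populations in fixed proportion blocks. Planted related pairs replace
#' the genotypes of donors from the largest population with pedigree draws
#' from [sim_related_pair()]. Variant positions are placed uniformly
#' (without replacement) along one 50-Mb synthetic chromosome, which
#' exercises distance-based clumping and gene-window annotation.
#'
#' @param config A [sim_config()].
#' @return A [geno_matrix()] with extra elements: `populations` (donor
#'   population labels), `pop_freqs` (variant x population frequency
#'   matrix), and `related_pairs` (tibble of planted pairs with their true
#'   degree).
#' @export
sim_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(child_seed(config$seed, "genotypes"), {
    n <- config$n_donors
    m <- config$n_variants
    K <- config$n_populations
    F_div <- config$fst
    p0 <- stats::runif(m, 0.05, 0.95)
    # variants carrying planted effects emulate common candidate variants
    # (secretor-status-like frequencies), so they survive MAF filtering
    planted_v <- unique(config$planted_variant_effects$variant)
    if (length(planted_v) > 0) {
      p0[planted_v] <- stats::runif(length(planted_v), 0.3, 0.7)
    }
    pop_freqs <- vapply(seq_len(K), function(k) {
      stats::rbeta(m, p0 * (1 - F_div) / F_div, (1 - p0) * (1 - F_div) / F_div)
    }, numeric(m))
    # clamp away from fixation so every variant stays polymorphic in
    # expectation and pedigree founders have valid frequencies
    pop_freqs <- pmin(pmax(pop_freqs, 1e-4), 1 - 1e-4)
    colnames(pop_freqs) <- names(config$population_weights)
    pop_counts <- diff(round(c(0, cumsum(config$population_weights)) * n))
    pops <- rep(names(config$population_weights), times = pop_counts)
    D <- matrix(NA_real_, n, m)
    for (k in seq_len(K)) {
      rows <- which(pops == names(config$population_weights)[k])
      if (length(rows) > 0) {
        D[rows, ] <- matrix(
          stats::rbinom(length(rows) * m, 2, rep(pop_freqs[, k],
                                                 each = length(rows))),
          nrow = length(rows))
      }
    }
    # plant related pairs among donors of the largest population
    main_pop <- names(which.max(config$population_weights))
    pool <- which(pops == main_pop)
    degrees <- rep(names(config$related_pairs),
                   times = unlist(config$related_pairs))
    if (2 * length(degrees) > length(pool)) {
      stop("not enough donors in the largest population for the ",
           "requested related pairs")
    }
    pair_rows <- utils::tail(pool, 2 * length(degrees))
    truth_pairs <- tibble::tibble(donor_i = character(0),
                                  donor_j = character(0),
                                  degree = character(0))
    donors <- sprintf("D%04d", seq_len(n))
    for (d in seq_along(degrees)) {
      i <- pair_rows[2 * d - 1]
      j <- pair_rows[2 * d]
      pair <- sim_related_pair(pop_freqs[, main_pop], degrees[d])
      D[i, ] <- pair[[1]]
      D[j, ] <- pair[[2]]
      truth_pairs <- dplyr::bind_rows(
        truth_pairs,
        tibble::tibble(donor_i = donors[i], donor_j = donors[j],
                       degree = degrees[d]))
    }
    if (config$missing_rate > 0) {
      D[stats::runif(length(D)) < config$missing_rate] <- NA_real_
    }
    variants <- tibble::tibble(
      chrom = "chrS",
      pos = sort(sample.int(50000000L, m)),
      id = sprintf("v%06d", seq_len(m)),
      ref = "A", alt = "G"
    )
    gm <- geno_matrix(D, variants, donors = donors)
    gm$populations <- pops
    gm$pop_freqs <- pop_freqs
    gm$related_pairs <- truth_pairs
    gm
  })
}

#' Simulate one related donor pair by Mendelian transmission
#'
#' Given per-variant population allele frequencies, draws founder
#' genotypes under Hardy-Weinberg equilibrium and transmits alleles
#' through a minimal pedigree: twins are duplicated genotypes;
#' first-degree pairs are parent and offspring (the child inherits one
#' allele from the parent, one from the population); second-degree pairs
#' are half-siblings sharing one parent; third-degree pairs are first
#' cousins via a four-founder pedigree.
#'
#' @param freqs Numeric vector of allele frequencies, each in (0, 1).
#' @param degree One of `"twin"`, `"first"`, `"second"`, `"third"`.
#' @param seed Optional integer seed for reproducible pairs.
#' @return A list of two dosage vectors.
#' @examples
#' pair <- sim_related_pair(runif(100, 0.1, 0.9), "twin", seed = 1)
#' identical(pair[[1]], pair[[2]])
#' @export
sim_related_pair <- function(freqs, degree, seed = NULL) {
  if (any(freqs <= 0 | freqs >= 1)) stop("freqs must lie strictly in (0, 1)")
  degree <- as.character(degree)
  if (!degree %in% c("twin", "first", "second", "third")) {
    stop("unknown relatedness degree: ", degree)
  }
  run <- function() {
    m <- length(freqs)
    founder <- function() stats::rbinom(m, 2, freqs)
    transmit <- function(g) stats::rbinom(m, 1, g / 2)
    pop_allele <- function() stats::rbinom(m, 1, freqs)
    switch(degree,
      twin = {
        g <- founder()
        list(g, g)
      },
      first = {
        parent <- founder()
        child <- transmit(parent) + pop_allele()
        list(parent, child)
      },
      second = {
        mother <- founder()
        sib1 <- transmit(mother) + transmit(founder())
        sib2 <- transmit(mother) + transmit(founder())
        list(sib1, sib2)
      },
      third = {
        gp1 <- founder()
        gp2 <- founder()
        sib1 <- transmit(gp1) + transmit(gp2)
        sib2 <- transmit(gp1) + transmit(gp2)
        cousin1 <- transmit(sib1) + transmit(founder())
        cousin2 <- transmit(sib2) + transmit(founder())
        list(cousin1, cousin2)
      })
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Simulate zero-inflated microbiome abundance tables
#'
#' Generates species (relative abundance) and pathway (reads-per-million)
#' tables over the donors of a simulated genotype matrix. Each feature has
#' a latent log10 abundance per donor: a feature-specific baseline plus
#' Gaussian donor noise, plus any planted effects — genetic principal
#' component slopes (applied to standardized PC scores of the genotypes)
#' and single-variant slopes (applied to the encoded dosage). Replicate
#' samples add small within-donor noise. Entries are then zeroed
#' independently (per-feature presence probabilities drawn from
#' `prevalence_range`, or a constant `zero_inflation`), species rows are
#' renormalized to sum to 1, and pathway values are left on the
#' reads-per-million scale.
#'
#' @param gm A genotype matrix from [sim_genotypes()].
#' @param config The same [sim_config()].
#' @return A list with elements `species` and `pathways` (each an
#'   [abundance_table()]) and `truth` (planted effects, with a
#'   `silenced` flag for any planted feature that was zeroed everywhere).
#' @export
sim_microbiome <- function(gm, config) {
  stopifnot(inherits(gm, "geno_matrix"), inherits(config, "sim_config"))
  k_pcs <- min(5, config$n_donors - 1, config$n_variants)
  pca <- genotype_pca(gm, k = k_pcs)
  Z <- scale(pca$scores)
  check_bounds <- function(eff, n_feat, tab) {
    eff <- eff[eff$table == tab, , drop = FALSE]
    if (nrow(eff) > 0 && (any(eff$feature < 1) || any(eff$feature > n_feat))) {
      stop("planted feature index out of bounds for ", tab, " table")
    }
    eff
  }
  ve <- config$planted_variant_effects
  if (nrow(ve) > 0 &&
      (any(ve$variant < 1) || any(ve$variant > config$n_variants))) {
    stop("planted variant index out of bounds")
  }
  pe <- config$planted_pc_effects
  if (nrow(pe) > 0 && any(pe$pc > ncol(Z))) {
    stop("planted PC index exceeds the number of components")
  }
  build <- function(n_feat, mu_range, tab, stage) {
    pe_tab <- check_bounds(pe, n_feat, tab)
    ve_tab <- check_bounds(ve, n_feat, tab)
    with_seed(child_seed(config$seed, stage), {
      n <- config$n_donors
      mu <- stats::runif(n_feat, mu_range[1], mu_range[2])
      # features carrying planted effects start from a low baseline so a
      # log-scale effect stays approximately linear after compositional
      # closure (a minor community member, not a dominant one)
      planted_f <- unique(c(pe_tab$feature, ve_tab$feature))
      if (length(planted_f) > 0) mu[planted_f] <- mu_range[1]
      latent <- matrix(mu, n, n_feat, byrow = TRUE) +
        matrix(stats::rnorm(n * n_feat, 0, config$sigma_feature), n, n_feat)
      for (r in seq_len(nrow(pe_tab))) {
        e <- pe_tab[r, ]
        latent[, e$feature] <- latent[, e$feature] + e$slope * Z[, e$pc]
      }
      for (r in seq_len(nrow(ve_tab))) {
        e <- ve_tab[r, ]
        g <- encode_genotype(gm$dosages[, e$variant], model = e$model)
        g[is.na(g)] <- mean(g, na.rm = TRUE)
        latent[, e$feature] <- latent[, e$feature] + e$slope * g
      }
      reps <- config$replicates_per_donor
      rows <- rep(seq_len(n), each = reps)
      lat_rep <- latent[rows, , drop = FALSE] +
        matrix(stats::rnorm(length(rows) * n_feat, 0, config$sigma_rep),
               length(rows), n_feat)
      present_prob <- if (!is.null(config$zero_inflation)) {
        rep(1 - config$zero_inflation, n_feat)
      } else {
        stats::runif(n_feat, config$prevalence_range[1],
                     config$prevalence_range[2])
      }
      mask <- matrix(stats::runif(length(lat_rep)), nrow(lat_rep)) <=
        matrix(present_prob, nrow(lat_rep), n_feat, byrow = TRUE)
      vals <- 10^lat_rep * mask
      # keep every sample non-empty: retain its largest latent feature
      empty <- rowSums(vals) == 0
      if (any(empty)) {
        top <- max.col(lat_rep[empty, , drop = FALSE], ties.method = "first")
        vals[cbind(which(empty), top)] <-
          10^lat_rep[cbind(which(empty), top)]
      }
      if (tab == "species") vals <- vals / rowSums(vals)
      feat_names <- sprintf("%s%03d", if (tab == "species") "sp" else "pwy",
                            seq_len(n_feat))
      colnames(vals) <- feat_names
      samples <- tibble::tibble(
        sample_id = sprintf("%s_r%d", gm$donors[rows],
                            rep(seq_len(reps), times = n)),
        donor = gm$donors[rows],
        body_site = config$body_site
      )
      tbl <- abundance_table(dplyr::bind_cols(samples, tibble::as_tibble(vals)),
                             kind = if (tab == "species") "species" else "pathway")
      silenced <- feat_names[colSums(feature_matrix(tbl) > 0) == 0]
      planted <- unique(c(pe_tab$feature, ve_tab$feature))
      silenced_planted <- intersect(silenced, feat_names[planted])
      if (length(silenced_planted) > 0) {
        warning("planted feature(s) zeroed in all samples: ",
                paste(silenced_planted, collapse = ", "))
      }
      list(tbl = tbl, silenced = silenced_planted)
    })
  }
  sp <- build(config$n_species, c(-4, -1), "species", "species")
  pw <- build(config$n_pathways, c(1, 4), "pathway", "pathways")
  truth <- list(
    pc_effects = pe,
    variant_effects = ve,
    silenced = c(sp$silenced, pw$silenced)
  )
  list(species = sp$tbl, pathways = pw$tbl, truth = truth)
}

#' Simulate a complete synthetic cohort
#'
#' Runs [sim_genotypes()] and [sim_microbiome()] under one configuration
#' and attaches donor metadata (sex, ethnicity = population label,
#' collection site), giving every downstream stage of the pipeline a
#' self-contained, reproducible input.
#'
#' @param config A [sim_config()].
#' @return A list of class `synthetic_cohort` with elements `genotypes`,
#'   `species`, `pathways`, `metadata` (tibble: donor, sex, ethnicity,
#'   collection_site) and `truth` (planted PC/variant effects, the true
#'   related pairs, and the configuration).
#' @examples
#' cohort <- sim_cohort(sim_config(n_donors = 40, n_variants = 300,
#'                                 n_species = 20, n_pathways = 10,
#'                                 related_pairs = c(first = 1), seed = 7))
#' cohort$truth$related_pairs
#' @export
sim_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  gm <- sim_genotypes(config)
  mb <- sim_microbiome(gm, config)
  metadata <- with_seed(child_seed(config$seed, "metadata"), {
    tibble::tibble(
      donor = gm$donors,
      sex = sample(c("female", "male"), length(gm$donors), replace = TRUE),
      ethnicity = gm$populations,
      collection_site = sample(c("site1", "site2"), length(gm$donors),
                               replace = TRUE)
    )
  })
  structure(
    list(genotypes = gm, species = mb$species, pathways = mb$pathways,
         metadata = metadata,
         truth = list(related_pairs = gm$related_pairs,
                      pc_effects = mb$truth$pc_effects,
                      variant_effects = mb$truth$variant_effects,
                      silenced = mb$truth$silenced,
                      config = config)),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> ", length(x$genotypes$donors), " donors, ",
      nrow(x$genotypes$variants), " variants, ",
      length(feature_cols(x$species)), " species, ",
      length(feature_cols(x$pathways)), " pathways\n", sep = "")
  cat("  planted related pairs: ", nrow(x$truth$related_pairs),
      "; planted PC effects: ", nrow(x$truth$pc_effects),
      "; planted variant effects: ", nrow(x$truth$variant_effects),
      "\n", sep = "")
  invisible(x)
}
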