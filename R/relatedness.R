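pair_key <- function(i, j) paste(pmin(i, j), pmax(i, j), sep = "\r")

#' Assign donor pairs to relatedness / ethnicity groups
#'
#' Combines pairwise community similarity (1 - Bray-Curtis, from
#' [similarity_pairs()]), pairwise kinship (from [kinship_pairs()]) and
#' donor metadata into one record per unordered donor pair, labelled
#' `relatives` (kinship degree third or closer, i.e. phi >= 0.0442;
#' takes precedence), `same ethnicity`, or `different ethnicity`.
#' Pairs are matched between the inputs irrespective of donor order.
#'
#' @param similarity Tibble `donor_i`, `donor_j`, `similarity` for one
#'   body site (donors lacking a profile there are simply absent).
#' @param kinship Tibble from [kinship_pairs()] (`donor_i`, `donor_j`,
#'   `phi`, `degree`).
#' @param metadata Donor table with columns `donor` and `ethnicity`.
#' @param body_site Body-site label attached to the output.
#' @return A tibble: `donor_i`, `donor_j`, `body_site`, `group`,
#'   `similarity`, `phi`, `degree`. Pairs with a donor of unknown
#'   ethnicity are dropped with a warning.
#' @export
assign_pair_groups <- function(similarity, kinship, metadata,
                               body_site = "stool") {
  similarity <- tibble::as_tibble(similarity)
  kinship <- tibble::as_tibble(kinship)
  metadata <- tibble::as_tibble(metadata)
  stopifnot(all(c("donor_i", "donor_j", "similarity") %in% names(similarity)),
            all(c("donor_i", "donor_j", "phi", "degree") %in% names(kinship)),
            all(c("donor", "ethnicity") %in% names(metadata)))
  eth <- stats::setNames(metadata$ethnicity, metadata$donor)
  out <- similarity |>
    dplyr::mutate(key = pair_key(.data$donor_i, .data$donor_j)) |>
    dplyr::left_join(
      kinship |>
        dplyr::transmute(key = pair_key(.data$donor_i, .data$donor_j),
                         phi = .data$phi, degree = .data$degree),
      by = "key") |>
    dplyr::select(-"key")
  eth_i <- unname(eth[out$donor_i])
  eth_j <- unname(eth[out$donor_j])
  known <- !is.na(eth_i) & !is.na(eth_j)
  if (!all(known)) {
    warning(sum(!known), " pair(s) dropped: donor without ethnicity")
    out <- out[known, ]
    eth_i <- eth_i[known]
    eth_j <- eth_j[known]
  }
  related <- !is.na(out$phi) & out$phi >= 0.0442
  out$group <- dplyr::case_when(
    related ~ "relatives",
    eth_i == eth_j ~ "same ethnicity",
    TRUE ~ "different ethnicity"
  )
  out$body_site <- body_site
  dplyr::select(out, "donor_i", "donor_j", "body_site", "group",
                "similarity", "phi", "degree")
}

#' Compare community similarity between relatives and other pairs
#'
#' Per body site, tests whether related donor pairs have more similar
#' microbiomes than all other pairs pooled, by a two-sample t-test of the
#' similarity scores (relatives vs everyone else). The gap between
#' same-ethnicity and different-ethnicity mean similarity is reported as
#' a descriptive alongside. With fewer than two relative pairs the test
#' statistic is undefined and only group means are returned.
#'
#' @param assignments Output of [assign_pair_groups()] (one or more body
#'   sites row-bound together).
#' @param welch Use the Welch t-test? Default `FALSE` (pooled variance).
#' @return A tibble with one row per (body_site, group): `n_pairs`,
#'   `mean_similarity`, plus the site-level `t`, `p` (relatives vs all
#'   others, repeated on each row of the site) and `ethnicity_gap`
#'   (same minus different ethnicity mean similarity).
#' @export
compare_groups <- function(assignments, welch = FALSE) {
  assignments <- tibble::as_tibble(assignments)
  purrr::map_dfr(split(assignments, assignments$body_site), function(a) {
    rel <- a$similarity[a$group == "relatives"]
    oth <- a$similarity[a$group != "relatives"]
    if (length(rel) >= 2 && length(oth) >= 2) {
      tt <- stats::t.test(rel, oth, var.equal = !welch)
      t_stat <- unname(tt$statistic)
      p <- tt$p.value
    } else {
      t_stat <- NA_real_
      p <- NA_real_
    }
    gap <- mean(a$similarity[a$group == "same ethnicity"]) -
      mean(a$similarity[a$group == "different ethnicity"])
    a |>
      dplyr::group_by(.data$body_site, .data$group) |>
      dplyr::summarise(n_pairs = dplyr::n(),
                       mean_similarity = mean(.data$similarity),
                       .groups = "drop") |>
      dplyr::mutate(t = t_stat, p = p, ethnicity_gap = gap)
  })
}

#' Plot similarity distributions by pair group
#'
#' @param assignments Output of [assign_pair_groups()].
#' @return A ggplot of similarity by group, faceted by body site.
#' @export
plot_pair_similarity <- function(assignments) {
  ggplot2::ggplot(tibble::as_tibble(assignments),
                  ggplot2::aes(.data$group, .data$similarity)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::facet_wrap(~body_site) +
    ggplot2::labs(x = NULL, y = "Bray-Curtis similarity") +
    ggplot2::theme_minimal()
}
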