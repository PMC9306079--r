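#' Amino-acid and B-vitamin trophy profiles
#'
#' Calls every amino-acid and B-vitamin biosynthesis pathway per genome
#' (via [pathway_calls()], i.e. with the one-missing-step allowance) and
#' summarises each genome's prototrophy.
#'
#' @param community An `ng_community`.
#' @param defs Pathway definitions; only `amino_acid` and `b_vitamin`
#'   categories are used.
#' @param calls Optionally, precomputed [pathway_calls()] output for those
#'   definitions.
#' @return A tibble with one row per genome: `genome_id`, `aa_present`
#'   and `vit_present` (named-logical list-columns), `n_aa`, `n_vit`,
#'   `aa_fraction` (= mean of `aa_present`), `vit_fraction`.
#' @export
trophy_profiles <- function(community, defs = read_pathway_defs(),
                            calls = NULL) {
  defs <- dplyr::filter(defs,
                        .data$category %in% c("amino_acid", "b_vitamin"))
  stopifnot(nrow(defs) > 0)
  if (is.null(calls)) calls <- pathway_calls(community, defs)
  calls <- dplyr::semi_join(calls, defs, by = "pathway_id")
  calls |>
    dplyr::group_by(.data$genome_id) |>
    dplyr::summarise(
      aa_present = list(rlang::set_names(
        .data$present[.data$category == "amino_acid"],
        .data$pathway_id[.data$category == "amino_acid"])),
      vit_present = list(rlang::set_names(
        .data$present[.data$category == "b_vitamin"],
        .data$pathway_id[.data$category == "b_vitamin"])),
      .groups = "drop") |>
    dplyr::mutate(
      n_aa = purrr::map_int(.data$aa_present, ~ sum(.x)),
      n_vit = purrr::map_int(.data$vit_present, ~ sum(.x)),
      aa_fraction = purrr::map_dbl(.data$aa_present, mean),
      vit_fraction = purrr::map_dbl(.data$vit_present, mean)) |>
    dplyr::arrange(match(.data$genome_id, community$genomes$genome_id))
}

#' Genomes able to synthesise a compound
#'
#' @param profiles Trophy profiles from [trophy_profiles()].
#' @param compound An amino-acid or B-vitamin pathway id (e.g.
#'   `"methionine"`, `"B12"`).
#' @return Character vector of genome ids, in profile order.
#' @export
providers <- function(profiles, compound) {
  if (nrow(profiles) == 0) return(character())
  pool <- c(names(profiles$aa_present[[1]]), names(profiles$vit_present[[1]]))
  if (!compound %in% pool) {
    stop("unknown compound '", compound, "'; valid ids: ",
         paste(pool, collapse = ", "), call. = FALSE)
  }
  has <- purrr::map_lgl(seq_len(nrow(profiles)), function(i) {
    v <- c(profiles$aa_present[[i]], profiles$vit_present[[i]])
    isTRUE(v[[compound]])
  })
  profiles$genome_id[has]
}

#' Community complementarity report
#'
#' For every amino acid and B-vitamin, lists the provider genomes (pathway
#' present) and the dependent genomes (pathway absent); provider and
#' dependent sets partition the community. Compounds with no provider are
#' flagged as community-wide auxotrophies. Optionally reports the Pearson
#' correlation of per-genome amino-acid prototrophy fraction with
#' completeness and abundance (reported as-is; no thresholding).
#'
#' @param profiles Trophy profiles from [trophy_profiles()].
#' @param community Optional `ng_community`; when given, prototrophy vs
#'   completeness/abundance correlations are attached as attributes
#'   `cor_completeness` and `cor_abundance`.
#' @return A tibble: `compound`, `category`, `n_providers`,
#'   `n_dependents`, `providers` and `dependents` (list-columns),
#'   `community_wide_auxotrophy`.
#' @export
complementarity_report <- function(profiles, community = NULL) {
  compounds <- tibble::tibble(
    compound = c(names(profiles$aa_present[[1]]),
                 names(profiles$vit_present[[1]])),
    category = rep(c("amino_acid", "b_vitamin"),
                   c(length(profiles$aa_present[[1]]),
                     length(profiles$vit_present[[1]]))))
  out <- purrr::map_dfr(seq_len(nrow(compounds)), function(i) {
    prov <- providers(profiles, compounds$compound[i])
    dep <- setdiff(profiles$genome_id, prov)
    tibble::tibble(
      compound = compounds$compound[i], category = compounds$category[i],
      n_providers = length(prov), n_dependents = length(dep),
      providers = list(prov), dependents = list(dep),
      community_wide_auxotrophy = length(prov) == 0)
  })
  if (!is.null(community)) {
    g <- dplyr::left_join(profiles, community$genomes, by = "genome_id")
    attr(out, "cor_completeness") <-
      stats::cor(g$aa_fraction, g$completeness)
    attr(out, "cor_abundance") <-
      if (all(is.na(g$abundance))) NA_real_ else
        stats::cor(g$aa_fraction, g$abundance, use = "complete.obs")
  }
  out
}

#' Wide trophy matrices
#'
#' @param profiles Trophy profiles from [trophy_profiles()].
#' @param category `"amino_acid"` or `"b_vitamin"`.
#' @return A tibble, one row per genome, one 0/1 column per compound.
#' @export
trophy_matrix <- function(profiles, category = c("amino_acid",
                                                 "b_vitamin")) {
  category <- match.arg(category)
  col <- if (category == "amino_acid") "aa_present" else "vit_present"
  purrr::map_dfr(seq_len(nrow(profiles)), function(i) {
    v <- profiles[[col]][[i]]
    tibble::as_tibble(c(list(genome_id = profiles$genome_id[i]),
                        as.list(setNames(as.integer(v), names(v)))))
  })
}
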