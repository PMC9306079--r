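#' Read the nitrogen-cycle marker-gene map
#'
#' The marker map defines, for each census group (e.g. the respiratory
#' nitrate reductase operon), the subunit genes whose joint presence sets
#' the group flag, plus optional accessory subunits that are recorded but
#' not required, and an optional per-gene `label` requirement. Labels carry
#' information a gene symbol alone cannot (nosZ clade I vs II, the
#' phylogenetic class of an nxr/nar homolog); they are expected as a
#' `label` column in the annotation table, derived upstream.
#'
#' Defaults require the catalytic core only: `amoA+amoB+amoC` (amoDE
#' accessory), `narG+narH` (narIJ accessory), all three `hzsABC` subunits,
#' `norB+norC`, `nrfA+nrfH`, `nirB+nirD`.
#'
#' @param path YAML file; defaults to the shipped map.
#' @return A tibble with columns `group`, `required` (list), `accessory`
#'   (list), `label` (NA when unlabelled), `count_prefix` (NA except for
#'   homolog-counting pseudo-groups such as hao-like).
#' @export
read_marker_map <- function(path = ng_file("nitrogen_markers.yaml")) {
  raw <- yaml::read_yaml(path)
  purrr::imap_dfr(raw$groups, function(g, name) {
    tibble::tibble(
      group = name,
      required = list(normalize_gene(unlist(g$required %||% character()))),
      accessory = list(normalize_gene(unlist(g$accessory %||% character()))),
      label = g$label %||% NA_character_,
      count_prefix = g$count_prefix %||% NA_character_)
  })
}

#' Census nitrogen-cycle marker genes across a community
#'
#' For every genome, sets one logical flag per marker group: `TRUE` when
#' all required subunit genes are present (with the matching label, for
#' labelled groups such as `nosZ_cladeII`). Homolog-counting groups (hao
#' like genes) produce an integer `<group>_count` column instead.
#'
#' @param community An `ng_community`.
#' @param marker_map Marker map tibble ([read_marker_map()]).
#' @return A tibble, one row per genome, in community order: `genome_id`,
#'   one logical column per group, integer columns for count groups.
#' @export
census <- function(community, marker_map = read_marker_map()) {
  ann <- community$annotations
  ids <- community$genomes$genome_id
  flag_groups <- dplyr::filter(marker_map, is.na(.data$count_prefix))
  count_groups <- dplyr::filter(marker_map, !is.na(.data$count_prefix))

  per_genome <- function(g) {
    rows <- ann[ann$genome_id == g, , drop = FALSE]
    flags <- vapply(seq_len(nrow(flag_groups)), function(i) {
      req <- flag_groups$required[[i]]
      lab <- flag_groups$label[[i]]
      pool <- if (is.na(lab)) rows$gene else rows$gene[!is.na(rows$label) &
                                                         rows$label == lab]
      length(req) > 0 && all(req %in% pool)
    }, logical(1))
    counts <- vapply(count_groups$count_prefix, function(p) {
      length(unique(rows$gene[startsWith(rows$gene, p)]))
    }, integer(1))
    vals <- c(as.list(flags), as.list(counts))
    names(vals) <- c(flag_groups$group,
                     if (nrow(count_groups) > 0)
                       paste0(count_groups$group, "_count"))
    tibble::as_tibble(c(list(genome_id = g), vals))
  }
  if (length(ids) == 0) {
    cols <- c(list(genome_id = character()),
              rlang::set_names(rep(list(logical()), nrow(flag_groups)),
                               flag_groups$group),
              rlang::set_names(rep(list(integer()), nrow(count_groups)),
                               if (nrow(count_groups) > 0)
                                 paste0(count_groups$group, "_count")))
    return(tibble::as_tibble(cols))
  }
  purrr::map_dfr(ids, per_genome)
}

#' Assign nitrogen-cycle guilds from a marker census
#'
#' Guild rules:
#' * `aob` — aerobic ammonia oxidizer: amo operon and hao.
#' * `anaob` — anammox: hzsABC and hdh.
#' * `nob_canonical` — canonical nitrite oxidizer: a canonical-class nxr,
#'   autotrophy, and neither amo nor hzs.
#' * `comammox` — amo plus any nxr.
#' * `dnra_complete` — a nitrate reductase (nar or nap) plus nrfHA or
#'   nirBD.
#' * `denitrifier_complete` — nitrate reductase, nitrite reductase
#'   (nirS/nirK), NO reductase (norBC/norZ) and nosZ (either clade).
#'
#' The denitrification endpoint class (`denit_class`) is derived from the
#' genome's transformation edges via [predict_endpoints()].
#'
#' @param census_tbl Census tibble from [census()].
#' @param trophy Trophy tibble from [classify_trophy()], or `NULL` to treat
#'   all genomes as non-autotrophs (only `nob_canonical` depends on it).
#' @param rules Transformation rules for the endpoint labels
#'   ([read_ncycle_rules()]).
#' @return A tibble: `genome_id`, logical guild columns, `denit_class`,
#'   `trophy`.
#' @export
assign_guilds <- function(census_tbl, trophy = NULL,
                          rules = read_ncycle_rules()) {
  tro <- if (is.null(trophy)) {
    tibble::tibble(genome_id = census_tbl$genome_id,
                   trophy = "non_autotroph")
  } else {
    dplyr::select(trophy, "genome_id", "trophy")
  }
  any_nxr <- census_tbl$nxrAB_anammox | census_tbl$nxr_like_periplasmic |
    census_tbl$nxr_canonical
  nitrate_red <- census_tbl$narGHIJ | census_tbl$napAB
  out <- census_tbl |>
    dplyr::left_join(tro, by = "genome_id") |>
    dplyr::mutate(
      aob = .data$amoCABDE & .data$hao,
      anaob = .data$hzsABC & .data$hdh,
      nob_canonical = .data$nxr_canonical & .data$trophy == "autotroph" &
        !.data$amoCABDE & !.data$hzsABC,
      comammox = .data$amoCABDE & any_nxr,
      dnra_complete = nitrate_red & (.data$nrfHA | .data$nirBD),
      denitrifier_complete = nitrate_red &
        (.data$nirS | .data$nirK) &
        (.data$norBC | .data$norZ) &
        (.data$nosZ_cladeI | .data$nosZ_cladeII))
  ends <- predict_endpoints(derive_edges(census_tbl, rules))
  out |>
    dplyr::left_join(ends, by = "genome_id") |>
    dplyr::mutate(denit_class = dplyr::coalesce(.data$denit_class,
                                                "none")) |>
    dplyr::select("genome_id", "aob", "anaob", "nob_canonical", "comammox",
                  "dnra_complete", "denitrifier_complete", "denit_class",
                  "trophy")
}

#' Community-level marker and guild counts
#'
#' Counts genomes per marker group, per joint condition, and per derived
#' summary metric, mirroring a Results-style census. With
#' `nxr_as_nar = TRUE`, genomes whose only nitrate-reduction candidate is
#' a periplasmic nxr-like homolog are added to the nitrate-reducer count
#' (the homologs cannot be assigned a direction from sequence alone).
#'
#' @param census_tbl Census tibble from [census()].
#' @param nxr_as_nar Count periplasmic nxr-like carriers without nar/nap as
#'   nitrate reducers. Default `FALSE`.
#' @return A tibble `metric`, `count`, with one row per metric:
#'   the raw marker groups, `nitrate_reducers`, `nxr_nar_homolog_carriers`,
#'   `nitrite_reducers`, `nir_and_nar`, `no_reducers`, `nor_and_nir`,
#'   `nor_and_nir_and_nar`, `noszII_and_nir`, `noszII_and_nar`,
#'   `noszII_and_nor`, and `n_genomes`.
#' @export
community_counts <- function(census_tbl, nxr_as_nar = FALSE) {
  x <- census_tbl
  flag_cols <- names(x)[vapply(x, is.logical, logical(1))]
  marker_counts <- vapply(flag_cols, function(cl) sum(x[[cl]]), integer(1))
  nar <- x$narGHIJ | x$napAB
  nir <- x$nirS | x$nirK
  nor <- x$norBC | x$norZ
  nitrate <- if (nxr_as_nar) nar | x$nxr_like_periplasmic else nar
  derived <- c(
    n_genomes = nrow(x),
    nitrate_reducers = sum(nitrate),
    nxr_nar_homolog_carriers = sum(x$narGHIJ | x$nxrAB_anammox |
                                     x$nxr_like_periplasmic |
                                     x$nxr_canonical),
    nitrite_reducers = sum(nir),
    nir_and_nar = sum(nir & x$narGHIJ),
    no_reducers = sum(nor),
    nor_and_nir = sum(nor & nir),
    nor_and_nir_and_nar = sum(nor & nir & nar),
    noszII_and_nir = sum(x$nosZ_cladeII & nir),
    noszII_and_nar = sum(x$nosZ_cladeII & nar),
    noszII_and_nor = sum(x$nosZ_cladeII & nor))
  tibble::tibble(
    metric = c(names(derived), flag_cols),
    count = as.integer(c(derived, marker_counts)))
}
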