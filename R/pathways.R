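#' Read declarative pathway definitions
#'
#' Pathway definitions live in a YAML file with one entry per pathway:
#' ```yaml
#' - pathway_id: methionine
#'   category: amino_acid        # amino_acid | b_vitamin | carbon_fixation
#'   steps:
#'     - [metA]
#'     - [metB]
#'     - [metC]
#'     - [metE, metH]            # alternative enzymes for one step
#'   key_genes: []               # carbon-fixation screening only
#' ```
#' Each step lists the alternative enzymes that can catalyse it; the step
#' counts as present when any one of them is encoded. `key_genes` is used
#' only by [classify_trophy()].
#'
#' @param path YAML file path; defaults to the definitions shipped with the
#'   package (20 amino acids, 8 B-vitamins, 5 carbon-fixation pathways).
#' @return A tibble with columns `pathway_id`, `category`, `steps`
#'   (list-column of lists of character vectors) and `key_genes`
#'   (list-column of character vectors).
#' @export
read_pathway_defs <- function(path = ng_file("pathway_defs.yaml")) {
  raw <- yaml::read_yaml(path)
  defs <- purrr::map_dfr(raw, function(p) {
    stopifnot(length(p$steps) >= 1)
    steps <- purrr::map(p$steps, function(s) normalize_gene(unlist(s)))
    stopifnot(all(lengths(steps) >= 1))
    tibble::tibble(
      pathway_id = p$pathway_id,
      category = p$category,
      steps = list(steps),
      key_genes = list(normalize_gene(unlist(p$key_genes %||% character()))))
  })
  stopifnot(!anyDuplicated(defs$pathway_id))
  defs
}

#' Is a single reaction step encoded?
#'
#' A step is present when the genome encodes at least one of its
#' alternative enzymes.
#'
#' @param step Character vector of alternative gene symbols for the step.
#' @param genes Character vector, the genome's gene set.
#' @return Logical scalar.
#' @export
step_present <- function(step, genes) {
  length(intersect(step, genes)) > 0
}

#' Call the presence of a pathway in one genome
#'
#' Applies the completeness heuristic: pathways with more than two steps
#' tolerate one missing step; pathways with one or two steps require every
#' step. (The two-step case is not covered by the stated rule for "fewer
#' than two" and "more than two" steps; requiring both steps is the
#' conservative reading and can be relaxed via `allow_missing_2step`.)
#'
#' @param pathway One row of a definitions tibble (see
#'   [read_pathway_defs()]) or a list with `pathway_id` and `steps`.
#' @param genes Character vector, the genome's gene set.
#' @param allow_missing_2step If `TRUE`, two-step pathways also tolerate
#'   one missing step. Default `FALSE`.
#' @return A one-row tibble: `pathway_id`, `n_steps`, `n_present`,
#'   `present`.
#' @export
call_pathway <- function(pathway, genes, allow_missing_2step = FALSE) {
  steps <- pathway$steps
  if (is.data.frame(pathway)) steps <- steps[[1]]
  n_steps <- length(steps)
  n_present <- sum(vapply(steps, step_present, logical(1), genes = genes))
  present <- if (n_steps > 2 || (n_steps == 2 && allow_missing_2step)) {
    n_steps - n_present <= 1
  } else {
    n_present == n_steps
  }
  tibble::tibble(pathway_id = pathway$pathway_id[[1]], n_steps = n_steps,
                 n_present = n_present, present = present)
}

#' Pathway calls for every genome x pathway pair
#'
#' @param community An `ng_community`.
#' @param defs Pathway definitions tibble ([read_pathway_defs()]).
#' @param allow_missing_2step Passed to [call_pathway()].
#' @return A long tibble (`genome_id`, `pathway_id`, `category`, `n_steps`,
#'   `n_present`, `present`), genomes and pathways in input order.
#' @export
pathway_calls <- function(community, defs, allow_missing_2step = FALSE) {
  stopifnot(nrow(defs) > 0)
  sets <- gene_sets(community)
  if (length(sets) == 0) {
    return(tibble::tibble(genome_id = character(), category = character(),
                          pathway_id = character(), n_steps = integer(),
                          n_present = integer(), present = logical()))
  }
  known <- unique(unlist(purrr::map(defs$steps, unlist)))
  seen <- unique(community$annotations$gene)
  # annotation vocabularies routinely exceed the definitions; just note it
  n_unknown <- length(setdiff(seen, known))
  if (n_unknown > 0) {
    rlang::inform(paste0(n_unknown, " annotated gene symbol(s) not used by ",
                         "any pathway definition (ignored)"),
                  .frequency = "once", .frequency_id = "ng_unknown_genes")
  }
  purrr::map_dfr(names(sets), function(g) {
    purrr::map_dfr(seq_len(nrow(defs)), function(i) {
      call_pathway(defs[i, ], sets[[g]], allow_missing_2step)
    }) |>
      dplyr::mutate(genome_id = g, category = defs$category,
                    .before = "pathway_id")
  })
}

#' Wide genome x pathway presence matrix
#'
#' @inheritParams pathway_calls
#' @param calls Optionally, precomputed [pathway_calls()] output.
#' @return A tibble, one row per genome, one 0/1 column per pathway.
#' @export
pathway_matrix <- function(community, defs, calls = NULL,
                           allow_missing_2step = FALSE) {
  if (is.null(calls)) {
    calls <- pathway_calls(community, defs, allow_missing_2step)
  }
  if (nrow(calls) == 0) {
    return(tibble::tibble(genome_id = character()))
  }
  calls |>
    dplyr::mutate(pathway_id = factor(.data$pathway_id,
                                      levels = unique(.data$pathway_id)),
                  genome_id = factor(.data$genome_id,
                                     levels = unique(.data$genome_id))) |>
    dplyr::select("genome_id", "pathway_id", "present") |>
    dplyr::mutate(present = as.integer(.data$present)) |>
    tidyr::pivot_wider(names_from = "pathway_id", values_from = "present") |>
    dplyr::mutate(genome_id = as.character(.data$genome_id))
}

#' Classify genomes as autotrophs by carbon-fixation key genes
#'
#' A genome is an autotroph when, for at least one carbon-fixation pathway
#' (CBB, rTCA, Wood-Ljungdahl, 3-hydroxypropionate,
#' 3-hydroxypropionate/4-hydroxybutyrate), all of that pathway's key genes
#' are encoded. This is key-gene screening, deliberately stricter than the
#' one-missing-step rule used for biosynthetic pathways.
#'
#' @param community An `ng_community`.
#' @param defs Pathway definitions; only rows with
#'   `category == "carbon_fixation"` and non-empty `key_genes` are used.
#' @return A tibble `genome_id`, `trophy` (`"autotroph"` /
#'   `"non_autotroph"`), plus a `fixation_pathways` list-column naming the
#'   matching pathways.
#' @export
classify_trophy <- function(community, defs = read_pathway_defs()) {
  fix <- dplyr::filter(defs, .data$category == "carbon_fixation",
                       lengths(.data$key_genes) > 0)
  stopifnot(nrow(fix) > 0)
  sets <- gene_sets(community)
  if (length(sets) == 0) {
    return(tibble::tibble(genome_id = character(), trophy = character(),
                          fixation_pathways = list()))
  }
  purrr::map_dfr(names(sets), function(g) {
    hit <- fix$pathway_id[vapply(fix$key_genes, function(k) {
      all(k %in% sets[[g]])
    }, logical(1))]
    tibble::tibble(
      genome_id = g,
      trophy = if (length(hit) > 0) "autotroph" else "non_autotroph",
      fixation_pathways = list(hit))
  })
}

ng_file <- function(...) {
  path <- system.file("extdata", ..., package = "nitroguild",
                      mustWork = FALSE)
  if (!nzchar(path)) {
    stop("packaged file not found: ", file.path(...), call. = FALSE)
  }
  path
}
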