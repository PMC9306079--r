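#' Read the fixture constraint file
#'
#' @param path YAML constraint file; defaults to the shipped one.
#' @return A list of constraints (each a named list with at least `id` and
#'   `type`).
#' @export
read_fixture_constraints <- function(path = ng_file("pna55_constraints.yaml")) {
  yaml::read_yaml(path)$constraints
}

#' Build the packaged 55-MAG community fixture
#'
#' Assembles the community from the shipped tables: per-genome nitrogen
#' marker annotations (with clade/class labels), a genome x pathway
#' presence table (expanded to gene level through the pathway definitions:
#' a present pathway contributes the first alternative enzyme of each of
#' its steps plus any key genes; an absent pathway contributes nothing),
#' and a quality table. The assembled community is then checked against
#' every constraint with [validate_fixture()]; any failure aborts with the
#' failing constraint ids, so an edited (contradictory) constraint file is
#' detected rather than silently ignored.
#'
#' @param constraints Constraint list ([read_fixture_constraints()]) or a
#'   path to a constraint YAML.
#' @param defs Pathway definitions.
#' @param nitrogen_path,pathways_path,quality_path Paths to the three
#'   fixture tables (defaults: the shipped ones).
#' @param validate Check the constraints after assembly. Default `TRUE`.
#' @return An `ng_community` of 55 genomes, with the pathway presence
#'   table (including the `constrained` tags) attached as attribute
#'   `pathway_table`.
#' @export
build_fixture <- function(constraints = read_fixture_constraints(),
                          defs = read_pathway_defs(),
                          nitrogen_path = ng_file("pna55_nitrogen.tsv"),
                          pathways_path = ng_file("pna55_pathways.tsv"),
                          quality_path = ng_file("pna55_quality.tsv"),
                          validate = TRUE) {
  if (is.character(constraints)) {
    constraints <- yaml::read_yaml(constraints)$constraints
  }
  nitrogen <- readr::read_tsv(nitrogen_path, col_types = "ccc",
                              progress = FALSE)
  pw <- readr::read_tsv(pathways_path, col_types = "ccii", progress = FALSE)
  quality <- read_quality_table(quality_path)

  by_id <- rlang::set_names(seq_len(nrow(defs)), defs$pathway_id)
  pathway_genes <- function(pid) {
    i <- by_id[[pid]]
    unique(c(vapply(defs$steps[[i]], `[`, character(1), 1),
             defs$key_genes[[i]]))
  }
  present <- pw[pw$present == 1, ]
  expanded <- purrr::map_dfr(seq_len(nrow(present)), function(k) {
    tibble::tibble(genome_id = present$genome_id[k],
                   gene = pathway_genes(present$pathway_id[k]),
                   label = NA_character_)
  })
  hits <- dplyr::bind_rows(
    dplyr::mutate(nitrogen, gene = normalize_gene(.data$gene)),
    dplyr::mutate(expanded, gene = normalize_gene(.data$gene)))
  community <- as_community(
    dplyr::mutate(hits, evalue = 0, bitscore = Inf, identity = 100,
                  .after = "gene"),
    quality, provenance = "packaged 55-MAG PNA community fixture")
  attr(community, "pathway_table") <- pw
  if (validate) {
    report <- validate_fixture(community, constraints, defs = defs)
    if (!all(report$pass)) {
      stop("fixture violates constraint(s): ",
           paste(report$constraint_id[!report$pass], collapse = ", "),
           call. = FALSE)
    }
  }
  community
}

#' Re-evaluate every fixture constraint against a community
#'
#' An independent check of the assembled community: each constraint is
#' evaluated from the community's census, guild, trophy, pathway and
#' network results, not from the tables [build_fixture()] assembled.
#'
#' @param community An `ng_community`.
#' @param constraints Constraint list; see [read_fixture_constraints()].
#' @param defs Pathway definitions.
#' @param marker_map Marker map.
#' @param rules Transformation rules.
#' @return A tibble: `constraint_id`, `type`, `pass`, `detail` (observed
#'   value for failed constraints).
#' @export
validate_fixture <- function(community,
                             constraints = read_fixture_constraints(),
                             defs = read_pathway_defs(),
                             marker_map = read_marker_map(),
                             rules = read_ncycle_rules()) {
  cen <- census(community, marker_map)
  trophy <- classify_trophy(community, defs)
  guilds <- assign_guilds(cen, trophy, rules)
  calls <- pathway_calls(community, defs)
  profiles <- trophy_profiles(community, defs, calls = calls)
  edges <- derive_edges(cen, rules)
  net <- build_exchange_network(edges)
  counts <- list(`FALSE` = community_counts(cen, nxr_as_nar = FALSE),
                 `TRUE` = community_counts(cen, nxr_as_nar = TRUE))

  flag_of <- function(genome, group) {
    v <- cen[[group]][cen$genome_id == genome]
    length(v) == 1 && isTRUE(v)
  }
  category_ids <- function(cat) defs$pathway_id[defs$category == cat]
  present_set <- function(genome, cat) {
    ids <- category_ids(cat)
    sub <- calls[calls$genome_id == genome & calls$pathway_id %in% ids, ]
    sub$pathway_id[sub$present]
  }

  eval_one <- function(con) {
    obs <- NULL
    ok <- switch(
      con$type,
      census_count = {
        tab <- counts[[as.character(isTRUE(con$nxr_as_nar))]]
        obs <- tab$count[tab$metric == con$metric]
        length(obs) == 1 && obs == con$value
      },
      flag_all = {
        vals <- outer(unlist(con$genomes), unlist(con$groups),
                      Vectorize(flag_of))
        obs <- sum(vals != isTRUE(con$value))
        all(vals == isTRUE(con$value))
      },
      flag_any = {
        hit <- vapply(unlist(con$genomes), function(g) {
          any(vapply(unlist(con$groups), function(gr) flag_of(g, gr),
                     logical(1)))
        }, logical(1))
        obs <- sum(!hit)
        all(hit)
      },
      hao_like_count = {
        obs <- cen$hao_like_count[cen$genome_id == con$genome]
        length(obs) == 1 && obs == con$value
      },
      guild_set = {
        obs <- guilds$genome_id[guilds[[con$guild]]]
        setequal(obs, unlist(con$genomes) %||% character())
      },
      autotroph_set = {
        obs <- trophy$genome_id[trophy$trophy == "autotroph"]
        setequal(obs, unlist(con$genomes))
      },
      autotroph_nxr_overlap = {
        auto <- trophy$genome_id[trophy$trophy == "autotroph"]
        nxr <- cen$genome_id[cen$nxr_like_periplasmic]
        obs <- intersect(auto, nxr)
        setequal(obs, unlist(con$genomes))
      },
      full_prototrophs = {
        ids <- category_ids(con$category)
        full <- vapply(community$genomes$genome_id, function(g) {
          setequal(present_set(g, con$category), ids)
        }, logical(1))
        obs <- community$genomes$genome_id[full]
        setequal(obs, unlist(con$genomes) %||% character())
      },
      pathway_all = {
        ids <- category_ids(con$category)
        ok_each <- vapply(unlist(con$genomes), function(g) {
          got <- present_set(g, con$category)
          if (isTRUE(con$present)) setequal(got, ids) else length(got) == 0
        }, logical(1))
        obs <- sum(!ok_each)
        all(ok_each)
      },
      aa_missing_exactly = {
        ids <- category_ids("amino_acid")
        obs <- setdiff(ids, present_set(con$genome, "amino_acid"))
        setequal(obs, unlist(con$missing))
      },
      providers_eq = {
        obs <- providers(profiles, con$compound)
        setequal(obs, unlist(con$genomes))
      },
      exchange_candidate = {
        row <- net$intermediates[
          net$intermediates$intermediate == con$intermediate, ]
        obs <- if (nrow(row) == 1) row$acceptors[[1]] else character()
        nrow(row) == 1 && row$exchange_candidate &&
          all(unlist(con$acceptors_include) %in% obs)
      },
      endpoint = {
        ends <- predict_endpoints(edges)
        obs <- ends$denit_class[match(unlist(con$genomes), ends$genome_id)]
        all(!is.na(obs) & obs == con$denit_class)
      },
      stop("unknown constraint type: ", con$type, call. = FALSE))
    tibble::tibble(
      constraint_id = con$id, type = con$type, pass = isTRUE(ok),
      detail = if (isTRUE(ok)) NA_character_ else
        paste0("observed: ", paste(obs, collapse = ",")))
  }
  purrr::map_dfr(constraints, eval_one)
}
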