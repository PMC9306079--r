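#' Read nitrogen-transformation rules
#'
#' The rule table licenses, for each marker group, one transformation edge
#' over the nitrogen intermediates `NH3, NH2OH, NO2-, NO3-, NO, N2O, N2,
#' NH4+, N2H4`. Hydrazine synthase consumes two substrates (NO and NH4+)
#' and is encoded as two rules. The anammox nitrite oxidoreductase is
#' reversible: it emits both `NO2- -> NO3-` (tagged as the
#' anammox-attributed nitrate source) and the reverse edge. Rules for the
#' hypothesized activities of hao-like homologs ship disabled and are
#' switched on with `include_hypothetical = TRUE` in [derive_edges()].
#'
#' @param path YAML file; defaults to the shipped rules.
#' @return A tibble: `group`, `substrate`, `product`, `hypothetical`,
#'   `note`.
#' @export
read_ncycle_rules <- function(path = ng_file("ncycle_rules.yaml")) {
  raw <- yaml::read_yaml(path)
  purrr::map_dfr(raw$rules, function(r) {
    base <- tibble::tibble(
      group = r$group, substrate = r$from, product = r$to,
      hypothetical = isTRUE(r$hypothetical),
      note = r$note %||% NA_character_)
    if (isTRUE(r$reversible)) {
      base <- dplyr::bind_rows(
        base,
        dplyr::mutate(base, substrate = r$to, product = r$from,
                      note = NA_character_))
    }
    base
  })
}

#' Derive per-genome nitrogen-transformation edges
#'
#' A pure function of the marker census: each genome gets exactly the
#' edges licensed by its `TRUE` group flags (or positive homolog counts,
#' for count-based groups such as hao-like).
#'
#' @param census_tbl Census tibble from [census()].
#' @param rules Rule tibble from [read_ncycle_rules()].
#' @param include_hypothetical Also emit edges from rules marked
#'   hypothetical (hao-like homolog activities). Default `FALSE`.
#' @return A tibble: `genome_id`, `substrate`, `product`, `enzyme` (the
#'   marker group), `note`.
#' @export
derive_edges <- function(census_tbl, rules = read_ncycle_rules(),
                         include_hypothetical = FALSE) {
  if (!include_hypothetical) {
    rules <- dplyr::filter(rules, !.data$hypothetical)
  }
  licensed <- function(group) {
    if (group %in% names(census_tbl)) {
      return(census_tbl[[group]])
    }
    cnt <- paste0(group, "_count")
    if (cnt %in% names(census_tbl)) {
      return(census_tbl[[cnt]] > 0)
    }
    stop("rule references unknown enzyme group: ", group, call. = FALSE)
  }
  purrr::map_dfr(seq_len(nrow(rules)), function(i) {
    on <- licensed(rules$group[i])
    tibble::tibble(genome_id = census_tbl$genome_id[on],
                   substrate = rules$substrate[i],
                   product = rules$product[i],
                   enzyme = rules$group[i],
                   note = rules$note[i])
  }) |>
    dplyr::arrange(match(.data$genome_id, census_tbl$genome_id))
}

denit_chain <- c("NO3-", "NO2-", "NO", "N2O", "N2")

#' Predict denitrification endpoints per genome
#'
#' Follows the linear respiratory chain NO3- -> NO2- -> NO -> N2O -> N2
#' through each genome's edges and labels the maximal contiguous spans,
#' e.g. `"NO3->NO2"`, `"NO2->N2O"`, `"full"`, `"none"`; genomes with
#' disjoint spans get a composite label (spans joined with `+`). DNRA and
#' anammox edges are not part of the chain and do not affect the label.
#'
#' @param edges Edge tibble from [derive_edges()].
#' @return A tibble `genome_id`, `denit_class`, one row per genome that
#'   appears in `edges` (genomes with no edges at all are absent; join
#'   against the census and fill `"none"` if needed — [assign_guilds()]
#'   does this).
#' @export
predict_endpoints <- function(edges) {
  span_label <- function(i, j) {
    if (i == 1 && j == 4) return("full")
    paste0(sub("-$", "", denit_chain[i]), "->",
           sub("-$", "", denit_chain[j + 1]))
  }
  per_genome <- function(d) {
    links <- vapply(1:4, function(i) {
      any(d$substrate == denit_chain[i] & d$product == denit_chain[i + 1])
    }, logical(1))
    if (!any(links)) return("none")
    r <- rle(links)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    spans <- purrr::map2_chr(starts[r$values], ends[r$values], span_label)
    paste(spans, collapse = "+")
  }
  edges |>
    dplyr::group_by(.data$genome_id) |>
    dplyr::summarise(denit_class = per_genome(dplyr::pick(dplyr::everything())),
                     .groups = "drop")
}

#' Build the community NOx exchange network
#'
#' For every intermediate, partitions genomes into donors (produce but do
#' not consume it) and acceptors (consume but do not produce it). An
#' intermediate is an exchange candidate when both sets are non-empty:
#' its turnover then necessarily crosses cell boundaries if both ends are
#' realised.
#'
#' @param edges Community edge tibble from [derive_edges()].
#' @return An object of class `ng_exchange_network`: a list with `edges`
#'   (the input) and `intermediates`, a tibble with per-intermediate
#'   donor/acceptor lists and the `exchange_candidate` flag.
#' @export
build_exchange_network <- function(edges) {
  inter <- sort(unique(c(edges$substrate, edges$product)))
  tab <- purrr::map_dfr(inter, function(x) {
    producers <- unique(edges$genome_id[edges$product == x])
    consumers <- unique(edges$genome_id[edges$substrate == x])
    donors <- sort(setdiff(producers, consumers))
    acceptors <- sort(setdiff(consumers, producers))
    candidate <- length(donors) > 0 && length(acceptors) > 0
    tibble::tibble(
      intermediate = x,
      n_producers = length(producers),
      n_consumers = length(consumers),
      donors = list(donors),
      acceptors = list(acceptors),
      exchange_candidate = candidate)
  })
  structure(list(edges = tibble::as_tibble(edges), intermediates = tab),
            class = "ng_exchange_network")
}

#' @export
print.ng_exchange_network <- function(x, ...) {
  cand <- x$intermediates$intermediate[x$intermediates$exchange_candidate]
  cat("<ng_exchange_network> ", nrow(x$edges), " edges over ",
      nrow(x$intermediates), " intermediates\n", sep = "")
  cat("exchange candidates: ",
      if (length(cand)) paste(cand, collapse = ", ") else "(none)", "\n",
      sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an exchange network into a long produce/consume edge table
#'
#' @param x An `ng_exchange_network`.
#' @param ... Unused.
#' @return A tibble: `genome_id`, `intermediate`, `role`
#'   (`"produce"`/`"consume"`), `enzyme`.
#' @exportS3Method generics::tidy
tidy.ng_exchange_network <- function(x, ...) {
  dplyr::bind_rows(
    x$edges |>
      dplyr::transmute(genome_id = .data$genome_id,
                       intermediate = .data$product,
                       role = "produce", enzyme = .data$enzyme),
    x$edges |>
      dplyr::transmute(genome_id = .data$genome_id,
                       intermediate = .data$substrate,
                       role = "consume", enzyme = .data$enzyme)) |>
    dplyr::arrange(.data$intermediate, .data$role, .data$genome_id)
}

#' One-row network summary
#'
#' @param x An `ng_exchange_network`.
#' @param ... Unused.
#' @return A tibble with genome, edge, intermediate and exchange-candidate
#'   counts.
#' @exportS3Method generics::glance
glance.ng_exchange_network <- function(x, ...) {
  tibble::tibble(
    n_genomes = length(unique(x$edges$genome_id)),
    n_edges = nrow(x$edges),
    n_intermediates = nrow(x$intermediates),
    n_exchange_candidates = sum(x$intermediates$exchange_candidate))
}

#' Export an exchange network to an edge-list TSV and a DOT graph
#'
#' The TSV holds one row per transformation edge (deterministic order) and
#' round-trips through [read_network()]. The DOT file renders genomes as
#' boxes and intermediates as ellipses, exchange candidates highlighted.
#'
#' @param net An `ng_exchange_network`.
#' @param edges_path Output TSV path.
#' @param dot_path Optional output DOT path (skipped when `NULL`).
#' @return `net`, invisibly.
#' @export
export_network <- function(net, edges_path, dot_path = NULL) {
  edges <- dplyr::arrange(net$edges, .data$genome_id, .data$substrate,
                          .data$product, .data$enzyme)
  readr::write_tsv(edges, edges_path, progress = FALSE, na = "")
  if (!is.null(dot_path)) {
    cand <- net$intermediates$intermediate[net$intermediates$exchange_candidate]
    q <- function(x) paste0('"', x, '"')
    lines <- c(
      "digraph nox_exchange {",
      "  rankdir=LR;",
      paste0("  ", q(unique(edges$genome_id)), " [shape=box];"),
      paste0("  ", q(setdiff(net$intermediates$intermediate, cand)),
             " [shape=ellipse];"),
      if (length(cand) > 0)
        paste0("  ", q(cand),
               ' [shape=ellipse, style=filled, fillcolor="gold"];'),
      paste0("  ", q(edges$substrate), " -> ", q(edges$genome_id),
             " [style=dashed];"),
      paste0("  ", q(edges$genome_id), " -> ", q(edges$product), ";"),
      "}")
    writeLines(lines, dot_path)
  }
  invisible(net)
}

#' Read an exchange network back from an edge-list TSV
#'
#' @param edges_path TSV written by [export_network()].
#' @return An `ng_exchange_network`.
#' @export
read_network <- function(edges_path) {
  edges <- readr::read_tsv(edges_path, col_types = readr::cols(
    .default = "c"), progress = FALSE)
  if (!"note" %in% names(edges)) edges$note <- NA_character_
  edges$note[!is.na(edges$note) & edges$note == ""] <- NA_character_
  build_exchange_network(edges)
}
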