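#' Read a per-genome gene annotation table
#'
#' Reads a tab-separated annotation table with one row per gene hit. The
#' mandatory columns are `genome_id` and `gene`; the hit-statistic columns
#' `evalue`, `bitscore` and `identity` are optional, as is a free-text
#' `label` column carrying per-gene metadata (e.g. a nosZ clade or an nxr
#' phylogenetic class derived upstream). Presence-only tables (no
#' statistics) are accepted: missing statistics are filled with sentinel
#' values that pass [filter_hits()] unconditionally (`evalue = 0`,
#' `bitscore = Inf`, `identity = 100`).
#'
#' @param path Path to a TSV file with a header row.
#' @return A tibble with columns `genome_id`, `gene`, `evalue`, `bitscore`,
#'   `identity`, `label` (NA when absent in the file).
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("genome_id\tgene", "G1\tnarG", "G1\tnarH"), tf)
#' read_annotation_table(tf)
read_annotation_table <- function(path) {
  hits <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                          progress = FALSE)
  missing <- setdiff(c("genome_id", "gene"), names(hits))
  if (length(missing) > 0) {
    stop("annotation table ", path, " lacks mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(hits) == 0) {
    warning("annotation table ", path, " is empty", call. = FALSE)
  }
  # sentinel pass-by-default statistics for presence-only tables
  if (!"evalue" %in% names(hits)) hits$evalue <- "0"
  if (!"bitscore" %in% names(hits)) hits$bitscore <- "Inf"
  if (!"identity" %in% names(hits)) hits$identity <- "100"
  if (!"label" %in% names(hits)) hits$label <- NA_character_
  hits |>
    dplyr::mutate(
      evalue = as.numeric(.data$evalue),
      bitscore = as.numeric(.data$bitscore),
      identity = as.numeric(.data$identity),
      gene = normalize_gene(.data$gene)
    ) |>
    dplyr::select("genome_id", "gene", "evalue", "bitscore", "identity",
                  "label") |>
    tibble::as_tibble()
}

# lower-case gene symbols, upper-case K numbers; keeps copy suffixes intact
normalize_gene <- function(gene) {
  gene <- trimws(gene)
  ko <- grepl("^[Kk][0-9]{5}$", gene)
  out <- tolower(gene)
  out[ko] <- toupper(gene[ko])
  out
}

#' Filter annotation hits on the homology-search thresholds
#'
#' Retains hits with `evalue < 1e-5`, `bitscore > 60` and
#' `identity > 30` (percent). All three inequalities are strict; hits at
#' the boundary are dropped. Rows with sentinel statistics (from
#' presence-only tables) always pass.
#'
#' @param hits A data frame of gene hits as returned by
#'   [read_annotation_table()].
#' @param max_evalue,min_bitscore,min_identity Threshold overrides.
#' @return The retained rows, in input order, as a tibble.
#' @export
filter_hits <- function(hits, max_evalue = 1e-5, min_bitscore = 60,
                        min_identity = 30) {
  hits |>
    dplyr::filter(.data$evalue < max_evalue,
                  .data$bitscore > min_bitscore,
                  .data$identity > min_identity) |>
    tibble::as_tibble()
}

#' Read a MAG quality table
#'
#' Tab-separated, one row per genome, with columns `genome_id`,
#' `completeness`, `contamination` and optionally `abundance` (relative
#' metagenome fraction, percent) and `assembly_size` (bp, used by
#' [dereplicate()]).
#'
#' @param path Path to the TSV file.
#' @return A tibble.
#' @export
read_quality_table <- function(path) {
  q <- readr::read_tsv(path, col_types = readr::cols(
    genome_id = "c", .default = "d"), progress = FALSE)
  missing <- setdiff(c("genome_id", "completeness", "contamination"),
                     names(q))
  if (length(missing) > 0) {
    stop("quality table ", path, " lacks mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!"abundance" %in% names(q)) q$abundance <- NA_real_
  tibble::as_tibble(q)
}

#' Quality-control filter for MAGs
#'
#' A genome is retained if its completeness is at least 70 percent, or if
#' it is less complete but has zero contamination.
#'
#' @param genomes A data frame with `completeness` and `contamination`
#'   columns (a quality table or the `genomes` table of a community), or a
#'   community object from [as_community()].
#' @param min_completeness Completeness floor in percent (default 70).
#' @return The retained rows (or the filtered community), input order
#'   preserved.
#' @export
qc_filter <- function(genomes, min_completeness = 70) {
  if (inherits(genomes, "ng_community")) {
    kept <- qc_filter(genomes$genomes, min_completeness)
    return(community_subset(genomes, kept$genome_id))
  }
  genomes |>
    dplyr::filter(.data$completeness >= min_completeness |
                    .data$contamination == 0) |>
    tibble::as_tibble()
}

#' Dereplicate redundant assemblies of one MAG
#'
#' When the same draft genome is recovered from several samples, keeps the
#' best version: ranked by higher completeness, then lower contamination,
#' then larger assembly size (when an `assembly_size` column is present).
#' Ties are broken deterministically by input order.
#'
#' @param candidates A data frame of candidate versions (same `genome_id`),
#'   with `completeness` and `contamination` columns.
#' @return A one-row tibble, the selected candidate.
#' @export
dereplicate <- function(candidates) {
  if (nrow(candidates) == 0) {
    stop("dereplicate() needs at least one candidate", call. = FALSE)
  }
  size <- if ("assembly_size" %in% names(candidates)) {
    candidates$assembly_size
  } else {
    rep(0, nrow(candidates))
  }
  ord <- order(-candidates$completeness, candidates$contamination, -size,
               seq_len(nrow(candidates)))
  tibble::as_tibble(candidates[ord[1], , drop = FALSE])
}

#' Assemble a community object from hits and quality tables
#'
#' Bundles a filtered annotation table and a genome quality table into a
#' community: a list with a `genomes` tibble (one row per genome; quality,
#' abundance) and an `annotations` tibble (one row per retained gene, with
#' optional per-gene `label` metadata). Gene sets are deduplicated per
#' genome (keeping the first occurrence of each gene/label pair).
#'
#' @param hits A (filtered) annotation table; see [filter_hits()].
#' @param quality A quality table; see [read_quality_table()].
#' @param provenance Free-text provenance note stored on the object.
#' @return An object of class `ng_community`.
#' @export
as_community <- function(hits, quality, provenance = "") {
  stopifnot(!anyDuplicated(quality$genome_id))
  if (!"label" %in% names(hits)) hits$label <- NA_character_
  ann <- hits |>
    dplyr::mutate(gene = normalize_gene(.data$gene)) |>
    dplyr::distinct(.data$genome_id, .data$gene, .keep_all = TRUE) |>
    dplyr::select("genome_id", "gene", "label")
  orphan <- setdiff(ann$genome_id, quality$genome_id)
  if (length(orphan) > 0) {
    warning("annotations for genome(s) absent from the quality table ",
            "are dropped: ", paste(orphan, collapse = ", "), call. = FALSE)
    ann <- dplyr::filter(ann, .data$genome_id %in% quality$genome_id)
  }
  structure(
    list(genomes = tibble::as_tibble(quality),
         annotations = tibble::as_tibble(ann),
         provenance = provenance),
    class = "ng_community")
}

community_subset <- function(community, genome_ids) {
  community$genomes <- dplyr::filter(
    community$genomes, .data$genome_id %in% genome_ids)
  community$annotations <- dplyr::filter(
    community$annotations, .data$genome_id %in% genome_ids)
  community
}

#' Per-genome gene sets of a community
#'
#' @param community An `ng_community`.
#' @return A named list of character vectors (deduplicated gene symbols),
#'   one element per genome, in `genomes` table order; genomes without any
#'   annotation get an empty vector.
#' @export
gene_sets <- function(community) {
  sets <- split(community$annotations$gene, community$annotations$genome_id)
  ids <- community$genomes$genome_id
  out <- lapply(ids, function(g) unique(sets[[g]] %||% character()))
  names(out) <- ids
  out
}

#' @export
print.ng_community <- function(x, ...) {
  cat("<ng_community> ", nrow(x$genomes), " genomes, ",
      nrow(x$annotations), " gene annotations\n", sep = "")
  if (nzchar(x$provenance)) cat("provenance: ", x$provenance, "\n", sep = "")
  invisible(x)
}

#' Write a community back to annotation + quality TSV files
#'
#' @param community An `ng_community`.
#' @param annotations_path,quality_path Output file paths.
#' @return The community, invisibly.
#' @export
write_community <- function(community, annotations_path, quality_path) {
  readr::write_tsv(community$annotations, annotations_path, progress = FALSE)
  readr::write_tsv(community$genomes, quality_path, progress = FALSE)
  invisible(community)
}

#' Read a community from annotation + quality TSV files
#'
#' Convenience inverse of [write_community()]; applies [filter_hits()] with
#' default thresholds (a no-op for presence-only tables).
#'
#' @param annotations_path,quality_path Input file paths.
#' @param provenance Provenance note.
#' @return An `ng_community`.
#' @export
read_community <- function(annotations_path, quality_path,
                           provenance = annotations_path) {
  hits <- filter_hits(read_annotation_table(annotations_path))
  as_community(hits, read_quality_table(quality_path), provenance)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
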