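#' Recruit reads to marker-gene references
#'
#' Aligns each read semi-globally (read end-to-end, reference locally,
#' i.e. usearch_global semantics) against every reference, on both strands
#' by default, and keeps the best reference by identity. Identity is
#' matches over alignment columns (internal gaps counted); a read is
#' recruited when identity and query coverage meet the thresholds, both
#' inclusive (default 0.85 identity, 0.90 coverage). Reads shorter than
#' `min_length` (default 45 nt, the usual trimming floor) are not aligned.
#'
#' @param reads A `Biostrings::DNAStringSet`, a named character vector, or
#'   a path to a FASTA/FASTQ file.
#' @param refs Reference sequences, same accepted forms; must be
#'   non-empty.
#' @param min_identity,min_coverage Recruitment thresholds (fractions,
#'   inclusive).
#' @param min_length Minimum read length in nt.
#' @param both_strands Also align the reverse complement and keep the
#'   better strand. Default `TRUE`.
#' @return A tibble with one row per read of sufficient length:
#'   `read_id`, `ref_id` (best reference), `strand` (`"+"`/`"-"`),
#'   `identity`, `query_coverage`, `aligned` (passed both thresholds).
#' @export
align_reads <- function(reads, refs, min_identity = 0.85,
                        min_coverage = 0.90, min_length = 45,
                        both_strands = TRUE) {
  reads <- as_dna(reads)
  refs <- as_dna(refs)
  if (length(refs) == 0) {
    stop("reference set is empty", call. = FALSE)
  }
  keep <- Biostrings::width(reads) >= min_length
  reads <- reads[keep]
  if (length(reads) == 0) {
    return(tibble::tibble(read_id = character(), ref_id = character(),
                          strand = character(), identity = double(),
                          query_coverage = double(), aligned = logical()))
  }
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                  baseOnly = FALSE)
  strands <- list(`+` = reads,
                  `-` = if (both_strands)
                    Biostrings::reverseComplement(reads))
  strands <- strands[!vapply(strands, is.null, logical(1))]
  best_id <- rep(-1, length(reads))
  best_ref <- rep(NA_character_, length(reads))
  best_strand <- rep(NA_character_, length(reads))
  for (s in names(strands)) {
    for (j in seq_along(refs)) {
      aln <- Biostrings::pairwiseAlignment(
        strands[[s]], refs[[j]], type = "global-local",
        substitutionMatrix = mat, gapOpening = 5, gapExtension = 2)
      idn <- Biostrings::pid(aln, type = "PID1") / 100
      gain <- idn > best_id
      best_id[gain] <- idn[gain]
      best_ref[gain] <- names(refs)[j]
      best_strand[gain] <- s
    }
  }
  # the read aligns end-to-end in a query-global alignment
  coverage <- rep(1, length(reads))
  tibble::tibble(
    read_id = names(reads),
    ref_id = best_ref,
    strand = best_strand,
    identity = best_id,
    query_coverage = coverage,
    aligned = best_id >= min_identity & coverage >= min_coverage)
}

as_dna <- function(x) {
  if (inherits(x, "DNAStringSet")) return(x)
  if (is.character(x) && length(x) == 1 && file.exists(x)) {
    fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", x, ignore.case = TRUE))
      "fastq" else "fasta"
    return(Biostrings::readDNAStringSet(x, format = fmt))
  }
  out <- Biostrings::DNAStringSet(x)
  if (is.null(names(out))) names(out) <- paste0("seq", seq_along(out))
  out
}

#' Summarise recruited reads per reference group as reads per million
#'
#' @param hits Hit tibble from [align_reads()].
#' @param groups A data frame mapping `ref_id` to `group_id` (a reference
#'   taxon or gene group); every group in this map is reported, including
#'   groups with zero recruited reads (0 RPM).
#' @param total_reads Total number of screened reads (> 0); the RPM
#'   denominator.
#' @return A tibble: `group_id`, `hit_count`, `total_reads`, `rpm`
#'   (`hit_count / total_reads * 1e6`).
#' @export
rpm_summary <- function(hits, groups, total_reads) {
  if (!is.numeric(total_reads) || total_reads <= 0) {
    stop("total_reads must be a positive count", call. = FALSE)
  }
  counted <- hits |>
    dplyr::filter(.data$aligned) |>
    dplyr::inner_join(groups, by = "ref_id") |>
    dplyr::count(.data$group_id, name = "hit_count")
  groups |>
    dplyr::distinct(.data$group_id) |>
    dplyr::left_join(counted, by = "group_id") |>
    dplyr::mutate(
      hit_count = dplyr::coalesce(.data$hit_count, 0L),
      total_reads = as.integer(total_reads),
      rpm = .data$hit_count / total_reads * 1e6)
}
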