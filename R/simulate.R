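#' Guild templates used by the community simulator
#'
#' Each template defines the marker genes (with labels where relevant)
#' that make a genome a member of one functional type, and the guild flags
#' a perfect census should recover for it.
#'
#' @return A named list of templates; each has `genes` (tibble `gene`,
#'   `label`) and `guilds` (character vector of expected guild flags).
#' @export
guild_templates <- function() {
  tb <- function(gene, label = NA_character_) {
    tibble::tibble(gene = gene, label = rep_len(label, length(gene)))
  }
  list(
    aob = list(
      genes = dplyr::bind_rows(
        tb(c("amoA", "amoB", "amoC", "amoD", "amoE", "hao", "nirK",
             "norB", "norC"))),
      guilds = "aob"),
    anaob = list(
      genes = dplyr::bind_rows(
        tb(c("hzsA", "hzsB", "hzsC", "hdh")),
        tb(c("nxrA", "nxrB"), "anammox")),
      guilds = "anaob"),
    denitrifier = list(
      genes = dplyr::bind_rows(
        tb(c("narG", "narH", "narI", "nirS", "norB", "norC")),
        tb("nosZ", "cladeI")),
      guilds = "denitrifier_complete"),
    dnra = list(
      genes = tb(c("narG", "narH", "nrfA", "nrfH")),
      guilds = "dnra_complete"),
    partial = list(
      genes = dplyr::bind_rows(tb("nirS"), tb("nosZ", "cladeII")),
      guilds = character()))
}

#' Simulate a community with known guild structure
#'
#' Draws genomes from the guild templates, adds random accessory genes,
#' and thins each genome's true gene set with a uniform per-gene dropout
#' model: a gene is retained with probability completeness/100, emulating
#' how genome incompleteness hides real gene content. Same seed, same
#' output.
#'
#' @param n_genomes Number of genomes.
#' @param guild_mix Named numeric vector of template proportions (names
#'   from [guild_templates()]); must sum to 1.
#' @param completeness_range Length-2 percent interval from which each
#'   genome's completeness is drawn uniformly; `c(100, 100)` disables
#'   dropout.
#' @param n_accessory Accessory genes per genome (drawn from a neutral
#'   pool).
#' @param seed Integer seed (mandatory; reproducibility).
#' @return A list: `community` (an `ng_community`) and `truth` (tibble
#'   `genome_id`, `template`, `guilds` list-column, `completeness`).
#' @export
simulate_community <- function(n_genomes = 100,
                               guild_mix = c(aob = 0.15, anaob = 0.15,
                                             denitrifier = 0.2, dnra = 0.2,
                                             partial = 0.3),
                               completeness_range = c(100, 100),
                               n_accessory = 20, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  if (abs(sum(guild_mix) - 1) > 1e-8 || any(guild_mix < 0)) {
    stop("guild_mix proportions must be non-negative and sum to 1",
         call. = FALSE)
  }
  templates <- guild_templates()
  if (!all(names(guild_mix) %in% names(templates))) {
    stop("unknown template in guild_mix: ",
         paste(setdiff(names(guild_mix), names(templates)), collapse = ", "),
         call. = FALSE)
  }
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  pool <- sprintf("acc%04d", 1:500)
  picks <- sample(names(guild_mix), n_genomes, replace = TRUE,
                  prob = guild_mix)
  comp <- stats::runif(n_genomes, completeness_range[1],
                       completeness_range[2])
  rows <- purrr::map_dfr(seq_len(n_genomes), function(i) {
    gid <- sprintf("SIM%04d", i)
    genes <- dplyr::bind_rows(
      templates[[picks[i]]]$genes,
      tibble::tibble(gene = sample(pool, n_accessory),
                     label = NA_character_))
    keep <- stats::runif(nrow(genes)) <= comp[i] / 100
    dplyr::mutate(genes[keep, ], genome_id = gid, .before = 1)
  })
  quality <- tibble::tibble(
    genome_id = sprintf("SIM%04d", seq_len(n_genomes)),
    completeness = comp, contamination = 0, abundance = NA_real_)
  hits <- dplyr::mutate(rows, evalue = 0, bitscore = Inf, identity = 100,
                        .after = "gene")
  list(
    community = as_community(hits, quality,
                             provenance = paste0("simulated, seed ", seed)),
    truth = tibble::tibble(
      genome_id = quality$genome_id, template = picks,
      guilds = purrr::map(picks, ~ templates[[.x]]$guilds),
      completeness = comp))
}

#' Fraction of simulated genomes whose guild set is recovered exactly
#'
#' Runs the census and guild assignment on a simulated community and
#' compares each genome's recovered guild-flag set against the template's
#' expected set. Dropout can only remove genes, so recovery is monotone in
#' completeness.
#'
#' @param sim Output of [simulate_community()].
#' @param marker_map,rules Census configuration.
#' @return A single number in \[0, 1\].
#' @export
guild_recovery <- function(sim, marker_map = read_marker_map(),
                           rules = read_ncycle_rules()) {
  cen <- census(sim$community, marker_map)
  guilds <- assign_guilds(cen, trophy = NULL, rules = rules)
  guild_cols <- c("aob", "anaob", "nob_canonical", "comammox",
                  "dnra_complete", "denitrifier_complete")
  got <- purrr::map(seq_len(nrow(guilds)), function(i) {
    guild_cols[vapply(guild_cols, function(cl) guilds[[cl]][i], logical(1))]
  })
  want <- sim$truth$guilds[match(guilds$genome_id, sim$truth$genome_id)]
  mean(purrr::map2_lgl(got, want, setequal))
}

#' Simulate shotgun reads from reference sequences
#'
#' Draws fixed-length substrings from the references (both strands),
#' applies substitutions at the given per-base rate, and records the
#' planted provenance so recruitment recall can be computed. Optionally
#' writes a FASTQ file (constant quality).
#'
#' @param refs Reference sequences (`DNAStringSet`, named character, or
#'   FASTA path).
#' @param n_reads Number of reads.
#' @param read_length Read length in nt; must not exceed the shortest
#'   reference.
#' @param divergence Per-base substitution probability in \[0, 0.5\].
#' @param seed Integer seed (mandatory).
#' @param out_fastq Optional path; when given, reads are written as FASTQ.
#' @return A list: `reads` (`DNAStringSet`), `truth` (tibble `read_id`,
#'   `ref_id`, `start`, `strand`, `n_subs`), and `fastq` (path or `NULL`).
#' @export
simulate_reads <- function(refs, n_reads = 1000, read_length = 100,
                           divergence = 0, seed, out_fastq = NULL) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(divergence >= 0, divergence <= 0.5)
  refs <- as_dna(refs)
  if (read_length > min(Biostrings::width(refs))) {
    stop("read_length exceeds the shortest reference (",
         min(Biostrings::width(refs)), " nt)", call. = FALSE)
  }
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  bases <- c("A", "C", "G", "T")
  ref_idx <- sample(length(refs), n_reads, replace = TRUE)
  strand <- sample(c("+", "-"), n_reads, replace = TRUE)
  seqs <- character(n_reads)
  start <- integer(n_reads)
  n_subs <- integer(n_reads)
  for (i in seq_len(n_reads)) {
    w <- Biostrings::width(refs)[ref_idx[i]]
    start[i] <- sample(w - read_length + 1, 1)
    frag <- Biostrings::subseq(refs[[ref_idx[i]]], start[i],
                               start[i] + read_length - 1)
    if (strand[i] == "-") frag <- Biostrings::reverseComplement(frag)
    s <- strsplit(as.character(frag), "")[[1]]
    hit <- which(stats::runif(read_length) < divergence)
    for (j in hit) s[j] <- sample(setdiff(bases, s[j]), 1)
    n_subs[i] <- length(hit)
    seqs[i] <- paste(s, collapse = "")
  }
  ids <- sprintf("read%05d", seq_len(n_reads))
  reads <- Biostrings::DNAStringSet(rlang::set_names(seqs, ids))
  if (!is.null(out_fastq)) {
    qual <- strrep("I", read_length)
    writeLines(paste0("@", ids, "\n", seqs, "\n+\n", qual), out_fastq)
  }
  list(reads = reads,
       truth = tibble::tibble(read_id = ids,
                              ref_id = names(refs)[ref_idx],
                              start = start, strand = strand,
                              n_subs = n_subs),
       fastq = out_fastq)
}
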