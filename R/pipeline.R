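#' Run the full inference pipeline on annotation and quality tables
#'
#' Executes, in order: hit filtering, MAG quality control, the nitrogen
#' marker census, trophy classification, guild assignment, community
#' counts, the NOx exchange network, auxotrophy/complementarity profiling,
#' and (when reads and references are supplied) the marker-gene read
#' screen. All results are written under `out_dir` as TSV/JSON/DOT plus a
#' human-readable text summary; every number in the text summary is also
#' present in `summary.json`. Output is a pure function of the inputs and
#' configuration: rerunning with the same arguments produces byte-
#' identical files. On a stage failure the partial output directory is
#' removed and the error names the stage.
#'
#' @param annotations_path,quality_path Input TSVs (see
#'   [read_annotation_table()], [read_quality_table()]).
#' @param out_dir Output directory (must not already contain a run unless
#'   `overwrite = TRUE`).
#' @param reads,refs,ref_groups Optional read screen inputs: FASTA/FASTQ
#'   reads, FASTA references, and a `ref_id`/`group_id` data frame.
#' @param defs,marker_map,rules Configuration tables (shipped defaults).
#' @param nxr_as_nar,include_hypothetical Rule switches (see
#'   [community_counts()], [derive_edges()]).
#' @param max_evalue,min_bitscore,min_identity Hit filter overrides.
#' @param min_completeness QC completeness floor (percent).
#' @param overwrite Replace an existing output directory.
#' @return Invisibly, a list with every intermediate result (`community`,
#'   `census`, `guilds`, `counts`, `network`, `profiles`,
#'   `complementarity`, `rpm`, `files`).
#' @export
run_pipeline <- function(annotations_path, quality_path, out_dir,
                         reads = NULL, refs = NULL, ref_groups = NULL,
                         defs = read_pathway_defs(),
                         marker_map = read_marker_map(),
                         rules = read_ncycle_rules(),
                         nxr_as_nar = FALSE, include_hypothetical = FALSE,
                         max_evalue = 1e-5, min_bitscore = 60,
                         min_identity = 30, min_completeness = 70,
                         overwrite = FALSE) {
  for (p in c(annotations_path, quality_path)) {
    if (!file.exists(p)) stop("input file not found: ", p, call. = FALSE)
  }
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0 && !overwrite) {
    stop("output directory ", out_dir,
         " is not empty (use overwrite = TRUE)", call. = FALSE)
  }
  stage_dir <- tempfile("ng_run_")
  dir.create(stage_dir)
  ok <- FALSE
  on.exit(if (!ok) unlink(stage_dir, recursive = TRUE))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  out <- function(f) file.path(stage_dir, f)
  config <- list(
    annotations = annotations_path, quality = quality_path,
    nxr_as_nar = nxr_as_nar, include_hypothetical = include_hypothetical,
    max_evalue = max_evalue, min_bitscore = min_bitscore,
    min_identity = min_identity, min_completeness = min_completeness,
    read_screen = !is.null(reads))

  community <- stage("qc", {
    hits <- filter_hits(read_annotation_table(annotations_path),
                        max_evalue, min_bitscore, min_identity)
    qc_filter(as_community(hits, read_quality_table(quality_path),
                           provenance = annotations_path),
              min_completeness)
  })
  cen <- stage("census", census(community, marker_map))
  trophy <- stage("trophy", classify_trophy(community, defs))
  guilds <- stage("guilds", assign_guilds(cen, trophy, rules))
  counts <- stage("counts", community_counts(cen, nxr_as_nar))
  net <- stage("network", {
    build_exchange_network(derive_edges(cen, rules, include_hypothetical))
  })
  profiles <- stage("auxotrophy", trophy_profiles(community, defs))
  compl <- stage("auxotrophy", complementarity_report(profiles, community))
  rpm <- NULL
  if (!is.null(reads)) {
    rpm <- stage("read_screen", {
      if (is.null(refs) || is.null(ref_groups)) {
        stop("reads given without refs/ref_groups")
      }
      reads_set <- as_dna(reads)
      hits <- align_reads(reads_set, refs)
      rpm_summary(hits, ref_groups, total_reads = length(reads_set))
    })
  }

  stage("report", {
    readr::write_tsv(cen, out("census.tsv"), progress = FALSE)
    readr::write_tsv(
      dplyr::select(guilds, -dplyr::any_of("fixation_pathways")),
      out("guilds.tsv"), progress = FALSE)
    readr::write_tsv(counts, out("counts.tsv"), progress = FALSE)
    export_network(net, out("network_edges.tsv"), out("network.dot"))
    readr::write_tsv(trophy_matrix(profiles, "amino_acid"),
                     out("aa_matrix.tsv"), progress = FALSE)
    readr::write_tsv(trophy_matrix(profiles, "b_vitamin"),
                     out("vitamin_matrix.tsv"), progress = FALSE)
    readr::write_tsv(
      dplyr::select(compl, "compound", "category", "n_providers",
                    "n_dependents", "community_wide_auxotrophy"),
      out("complementarity.tsv"), progress = FALSE)
    if (!is.null(rpm)) {
      readr::write_tsv(rpm, out("rpm.tsv"), progress = FALSE)
    }
    cand <- dplyr::filter(net$intermediates, .data$exchange_candidate)
    summary <- list(
      config = config,
      n_genomes = nrow(community$genomes),
      counts = rlang::set_names(as.list(counts$count), counts$metric),
      guilds = rlang::set_names(
        lapply(c("aob", "anaob", "nob_canonical", "comammox",
                 "dnra_complete", "denitrifier_complete"),
               function(g) guilds$genome_id[guilds[[g]]]),
        c("aob", "anaob", "nob_canonical", "comammox", "dnra_complete",
          "denitrifier_complete")),
      autotrophs = trophy$genome_id[trophy$trophy == "autotroph"],
      exchange_candidates = rlang::set_names(
        purrr::map(seq_len(nrow(cand)), function(i) {
          list(donors = cand$donors[[i]], acceptors = cand$acceptors[[i]])
        }), cand$intermediate),
      prototrophy = list(
        full_aa_prototrophs = profiles$genome_id[profiles$aa_fraction == 1],
        mean_aa_fraction = mean(profiles$aa_fraction),
        community_wide_auxotrophies =
          compl$compound[compl$community_wide_auxotrophy]),
      rpm = if (!is.null(rpm))
        rlang::set_names(as.list(rpm$rpm), rpm$group_id))
    jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, null = "null")
    writeLines(render_text_summary(summary), out("summary.txt"))
    manifest <- sort(dir(stage_dir))
    jsonlite::write_json(c(manifest, "manifest.json"),
                         out("manifest.json"), pretty = TRUE)
  })

  if (dir.exists(out_dir)) unlink(out_dir, recursive = TRUE)
  dir.create(out_dir, recursive = TRUE)
  for (f in dir(stage_dir)) {
    file.copy(file.path(stage_dir, f), file.path(out_dir, f))
  }
  unlink(stage_dir, recursive = TRUE)
  ok <- TRUE
  invisible(list(community = community, census = cen, guilds = guilds,
                 counts = counts, network = net, profiles = profiles,
                 complementarity = compl, rpm = rpm,
                 files = file.path(out_dir, sort(dir(out_dir)))))
}

render_text_summary <- function(s) {
  cnt <- function(m) s$counts[[m]]
  lines <- c(
    "Community functional summary",
    "============================",
    sprintf("Genomes passing QC: %d", s$n_genomes),
    "",
    "Nitrogen marker census:",
    sprintf("  nitrate reductase operon (nar): %d", cnt("narGHIJ")),
    sprintf("  nxr/nar homolog carriers: %d", cnt("nxr_nar_homolog_carriers")),
    sprintf("  nitrate reducers%s: %d",
            if (isTRUE(s$config$nxr_as_nar)) " (nxr-like counted)" else "",
            cnt("nitrate_reducers")),
    sprintf("  nitrite reducers (nirS %d / nirK %d): %d",
            cnt("nirS"), cnt("nirK"), cnt("nitrite_reducers")),
    sprintf("  both nir and nar: %d", cnt("nir_and_nar")),
    sprintf("  NO reducers (norBC %d / norZ %d): %d",
            cnt("norBC"), cnt("norZ"), cnt("no_reducers")),
    sprintf("  nosZ clade I: %d, clade II: %d (with nir: %d, with nar: %d)",
            cnt("nosZ_cladeI"), cnt("nosZ_cladeII"), cnt("noszII_and_nir"),
            cnt("noszII_and_nar")),
    sprintf("  DNRA nitrite reductases: nrfHA %d, nirBD %d",
            cnt("nrfHA"), cnt("nirBD")),
    "",
    "Guilds:",
    sprintf("  AOB: %s", paste(s$guilds$aob, collapse = ", ")),
    sprintf("  AnAOB: %s", paste(s$guilds$anaob, collapse = ", ")),
    sprintf("  canonical NOB: %s",
            if (length(s$guilds$nob_canonical))
              paste(s$guilds$nob_canonical, collapse = ", ") else "(none)"),
    sprintf("  complete denitrifiers: %s",
            paste(s$guilds$denitrifier_complete, collapse = ", ")),
    sprintf("  complete DNRA: %s",
            paste(s$guilds$dnra_complete, collapse = ", ")),
    sprintf("  autotrophs (%d): %s", length(s$autotrophs),
            paste(s$autotrophs, collapse = ", ")),
    "",
    sprintf("Exchange-candidate intermediates: %s",
            if (length(s$exchange_candidates))
              paste(names(s$exchange_candidates), collapse = ", ")
            else "(none)"),
    "",
    "Prototrophy:",
    sprintf("  fully AA-prototrophic: %s",
            paste(s$prototrophy$full_aa_prototrophs, collapse = ", ")),
    sprintf("  mean AA prototrophy fraction: %.3f",
            s$prototrophy$mean_aa_fraction),
    sprintf("  community-wide auxotrophies: %s",
            if (length(s$prototrophy$community_wide_auxotrophies))
              paste(s$prototrophy$community_wide_auxotrophies,
                    collapse = ", ") else "(none)"))
  if (!is.null(s$rpm)) {
    lines <- c(lines, "", "Read screen (RPM):",
               sprintf("  %s: %.1f", names(s$rpm), unlist(s$rpm)))
  }
  lines
}
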