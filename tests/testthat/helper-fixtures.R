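# Shared test helpers: tiny in-code fixtures and independent oracles.

write_tmp_tsv <- function(df) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  readr::write_tsv(df, path, progress = FALSE, na = "")
  path
}

# Random gene-hit table with statistics straddling all three thresholds.
random_hits <- function(n, seed) {
  set.seed(seed)
  tibble::tibble(
    genome_id = sample(paste0("G", 1:5), n, replace = TRUE),
    gene = sample(letters, n, replace = TRUE),
    evalue = 10^stats::runif(n, -12, -2),
    bitscore = stats::runif(n, 20, 120),
    identity = stats::runif(n, 10, 90),
    label = NA_character_)
}

# Minimal community from a named list of gene-character-vectors.
toy_community <- function(gene_list, completeness = 95,
                          contamination = 0.5) {
  hits <- purrr::imap_dfr(gene_list, function(genes, id) {
    tibble::tibble(genome_id = id, gene = genes,
                   evalue = 0, bitscore = Inf, identity = 100,
                   label = NA_character_)
  })
  if (length(gene_list) == 0) {
    hits <- tibble::tibble(genome_id = character(), gene = character(),
                           evalue = double(), bitscore = double(),
                           identity = double(), label = character())
  }
  quality <- tibble::tibble(
    genome_id = as.character(names(gene_list)),
    completeness = rep_len(completeness, length(gene_list)),
    contamination = rep_len(contamination, length(gene_list)),
    abundance = NA_real_)
  as_community(hits, quality)
}

# Community built from explicit (gene, label) tibbles per genome, for
# census tests needing clade/class labels.
labelled_community <- function(tbl_list) {
  hits <- purrr::imap_dfr(tbl_list, function(tb, id) {
    dplyr::mutate(tb, genome_id = id, evalue = 0, bitscore = Inf,
                  identity = 100, .before = 1)
  })
  quality <- tibble::tibble(genome_id = names(tbl_list),
                            completeness = 95, contamination = 0,
                            abundance = NA_real_)
  as_community(hits, quality)
}

genes_with_labels <- function(gene, label = NA_character_) {
  tibble::tibble(gene = gene, label = rep_len(label, length(gene)))
}

# The shipped fixture, built once per test run.
pna_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_fixture(validate = FALSE)
    cache
  }
})
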