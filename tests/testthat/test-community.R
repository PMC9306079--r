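test_that("annotation tables are read with sentinel statistics", {
  path <- write_tmp_tsv(tibble::tibble(
    genome_id = c("G1", "G1", "G2"), gene = c("narG", "narH", "nirS"),
    evalue = c(1e-10, 1e-8, 1e-20), bitscore = c(80, 90, 200),
    identity = c(45, 50, 88)))
  hits <- read_annotation_table(path)
  expect_equal(nrow(hits), 3)
  expect_equal(hits$gene, c("narg", "narh", "nirs"))

  # presence-only table: sentinels must pass the filter unconditionally
  p2 <- write_tmp_tsv(tibble::tibble(genome_id = "G1",
                                     gene = c("hzsA", "hdh")))
  h2 <- read_annotation_table(p2)
  expect_equal(nrow(filter_hits(h2)), 2)

  p3 <- write_tmp_tsv(tibble::tibble(genome_id = "G1", foo = "x"))
  expect_error(read_annotation_table(p3), "gene")
})

test_that("K numbers keep their case, symbols are lower-cased", {
  expect_equal(normalize_gene(c("K00370", "k00371", "NarG")),
               c("K00370", "K00371", "narg"))
})

test_that("hit filter applies strict thresholds and matches a row-wise
          predicate oracle", {
  hits <- tibble::tibble(
    genome_id = "G", gene = letters[1:4],
    evalue = c(1e-6, 1e-5, 1e-6, 1e-6),
    bitscore = c(61, 100, 60, 61),
    identity = c(31, 90, 31, 30), label = NA_character_)
  kept <- filter_hits(hits)
  expect_equal(kept$gene, "a")  # rows 2-4 each sit on one boundary

  big <- random_hits(1000, seed = 42)
  kept <- filter_hits(big)
  oracle <- big[mapply(function(e, b, i) e < 1e-5 && b > 60 && i > 30,
                       big$evalue, big$bitscore, big$identity), ]
  expect_equal(kept, tibble::as_tibble(oracle))
  # idempotent and order-preserving
  expect_equal(filter_hits(kept), kept)
})

test_that("QC keeps complete or contamination-free genomes only", {
  q <- tibble::tibble(
    genome_id = c("A", "B", "C", "D"),
    completeness = c(72, 50, 50, 70),
    contamination = c(3, 0, 1, 5))
  kept <- qc_filter(q)
  expect_equal(kept$genome_id, c("A", "B", "D"))
  expect_equal(qc_filter(kept), kept)

  # set-builder oracle on a random table
  set.seed(7)
  rq <- tibble::tibble(genome_id = paste0("G", 1:200),
                       completeness = stats::runif(200, 30, 100),
                       contamination = sample(c(0, 0, 1, 2, 5), 200, TRUE))
  expect_equal(
    qc_filter(rq)$genome_id,
    rq$genome_id[vapply(seq_len(200), function(i) {
      rq$completeness[i] >= 70 || rq$contamination[i] == 0
    }, logical(1))])
})

test_that("dereplication ranks completeness, then contamination, then
          assembly size, and returns an input element", {
  cand <- tibble::tibble(genome_id = "M",
                         completeness = c(90, 85),
                         contamination = c(2, 0))
  expect_equal(dereplicate(cand)$completeness, 90)

  tie <- tibble::tibble(genome_id = "M", completeness = c(90, 90),
                        contamination = c(2, 1))
  expect_equal(dereplicate(tie)$contamination, 1)

  single <- tibble::tibble(genome_id = "M", completeness = 75,
                           contamination = 1)
  expect_equal(dereplicate(single), single)
  expect_error(dereplicate(single[0, ]), "at least one")

  # enumerated ranking oracle on random candidate sets
  set.seed(11)
  for (k in 1:25) {
    cs <- tibble::tibble(
      genome_id = "M",
      completeness = sample(70:99, 4, replace = TRUE),
      contamination = sample(0:3, 4, replace = TRUE),
      assembly_size = sample(1:5 * 1e6, 4, replace = TRUE))
    pick <- dereplicate(cs)
    best <- cs[order(-cs$completeness, cs$contamination,
                     -cs$assembly_size), ][1, ]
    expect_equal(pick, best)
    expect_true(any(apply(cs, 1, function(r) all(r == unlist(pick)))))
  }
})

test_that("communities deduplicate genes and round-trip through TSV", {
  com <- toy_community(list(G1 = c("narG", "narG", "nirS"), G2 = "nosZ"))
  expect_equal(gene_sets(com)$G1, c("narg", "nirs"))

  ann <- withr::local_tempfile(fileext = ".tsv")
  qual <- withr::local_tempfile(fileext = ".tsv")
  write_community(com, ann, qual)
  back <- read_community(ann, qual)
  expect_equal(gene_sets(back), gene_sets(com))
  expect_equal(back$genomes, com$genomes)
})
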