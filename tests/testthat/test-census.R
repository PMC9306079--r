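mmap <- read_marker_map()
rules <- read_ncycle_rules()

test_that("operon flags require the catalytic core with matching labels", {
  com <- labelled_community(list(
    aob = genes_with_labels(c("amoA", "amoB", "amoC", "hao", "nirK",
                              "norB", "norC")),
    amx = dplyr::bind_rows(
      genes_with_labels(c("hzsA", "hzsB", "hzsC", "hdh")),
      genes_with_labels(c("nxrA", "nxrB"), "anammox")),
    partial_operons = genes_with_labels(c("narG", "norB", "hzsA",
                                          "hzsB")),
    nosz2 = genes_with_labels("nosZ", "cladeII"),
    empty = genes_with_labels(character())))
  cen <- census(com, mmap)

  aob <- cen[cen$genome_id == "aob", ]
  expect_true(aob$amoCABDE && aob$hao && aob$nirK && aob$norBC)
  expect_false(aob$narGHIJ || aob$nosZ_cladeII)

  amx <- cen[cen$genome_id == "amx", ]
  expect_true(amx$hzsABC && amx$hdh && amx$nxrAB_anammox)
  expect_false(amx$nirK || amx$nxr_like_periplasmic)

  part <- cen[cen$genome_id == "partial_operons", ]
  expect_false(part$narGHIJ)   # narH missing
  expect_false(part$norBC)     # norC missing
  expect_false(part$hzsABC)    # hzsC missing

  nosz <- cen[cen$genome_id == "nosz2", ]
  expect_true(nosz$nosZ_cladeII)
  expect_false(nosz$nosZ_cladeI)

  emp <- cen[cen$genome_id == "empty", ]
  flags <- vapply(emp, is.logical, logical(1))
  expect_false(any(unlist(emp[, flags])))
  expect_equal(emp$hao_like_count, 0L)
})

test_that("hao-like homolog copies are counted, not flagged", {
  com <- pna_fixture()
  cen <- census(com, mmap)
  expect_equal(cen$hao_like_count[match(c("AMX1", "AMX2", "AMX3"),
                                        cen$genome_id)],
               c(10L, 10L, 6L))
})

test_that("guild assignment follows the marker logic", {
  com <- labelled_community(list(
    full_denit = dplyr::bind_rows(
      genes_with_labels(c("narG", "narH", "narI", "nirS", "norB",
                          "norC")),
      genes_with_labels("nosZ", "cladeI")),
    dnra = genes_with_labels(c("narG", "narH", "nrfA", "nrfH")),
    comammox = dplyr::bind_rows(
      genes_with_labels(c("amoA", "amoB", "amoC", "hao")),
      genes_with_labels(c("nxrA", "nxrB"), "canonical")),
    nob = genes_with_labels(c("nxrA", "nxrB", "rbcL", "prkB"),
                            c("canonical", "canonical", NA, NA))))
  cen <- census(com, mmap)
  trophy <- classify_trophy(com)
  g <- assign_guilds(cen, trophy, rules)

  expect_true(g$denitrifier_complete[g$genome_id == "full_denit"])
  expect_equal(g$denit_class[g$genome_id == "full_denit"], "full")
  expect_true(g$dnra_complete[g$genome_id == "dnra"])
  expect_true(g$comammox[g$genome_id == "comammox"])
  expect_false(g$nob_canonical[g$genome_id == "comammox"]) # amo present
  expect_true(g$nob_canonical[g$genome_id == "nob"])       # autotroph nxr
})

test_that("guild sets are monotone in gene content", {
  base <- genes_with_labels(c("narG", "narH", "nrfA", "nrfH"))
  extra <- dplyr::bind_rows(base,
                            genes_with_labels(c("nirS", "norB", "norC")),
                            genes_with_labels("nosZ", "cladeII"))
  com <- labelled_community(list(small = base, big = extra))
  g <- assign_guilds(census(com, mmap), NULL, rules)
  cols <- c("aob", "anaob", "dnra_complete", "denitrifier_complete")
  small <- unlist(g[g$genome_id == "small", cols])
  big <- unlist(g[g$genome_id == "big", cols])
  expect_true(all(big[small]))   # everything small has, big keeps
})

test_that("community counts equal brute-force per-genome counting", {
  com <- pna_fixture()
  cen <- census(com, mmap)
  counts <- community_counts(cen)
  brute <- function(pred) sum(vapply(seq_len(nrow(cen)), function(i) {
    pred(as.list(cen[i, ]))
  }, logical(1)))
  expect_equal(counts$count[counts$metric == "narGHIJ"],
               brute(function(r) r$narGHIJ))
  expect_equal(counts$count[counts$metric == "nitrite_reducers"],
               brute(function(r) r$nirS || r$nirK))
  expect_equal(counts$count[counts$metric == "nir_and_nar"],
               brute(function(r) (r$nirS || r$nirK) && r$narGHIJ))
  expect_equal(counts$count[counts$metric == "no_reducers"],
               brute(function(r) r$norBC || r$norZ))
  expect_equal(counts$count[counts$metric == "nxr_nar_homolog_carriers"],
               brute(function(r) r$narGHIJ || r$nxrAB_anammox ||
                       r$nxr_like_periplasmic || r$nxr_canonical))

  # random flag tables against the same brute force
  set.seed(21)
  rnd <- cen
  for (cl in names(rnd)[vapply(rnd, is.logical, logical(1))]) {
    rnd[[cl]] <- sample(c(TRUE, FALSE), nrow(rnd), replace = TRUE)
  }
  rc <- community_counts(rnd, nxr_as_nar = TRUE)
  want <- sum(vapply(seq_len(nrow(rnd)), function(i) {
    r <- as.list(rnd[i, ])
    r$narGHIJ || r$napAB || r$nxr_like_periplasmic
  }, logical(1)))
  expect_equal(rc$count[rc$metric == "nitrate_reducers"], want)
})

test_that("an empty community yields an all-zero summary", {
  cen <- census(toy_community(list()), mmap)
  counts <- community_counts(cen)
  expect_true(all(counts$count == 0))
})
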