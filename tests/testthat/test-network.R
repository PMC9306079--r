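mmap <- read_marker_map()
rules <- read_ncycle_rules()

cen_of <- function(tbl_list) census(labelled_community(tbl_list), mmap)

test_that("edges are licensed exactly by census flags", {
  cen <- cen_of(list(
    cfx2 = genes_with_labels(c("narG", "narH", "nirK")),
    clb1 = dplyr::bind_rows(genes_with_labels(c("narG", "narH")),
                            genes_with_labels("nosZ", "cladeII")),
    empty = genes_with_labels(character())))
  edges <- derive_edges(cen, rules)

  cfx2 <- edges[edges$genome_id == "cfx2", ]
  expect_setequal(paste(cfx2$substrate, cfx2$product),
                  c("NO3- NO2-", "NO2- NO"))
  clb1 <- edges[edges$genome_id == "clb1", ]
  expect_setequal(paste(clb1$substrate, clb1$product),
                  c("NO3- NO2-", "N2O N2"))
  expect_false("empty" %in% edges$genome_id)
})

test_that("anammox nxr is reversible and hzs consumes NO and NH4+", {
  cen <- cen_of(list(amx = dplyr::bind_rows(
    genes_with_labels(c("hzsA", "hzsB", "hzsC", "hdh")),
    genes_with_labels(c("nxrA", "nxrB"), "anammox"))))
  edges <- derive_edges(cen, rules)
  expect_setequal(
    paste(edges$substrate, edges$product),
    c("NO2- NO3-", "NO3- NO2-", "NO N2H4", "NH4+ N2H4", "N2H4 N2"))
  expect_true(any(grepl("NO3- source", edges$note)))
})

test_that("hypothetical hao-like edges are off unless requested", {
  cen <- cen_of(list(amx = genes_with_labels(
    c("hao_like.01", "hao_like.02"))))
  expect_equal(nrow(derive_edges(cen, rules)), 0)
  hyp <- derive_edges(cen, rules, include_hypothetical = TRUE)
  expect_true(all(hyp$enzyme == "hao_like"))
  expect_gt(nrow(hyp), 0)
})

test_that("a rule naming an unknown group is a configuration error", {
  cen <- cen_of(list(g = genes_with_labels("nirS")))
  bad <- tibble::tibble(group = "nirX", substrate = "NO2-", product = "NO",
                        hypothetical = FALSE, note = NA_character_)
  expect_error(derive_edges(cen, bad), "unknown enzyme group")
})

test_that("endpoint labels follow the denitrification chain", {
  cen <- cen_of(list(
    aob = genes_with_labels(c("amoA", "amoB", "amoC", "hao", "nirK",
                              "norB", "norC")),
    pro3 = dplyr::bind_rows(
      genes_with_labels(c("narG", "narH", "nirS", "norB", "norC")),
      genes_with_labels("nosZ", "cladeI")),
    clb1 = dplyr::bind_rows(genes_with_labels(c("narG", "narH")),
                            genes_with_labels("nosZ", "cladeII")),
    nar_only = genes_with_labels(c("narG", "narH")),
    nos_only = genes_with_labels("nosZ", "cladeII")))
  ends <- predict_endpoints(derive_edges(cen, rules))
  lab <- function(g) ends$denit_class[ends$genome_id == g]
  expect_equal(lab("aob"), "NO2->N2O")
  expect_equal(lab("pro3"), "full")
  expect_equal(lab("clb1"), "NO3->NO2+N2O->N2")
  expect_equal(lab("nar_only"), "NO3->NO2")
  expect_equal(lab("nos_only"), "N2O->N2")

  # chain-following oracle on random link patterns
  set.seed(31)
  chain <- c("NO3-", "NO2-", "NO", "N2O", "N2")
  for (k in 1:30) {
    links <- sample(c(TRUE, FALSE), 4, replace = TRUE)
    edges <- tibble::tibble(
      genome_id = "g",
      substrate = chain[1:4][links], product = chain[2:5][links],
      enzyme = "x", note = NA_character_)
    got <- if (nrow(edges) == 0) "none" else
      predict_endpoints(edges)$denit_class
    # oracle: walk the chain, collect maximal runs
    runs <- character()
    i <- 1
    while (i <= 4) {
      if (links[i]) {
        j <- i
        while (j < 4 && links[j + 1]) j <- j + 1
        runs <- c(runs, if (i == 1 && j == 4) "full" else
          paste0(sub("-$", "", chain[i]), "->", sub("-$", "", chain[j + 1])))
        i <- j + 1
      } else {
        i <- i + 1
      }
    }
    want <- if (length(runs) == 0) "none" else paste(runs, collapse = "+")
    expect_equal(got, want)
  }
})

test_that("edge derivation is order-invariant per genome", {
  com <- pna_fixture()
  cen <- census(com, mmap)
  edges1 <- derive_edges(cen, rules)
  cen_rev <- cen[rev(seq_len(nrow(cen))), ]
  edges2 <- derive_edges(cen_rev, rules)
  key <- function(e) sort(paste(e$genome_id, e$substrate, e$product,
                                e$enzyme))
  expect_equal(key(edges1), key(edges2))
})

test_that("exchange candidates require a donor and an acceptor", {
  # single genome with the full pathway: producer and consumer sets
  # overlap everywhere, so nothing can be exchanged
  cen <- cen_of(list(solo = dplyr::bind_rows(
    genes_with_labels(c("narG", "narH", "nirS", "norB", "norC")),
    genes_with_labels("nosZ", "cladeI"))))
  net <- build_exchange_network(derive_edges(cen, rules))
  expect_false(any(net$intermediates$exchange_candidate))

  # no genome may be both donor and acceptor of one intermediate
  com <- pna_fixture()
  edges <- derive_edges(census(com, mmap), rules)
  net <- build_exchange_network(edges)
  for (i in seq_len(nrow(net$intermediates))) {
    expect_length(intersect(net$intermediates$donors[[i]],
                            net$intermediates$acceptors[[i]]), 0)
  }

  # brute-force oracle on random communities
  set.seed(41)
  for (k in 1:10) {
    rnd <- tibble::tibble(
      genome_id = sample(paste0("g", 1:6), 12, replace = TRUE),
      substrate = sample(c("A", "B", "C"), 12, replace = TRUE),
      product = sample(c("A", "B", "C"), 12, replace = TRUE),
      enzyme = "e", note = NA_character_)
    rnd <- rnd[rnd$substrate != rnd$product, ]
    net <- build_exchange_network(rnd)
    for (x in net$intermediates$intermediate) {
      prod <- unique(rnd$genome_id[rnd$product == x])
      cons <- unique(rnd$genome_id[rnd$substrate == x])
      want <- length(setdiff(prod, cons)) > 0 &&
        length(setdiff(cons, prod)) > 0
      expect_identical(
        net$intermediates$exchange_candidate[
          net$intermediates$intermediate == x], want)
    }
  }
})

test_that("tidy and glance summarise the network", {
  cen <- cen_of(list(a = genes_with_labels("nirS"),
                     b = genes_with_labels("norZ")))
  net <- build_exchange_network(derive_edges(cen, rules))
  td <- tidy(net)
  expect_setequal(names(td), c("genome_id", "intermediate", "role",
                               "enzyme"))
  gl <- glance(net)
  expect_equal(gl$n_genomes, 2)
  expect_equal(gl$n_exchange_candidates,
               sum(net$intermediates$exchange_candidate))
})

test_that("network export round-trips and is deterministic", {
  com <- pna_fixture()
  net <- build_exchange_network(derive_edges(census(com, mmap), rules))
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  dot <- withr::local_tempfile(fileext = ".dot")
  export_network(net, f1, dot)
  back <- read_network(f1)
  expect_equal(back$intermediates, net$intermediates)
  export_network(back, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_true(any(grepl("digraph", readLines(dot))))

  # empty network: header-only file
  fe <- withr::local_tempfile(fileext = ".tsv")
  empty <- build_exchange_network(net$edges[0, ])
  export_network(empty, fe)
  expect_length(readLines(fe), 1)
})
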