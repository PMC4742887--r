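write_tsv_lines <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

test_that("edge lists are normalized, deduplicated and self-loop free", {
  g <- interaction_graph(tibble::tibble(from = c("A", "B", "A"),
                                        to = c("B", "A", "A")))
  expect_equal(nrow(g$edges), 1)
  expect_equal(g$n_self_loops_dropped, 1)
  expect_equal(g$n_duplicates_dropped, 1)

  path <- write_tsv_lines(c("src\tmyod1", "SRC\tMYOD1\textra\tcols"))
  g2 <- read_edge_list(path)
  expect_equal(g2$edges$from, "MYOD1")
  expect_equal(g2$edges$to, "SRC")
  expect_equal(nrow(g2$edges), 1)
})

test_that("headers are auto-detected and symbol maps applied", {
  path <- write_tsv_lines(c("Official Symbol A\tOfficial Symbol B",
                            "Src\tMyod"))
  g <- read_edge_list(path, symbol_map = default_symbol_map())
  expect_equal(sort(g$nodes), c("MYOD1", "SRC"))

  expect_error(read_edge_list(write_tsv_lines("just_one_column")),
               "fewer than 2")
  expect_warning(g0 <- read_edge_list(write_tsv_lines(character())), "empty")
  expect_equal(nrow(g0$edges), 0)
})

test_that("merging graphs unions edges and keeps provenance", {
  g1 <- read_edge_list(write_tsv_lines("A\tB"), source = "hprd")
  g2 <- read_edge_list(write_tsv_lines(c("A\tB", "B\tC")), source = "biogrid")
  m <- merge_graphs(g1, g2)
  expect_equal(nrow(m$edges), 2)
  expect_setequal(m$edges$source, c("hprd", "biogrid"))
  expect_equal(m$n_duplicates_dropped, 1)
})

test_that("direct and semi-direct classification works on toy graphs", {
  g <- interaction_graph(tibble::tibble(from = "CSNK2A2", to = "MYF5"))
  cls <- classify_regulators(g, "CSNK2A2")
  pair <- cls$pairs[cls$pairs$mrf == "MYF5", ]
  expect_equal(pair$connection, "direct")
  expect_equal(cls$kinases$label, "direct")

  g2 <- interaction_graph(tibble::tibble(from = c("K1", "X"),
                                         to = c("X", "MYOD1")))
  cls2 <- classify_regulators(g2, "K1")
  pair2 <- cls2$pairs[cls2$pairs$mrf == "MYOD1", ]
  expect_equal(pair2$connection, "semi_direct")
  expect_equal(pair2$intermediaries[[1]], "X")

  # absent kinases are flagged and labelled unconnected
  cls3 <- classify_regulators(g2, c("K1", "NEK4"))
  expect_false(cls3$kinases$in_graph[cls3$kinases$kinase == "NEK4"])
  expect_equal(cls3$kinases$label[cls3$kinases$kinase == "NEK4"],
               "unconnected")

  expect_error(classify_regulators(g2, c("K1", "MYOD1")), "overlap")
})

test_that("query kinases and MRFs are excluded as intermediaries by default", {
  g <- interaction_graph(tibble::tibble(from = c("K1", "K2"),
                                        to = c("K2", "MYOG")))
  strict <- classify_regulators(g, c("K1", "K2"))
  p <- strict$pairs[strict$pairs$kinase == "K1" & strict$pairs$mrf == "MYOG", ]
  expect_equal(p$connection, "none")
  loose <- classify_regulators(g, c("K1", "K2"),
                               allow_query_intermediaries = TRUE)
  p2 <- loose$pairs[loose$pairs$kinase == "K1" & loose$pairs$mrf == "MYOG", ]
  expect_equal(p2$connection, "semi_direct")
  expect_equal(p2$intermediaries[[1]], "K2")
})

test_that("classification is invariant to row order and case, and edges never demote", {
  set.seed(101)
  for (i in 1:20) {
    edges <- random_edge_list(12, 25)
    g <- interaction_graph(edges)
    g_shuffled <- interaction_graph(
      dplyr::mutate(edges[sample(nrow(edges)), ], from = tolower(.data$from)))
    kin <- c("G01", "G02", "G03")
    mrfs <- mrf_set(c("G10", "G11"))
    a <- classify_regulators(g, kin, mrfs)
    b <- classify_regulators(g_shuffled, kin, mrfs)
    expect_equal(a$pairs, b$pairs)

    # add an edge: labels can only move up the ladder
    extra <- interaction_graph(dplyr::bind_rows(
      edges, tibble::tibble(from = "G01", to = "G10")))
    c_ <- classify_regulators(extra, kin, mrfs)
    rank <- c(unconnected = 0, semi_direct = 1, direct = 2)
    expect_true(all(rank[c_$kinases$label] >= rank[a$kinases$label]))
  }
})

test_that("classification agrees with exhaustive two-hop enumeration", {
  set.seed(102)
  for (i in 1:60) {
    edges <- random_edge_list(sample(5:30, 1), sample(5:60, 1))
    g <- interaction_graph(edges)
    kin <- sprintf("G%02d", 1:3)
    mrfs <- sprintf("G%02d", 4:5)
    got <- classify_regulators(g, kin, mrf_set(mrfs))
    want <- oracle_two_hop(g$edges, kin, mrfs)
    merged <- dplyr::inner_join(got$pairs, want, by = c("kinase", "mrf"),
                                suffix = c("", "_want"))
    expect_equal(merged$connection, merged$connection_want)
    expect_equal(merged$intermediaries, merged$intermediaries_want)
  }
})

test_that("network summaries rank with deterministic tie-breaking", {
  # node E touches 4 MRFs and one kinase: top intermediary with count 4
  edges <- tibble::tibble(
    from = c("K1", "E", "E", "E", "E", "K2", "F"),
    to = c("E", "MYOD1", "MEF2A", "MEF2C", "MEF2D", "F", "MYF5"))
  cls <- classify_regulators(interaction_graph(edges), c("K1", "K2"))
  s <- summarize_network(cls)
  expect_equal(s$intermediary_ranking$intermediary[1], "E")
  expect_equal(s$intermediary_ranking$n_mrfs[1], 4)
  # K1 (4 MRFs) outranks K2 (1 MRF)
  expect_equal(s$kinase_ranking$kinase, c("K1", "K2"))
  expect_equal(s$kinase_ranking$n_mrfs, c(4L, 1L))

  # equal counts order alphabetically
  edges2 <- tibble::tibble(from = c("KB", "KA"), to = c("MYOG", "MYOG"))
  s2 <- summarize_network(classify_regulators(interaction_graph(edges2),
                                              c("KB", "KA")))
  expect_equal(s2$kinase_ranking$kinase, c("KA", "KB"))

  # a single direct pair gives one row in kinase and MRF tables
  s3 <- summarize_network(classify_regulators(
    interaction_graph(tibble::tibble(from = "CSNK2A2", to = "MYF5")),
    "CSNK2A2"))
  expect_equal(nrow(s3$kinase_ranking), 1)
  expect_equal(nrow(s3$mrf_ranking), 1)
  expect_equal(nrow(s3$intermediary_ranking), 0)
})

test_that("SIF export round-trips and handles empty classifications", {
  edges <- tibble::tibble(from = c("CSNK2A2", "K1", "X"),
                          to = c("MYF5", "X", "MYOD1"))
  cls <- classify_regulators(interaction_graph(edges), c("CSNK2A2", "K1"))
  sif <- tempfile(fileext = ".sif")
  lines <- export_subnetwork(cls, sif)
  back <- read_sif(sif)
  expect_equal(nrow(back), length(lines))
  expect_true(all(c("direct", "via") %in% back$relation))
  expect_true(any(back$from == "CSNK2A2" & back$relation == "direct" &
                    back$to == "MYF5"))
  # two-hop paths appear as kinase-via-intermediary and intermediary-via-mrf
  expect_true(any(back$from == "K1" & back$to == "X"))
  expect_true(any(back$from == "X" & back$to == "MYOD1"))
  nodes <- readr::read_tsv(paste0(tools::file_path_sans_ext(sif), "_nodes.tsv"),
                           show_col_types = FALSE)
  expect_setequal(nodes$role[nodes$node == "X"], "intermediary")

  # exporting again is byte-identical
  sif2 <- tempfile(fileext = ".sif")
  export_subnetwork(cls, sif2)
  expect_identical(readLines(sif), readLines(sif2))

  empty <- classify_regulators(interaction_graph(
    tibble::tibble(from = "A", to = "B")), "K9")
  sif3 <- tempfile(fileext = ".sif")
  export_subnetwork(empty, sif3)
  expect_equal(nrow(read_sif(sif3)), 0)
})
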