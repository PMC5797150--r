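make_stitch_file <- function() {
  write_stitch_fixture(tempfile(fileext = ".tsv"), c(
    "cpdA\tp1\t900\t0\t0\t0\t900",
    "cpdA\tp2\t0\t0\t0\t950\t950",
    "cpdB\tp1\t920\t150\t0\t300\t920"
  ))
}

test_that("stitch-like parsing scales raw integer scores by 1/1000", {
  rec <- parse_stitch_like(make_stitch_file())
  expect_equal(nrow(rec), 3)
  expect_equal(rec$combined_score, c(0.9, 0.95, 0.92))
  expect_equal(rec$experimental[1], 0.9)
  expect_equal(rec$textmining[2], 0.95)
  expect_equal(rec$protein_id, c("P1", "P2", "P1"))
  expect_true(all(rec$source_db == "stitch_like"))
})

test_that("stitch parser enforces the header and the 0-999 score range", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("compound_id\tprotein_id\texperimental", "a\tb\t1"), f)
  expect_error(parse_stitch_like(f), "missing column")

  f2 <- write_stitch_fixture(tempfile(fileext = ".tsv"),
                             "cpdA\tp1\t1500\t0\t0\t0\t900")
  expect_error(parse_stitch_like(f2), "0-999")

  f3 <- write_stitch_fixture(tempfile(fileext = ".tsv"), character(0))
  expect_equal(nrow(parse_stitch_like(f3)), 0)
})

test_that("SIF parsing keeps duplicates and flags malformed lines", {
  f <- tempfile(fileext = ".sif")
  writeLines(c("quercetin\tinteracts-with\tCYP1A2",
               "quercetin\tinteracts-with\tCYP1A2"), f)
  rec <- parse_sif_like(f)
  expect_equal(nrow(rec), 2)   # dedup happens at merge, not parse
  expect_equal(rec$protein_id[1], "CYP1A2")

  writeLines("one two", f)
  expect_error(parse_sif_like(f), "3 fields")
})

test_that("bindingdb-like records parse regardless of affinity value", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("compound_id\tprotein_id\taffinity_nM",
               "genistein\tEGFR\t12000.5"), f)
  rec <- parse_bindingdb_like(f)
  expect_equal(nrow(rec), 1)
  expect_equal(rec$affinity_nM, 12000.5)
})

test_that("filter removes textmining-only and sub-threshold records", {
  rec <- parse_stitch_like(make_stitch_file())
  kept <- filter_interactions(rec, min_score = 0.9)
  # textmining-only record removed even though its combined score is 0.95
  expect_equal(kept$protein_id, c("P1", "P1"))

  f <- write_stitch_fixture(tempfile(fileext = ".tsv"),
                            "cpdA\tp1\t890\t0\t0\t0\t890")
  low <- parse_stitch_like(f)
  expect_equal(nrow(filter_interactions(low, min_score = 0.9)), 0)  # strict <
  expect_equal(nrow(filter_interactions(low, min_score = 0.7)), 1)

  expect_error(filter_interactions(rec, min_score = 1.1), "min_score")
})

test_that("non-scored dialects pass the score filter vacuously", {
  f <- tempfile(fileext = ".sif")
  writeLines("c1\trel\tP9", f)
  sif <- parse_sif_like(f)
  expect_equal(nrow(filter_interactions(sif, min_score = 0.9)), 1)
})

test_that("filter is monotone in min_score and in the textmining switch", {
  idb <- gen_interaction_db(paste0("c", 1:30), n_proteins = 20, seed = 5,
                            n_extra = 200)
  prev <- Inf
  for (ms in c(0.5, 0.7, 0.9, 0.95)) {
    n <- nrow(filter_interactions(idb$stitch, min_score = ms))
    expect_lte(n, prev)
    prev <- n
  }
  with_tm <- filter_interactions(idb$stitch, exclude_textmining_only = FALSE)
  without <- filter_interactions(idb$stitch, exclude_textmining_only = TRUE)
  expect_lte(nrow(without), nrow(with_tm))
})

test_that("merge deduplicates pairs and unions their sources", {
  st <- parse_stitch_like(write_stitch_fixture(
    tempfile(fileext = ".tsv"), "cpdA\tp1\t950\t0\t0\t0\t950"))
  f <- tempfile(fileext = ".sif"); writeLines("cpdA\trel\tp1", f)
  sif <- parse_sif_like(f)
  net <- merge_interactions(st, sif)
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$sources, "pathway_commons_like;stitch_like")
  expect_equal(net$n_records, 2)
})

test_that("disjoint record sets concatenate additively", {
  f1 <- tempfile(); writeLines(paste0("a", 1:3, "\trel\tP", 1:3), f1)
  f2 <- tempfile(); writeLines(paste0("b", 1:4, "\trel\tQ", 1:4), f2)
  net <- merge_interactions(parse_sif_like(f1), parse_sif_like(f2))
  expect_equal(nrow(net$edges), 7)
})

test_that("merging an interactome's edges with themselves changes nothing", {
  idb <- gen_interaction_db(paste0("c", 1:20), n_proteins = 15, seed = 9,
                            n_extra = 50)
  once <- merge_interactions(idb$stitch, idb$sif, idb$bindingdb)
  twice <- merge_interactions(idb$stitch, idb$sif, idb$bindingdb,
                              idb$stitch, idb$sif, idb$bindingdb)
  expect_equal(twice$edges, once$edges)
})

test_that("source_overlap partitions nodes and matches the planted cells", {
  combos <- polyphenome:::source_combos()
  ccells <- setNames(c(2L, 3L, 4L, 1L, 1L, 1L, 2L), combos)
  pcells <- setNames(c(3L, 2L, 3L, 1L, 2L, 1L, 2L), combos)
  idb <- gen_interaction_db(paste0("c", 1:14), n_proteins = 14, seed = 3,
                            n_extra = 100, compound_cells = ccells,
                            protein_cells = pcells)
  net <- merge_interactions(filter_interactions(idb$stitch), idb$sif,
                            idb$bindingdb)
  ov <- source_overlap(net)
  expect_equal(sum(ov$compounds), length(net$compounds))
  expect_equal(sum(ov$proteins), length(net$proteins))
  for (cb in combos) {
    expect_equal(ov$compounds[ov$sources == cb], ccells[[cb]],
                 info = paste("compound cell", cb))
    expect_equal(ov$proteins[ov$sources == cb], pcells[[cb]],
                 info = paste("protein cell", cb))
  }
})

test_that("single-source and empty interactomes have degenerate overlaps", {
  f <- tempfile(); writeLines(paste0("c", 1:5, "\trel\tP", 1:5), f)
  net <- merge_interactions(parse_sif_like(f))
  ov <- source_overlap(net)
  expect_equal(nrow(ov), 1)
  expect_equal(ov$compounds, 5)

  empty <- merge_interactions(polyphenome:::empty_records())
  expect_equal(nrow(source_overlap(empty)), 0)
})

test_that("degree histogram follows the boundary conventions", {
  f <- tempfile(); writeLines(paste0("cpd\trel\tP", 1:5), f)
  net <- merge_interactions(parse_sif_like(f))
  h <- degree_histogram(net, "compound")
  expect_equal(h$count[h$bin == "<=10"], 1)
  expect_equal(sum(h$count), 1)

  # protein with exactly 50 partners goes to the higher (50-70) bin
  f2 <- tempfile(); writeLines(paste0("c", 1:50, "\trel\tHUB"), f2)
  net2 <- merge_interactions(parse_sif_like(f2))
  h2 <- degree_histogram(net2, "protein")
  expect_equal(h2$count[h2$bin == "50-70"], 1)
  # its 50 compound partners have degree 1 each
  hc <- degree_histogram(net2, "compound")
  expect_equal(hc$count[hc$bin == "<=10"], 50)

  expect_error(degree_histogram(net2, "protein", breaks = c(5, 2)),
               "increasing")
})

test_that("degree histogram equals a brute-force tally on synthetic networks", {
  idb <- gen_interaction_db(paste0("c", 1:40), n_proteins = 30, seed = 13,
                            n_extra = 300)
  net <- merge_interactions(filter_interactions(idb$stitch), idb$sif,
                            idb$bindingdb)
  for (side in c("compound", "protein")) {
    ids <- if (side == "compound") net$edges$compound_id else net$edges$protein_id
    deg <- as.integer(table(ids))
    binf <- if (side == "compound") polyphenome:::compound_degree_bin
            else polyphenome:::protein_degree_bin
    brute <- table(vapply(deg, binf, character(1)))
    h <- degree_histogram(net, side)
    for (b in names(brute)) {
      expect_equal(h$count[h$bin == b], as.integer(brute[[b]]))
    }
    expect_equal(sum(h$count), length(deg))
  }
})

test_that("protein id mapping rewrites known identifiers", {
  rec <- parse_sif_like({f <- tempfile(); writeLines("c1\trel\tp53", f); f})
  mapped <- map_protein_ids(rec, data.frame(from = "p53", to = "TP53"))
  expect_equal(mapped$protein_id, "TP53")
})

test_that("graphml and edge-list exports produce readable files", {
  f <- tempfile(); writeLines(c("c1\trel\tP1", "c2\trel\tP1"), f)
  net <- merge_interactions(parse_sif_like(f))
  g <- tempfile(fileext = ".graphml")
  write_interactome_graphml(net, g)
  gg <- igraph::read_graph(g, format = "graphml")
  expect_equal(igraph::vcount(gg), 3)
  expect_equal(igraph::ecount(gg), 2)
  e <- tempfile(fileext = ".tsv")
  write_edge_list(net, e)
  expect_equal(nrow(read.delim(e)), 2)
})
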