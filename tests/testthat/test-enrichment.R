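test_that("hypergeometric upper tail matches exhaustive enumeration", {
  # worked example: 4 of a 5-member pathway drawn in 4 of 10
  expect_equal(hypergeometric_p(4, 5, 4, 10), 5 / 210, tolerance = 1e-12)
  expect_equal(hyper_enum(4, 5, 4, 10), 5 / 210, tolerance = 1e-12)

  # full sweep over every feasible configuration with N <= 12
  for (N in 1:12) for (K in 0:N) for (n in 0:N) {
    for (k in 0:min(K, n)) {
      expect_equal(hypergeometric_p(k, K, n, N), hyper_enum(k, K, n, N),
                   tolerance = 1e-10,
                   info = sprintf("k=%d K=%d n=%d N=%d", k, K, n, N))
    }
  }
})

test_that("hypergeometric degenerate cases and errors", {
  expect_equal(hypergeometric_p(0, 5, 4, 10), 1)
  expect_equal(hypergeometric_p(4, 10, 4, 10), 1)   # K = N forces k = n
  expect_error(hypergeometric_p(5, 4, 10, 10), "parameter error")
  expect_error(hypergeometric_p(2, 5, 4, 3), "parameter error")
})

test_that("hypergeometric agrees with the distribution in stats", {
  set.seed(71)
  for (i in 1:200) {
    N <- sample(20:500, 1); K <- sample(1:N, 1); n <- sample(1:N, 1)
    k <- sample(0:min(K, n), 1)
    expect_equal(hypergeometric_p(k, K, n, N),
                 stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
                 tolerance = 1e-9)
  }
})

test_that("adding a hit never increases the p-value", {
  set.seed(5)
  for (i in 1:50) {
    N <- sample(30:200, 1); K <- sample(2:(N / 2), 1); n <- sample(2:(N / 2), 1)
    ks <- 0:(min(K, n) - 1)
    p <- vapply(ks, function(k) hypergeometric_p(k, K, n, N), numeric(1))
    expect_true(all(diff(p) <= 1e-12))
  }
})

test_that("bh_adjust equals the brute-force step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.4), 0.4)
  expect_equal(bh_adjust(rep(0.5, 4)), rep(0.5, 4))
  expect_error(bh_adjust(c(0.2, 1.2)), "parameter error")

  set.seed(42)
  for (i in 1:1000) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), bh_bruteforce(p), tolerance = 1e-12)
  }
})

test_that("enrich computes counts, coverage and the dual criterion", {
  sets <- list(pw1 = paste0("P", 1:10), pw2 = paste0("P", 11:30))
  universe <- paste0("P", 1:40)
  res <- enrich(paste0("P", c(1:3, 31:33)), sets, universe)
  r1 <- res[res$pathway_id == "pw1", ]
  expect_equal(r1$k, 3); expect_equal(r1$K, 10)
  expect_equal(r1$coverage, 0.3)
  expect_equal(r1$n, 6); expect_equal(r1$N, 40)
  expect_equal(r1$p_raw, hypergeometric_p(3, 10, 6, 40))
  expect_equal(res$p_bh, bh_adjust(res$p_raw))
  expect_equal(sort(strsplit(r1$hits, ";")[[1]]), c("P1", "P2", "P3"))
})

test_that("an empty query yields k = 0 everywhere and no significance", {
  sets <- list(pw1 = paste0("P", 1:5))
  res <- enrich(character(0), sets, paste0("P", 1:20))
  expect_equal(res$k, 0)
  expect_false(any(res$significant))
})

test_that("out-of-universe query proteins are dropped with a message", {
  sets <- list(pw1 = paste0("P", 1:5))
  expect_message(
    res <- enrich(c("P1", "XX"), sets, paste0("P", 1:10)),
    "outside the universe")
  expect_equal(res$n, 1)
  expect_error(enrich("P1", sets, character(0)), "empty universe")
})

test_that("significance respects strict thresholds on both criteria", {
  # construct a pathway fully covered by the query
  sets <- list(pw1 = paste0("P", 1:5), pw2 = paste0("P", 6:50))
  universe <- paste0("P", 1:100)
  res <- enrich(paste0("P", 1:5), sets, universe, alpha = 0.1,
                min_coverage = 0.1)
  expect_true(res$significant[res$pathway_id == "pw1"])
  # coverage exactly at the threshold must NOT count (strict >)
  res2 <- enrich(paste0("P", 1:5), sets, universe, min_coverage = 1)
  expect_false(any(res2$significant))
  # the raw-p reading is never stricter than the adjusted one
  raw <- enrich(paste0("P", 1:5), sets, universe, use_raw_p = TRUE)
  expect_true(all(res$significant <= raw$significant))
})

test_that("class-wise enrichment keys queries by class label", {
  sif <- tempfile()
  writeLines(c("cpd1\trel\tP1", "cpd1\trel\tP2", "cpd2\trel\tP3",
               "cpd3\trel\tP9"), sif)
  net <- merge_interactions(parse_sif_like(sif))
  classified <- data.frame(
    compound_id = c("cpd1", "cpd2", "cpd3"),
    excluded = FALSE, exclusion_reason = "none", matched_patterns = "x",
    subclasses = "flavonols",
    classes = c("flavonoids", "flavonoids", "stilbenes"),
    stringsAsFactors = FALSE)
  sets <- list(pw1 = paste0("P", 1:3), pw2 = paste0("P", 4:8))
  universe <- paste0("P", 1:9)
  res <- enrich_by_class(net, classified, sets, universe)
  flav <- res[res$query_label == "flavonoids", ]
  expect_equal(flav$k[flav$pathway_id == "pw1"], 3)
  expect_error(enrich_by_class(net, classified, sets, universe,
                               classes = "lignans"), "lignans")
})

test_that("two classes with identical compound sets give identical tables", {
  sif <- tempfile()
  writeLines(c("cpd1\trel\tP1", "cpd2\trel\tP2"), sif)
  net <- merge_interactions(parse_sif_like(sif))
  classified <- data.frame(
    compound_id = c("cpd1", "cpd2"), excluded = FALSE,
    exclusion_reason = "none", matched_patterns = "x", subclasses = "s",
    classes = "flavonoids;stilbenes", stringsAsFactors = FALSE)
  sets <- list(pw1 = paste0("P", 1:4))
  res <- enrich_by_class(net, classified, sets, paste0("P", 1:8))
  a <- res[res$query_label == "flavonoids", -1]
  b <- res[res$query_label == "stilbenes", -1]
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
})

test_that("a class with no interacting proteins is skipped with a log", {
  sif <- tempfile(); writeLines("cpd1\trel\tP1", sif)
  net <- merge_interactions(parse_sif_like(sif))
  classified <- data.frame(
    compound_id = c("cpd1", "lonely"), excluded = FALSE,
    exclusion_reason = "none", matched_patterns = "x", subclasses = "s",
    classes = c("flavonoids", "lignans"), stringsAsFactors = FALSE)
  sets <- list(pw1 = c("P1", "P2"))
  expect_message(
    res <- enrich_by_class(net, classified, sets, paste0("P", 1:5)),
    "no interacting proteins")
  expect_false("lignans" %in% res$query_label)
})

test_that("category summary percentages and the CMD roll-up", {
  results <- data.frame(
    query_label = "flavonoids",
    pathway_id = paste0("pw", 1:4),
    coverage = c(0.5, 0.2, 0.3, 0.1),
    significant = c(TRUE, FALSE, TRUE, FALSE),
    stringsAsFactors = FALSE)
  ontology <- data.frame(
    pathway_id = paste0("pw", 1:4),
    category = c("Metabolism", "Metabolism", "Human Diseases", "Human Diseases"),
    subcategory = c("Lipid metabolism", "Lipid metabolism",
                    "Cardiovascular Diseases",
                    "Endocrine and Metabolic Diseases"),
    stringsAsFactors = FALSE)
  cs <- category_summary(results, ontology)
  met <- cs$percent[cs$percent$category == "Metabolism", ]
  expect_equal(met$percent, 50)
  cmd <- cs$percent[cs$percent$category == "CMD", ]
  expect_equal(cmd$n_pathways, 2)
  expect_equal(cmd$n_significant, 1)

  none <- results; none$significant <- FALSE
  cs0 <- category_summary(none, ontology)
  expect_true(all(cs0$percent$percent == 0))
  expect_equal(nrow(cs0$coverage), 0)

  expect_error(category_summary(results, ontology[-1, ]), "pw1")
})

test_that("a planted pathway is recovered in a single seeded run", {
  universe <- sprintf("P%04d", 1:1000)
  set.seed(99)
  query <- sample(universe, 50)
  pw <- gen_pathway_collection(
    universe, n_pathways = 20, size_range = c(10, 60), planted =
      data.frame(query_label = "q", pathway_id = "pw_0001", odds_ratio = 8,
                 size = 50),
    query_sets = list(q = query), seed = 7)
  res <- enrich(query, pw$gene_sets, universe)
  expect_true(res$significant[res$pathway_id == "pw_0001"])
})
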