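test_that("compound generator is deterministic and validates parameters", {
  f1 <- tempfile(); f2 <- tempfile()
  gen_compound_library(40, 0.5, seed = 3, path = f1)
  gen_compound_library(40, 0.5, seed = 3, path = f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_error(gen_compound_library(10, 1.5, 1), "parameter error")
  expect_error(gen_compound_library(0, 0.5, 1), "parameter error")
})

test_that("every generated SMILES parses", {
  lib <- gen_compound_library(60, 0.7, seed = 19)
  expect_true(all(smiles_valid(lib$compounds$smiles)))
})

test_that("a fraction-zero library contains no polyphenol classes", {
  lib <- gen_compound_library(12, 0, seed = 2)
  cl <- classify_batch(standardize(lib$compounds$smiles,
                                   lib$compounds$compound_id))
  expect_true(all(cl$classes == ""))
})

test_that("ledger subclasses are recovered by the classifier (recall >= 0.95)", {
  lib <- gen_compound_library(100, 1, seed = 8)
  cl <- classify_batch(standardize(lib$compounds$smiles,
                                   lib$compounds$compound_id))
  led <- lib$ledger$planted_polyphenols
  hit <- vapply(names(led), function(id) {
    grepl(led[[id]], cl$subclasses[cl$compound_id == id], fixed = TRUE)
  }, logical(1))
  expect_gte(mean(hit), 0.95)
})

test_that("decoy exclusion reasons are recovered exactly", {
  lib <- gen_compound_library(40, 0.5, seed = 4)
  cl <- classify_batch(standardize(lib$compounds$smiles,
                                   lib$compounds$compound_id))
  led <- lib$ledger$decoys
  got <- vapply(names(led), function(id) {
    cl$exclusion_reason[cl$compound_id == id]
  }, character(1))
  expect_equal(unname(got), unname(unlist(led)))
  # plain decoys survive but match nothing
  plain <- names(led)[unlist(led) == "none"]
  expect_true(all(cl$classes[cl$compound_id %in% plain] == ""))
})

test_that("interaction generator honours its ledger", {
  cpds <- paste0("c", 1:30)
  idb <- gen_interaction_db(cpds, n_proteins = 20, seed = 6, n_extra = 500,
                            textmining_only_rate = 0.3)
  led <- idb$ledger
  tm_only <- idb$stitch$textmining > 0 & idb$stitch$experimental == 0 &
    idb$stitch$database == 0 & idb$stitch$prediction == 0
  expect_equal(sum(tm_only), led$n_textmining_only)
  # and the count is near the binomial expectation
  expect_lt(abs(led$n_textmining_only - 0.3 * 500),
            3 * sqrt(500 * 0.3 * 0.7) + 1)

  # planted hub holds the strictly maximal compound degree
  net <- merge_interactions(idb$stitch, idb$sif, idb$bindingdb)
  deg <- table(net$edges$compound_id)
  expect_equal(names(deg)[which.max(deg)], led$hub_compound)

  expect_error(
    gen_interaction_db(cpds, 20, 1,
                       compound_cells = setNames(rep(10L, 7),
                                                 polyphenome:::source_combos())),
    "exceed")
})

test_that("zero cross-source overlap leaves intersection cells empty", {
  combos <- polyphenome:::source_combos()
  cells <- setNames(rep(0L, 7), combos)
  cells[!grepl(";", combos)] <- 5L
  idb <- gen_interaction_db(paste0("c", 1:15), n_proteins = 15, seed = 10,
                            n_extra = 50, compound_cells = cells,
                            protein_cells = cells)
  net <- merge_interactions(filter_interactions(idb$stitch), idb$sif,
                            idb$bindingdb)
  ov <- source_overlap(net)
  expect_true(all(!grepl(";", ov$sources)))
})

test_that("pathway generator is byte-deterministic and validates sizes", {
  universe <- paste0("P", 1:100)
  d1 <- tempfile(); d2 <- tempfile()
  gen_pathway_collection(universe, n_pathways = 8, size_range = c(5, 20),
                         seed = 12, dir = d1)
  gen_pathway_collection(universe, n_pathways = 8, size_range = c(5, 20),
                         seed = 12, dir = d2)
  expect_identical(readLines(file.path(d1, "pathways.gmt")),
                   readLines(file.path(d2, "pathways.gmt")))
  expect_error(
    gen_pathway_collection(universe, size_range = c(10, 200)),
    "exceeds universe")
  expect_error(
    gen_pathway_collection(universe, planted = data.frame(
      query_label = "ghost", pathway_id = "pw_0001", odds_ratio = 5),
      query_sets = list()),
    "ghost")
})

test_that("gmt and ontology round-trip through their readers", {
  universe <- paste0("P", 1:50)
  d <- tempfile()
  pw <- gen_pathway_collection(universe, n_pathways = 5,
                               size_range = c(4, 10), seed = 9, dir = d)
  sets <- read_gmt(file.path(d, "pathways.gmt"))
  expect_equal(sets[names(pw$gene_sets)], pw$gene_sets,
               ignore_attr = TRUE)
  ont <- read_pathway_ontology(file.path(d, "ontology.tsv"))
  expect_equal(ont, pw$ontology)
})

test_that("food generator realizes requested overlaps exactly", {
  pool <- paste0("c", 1:40)
  # identical foods via superset mechanism
  ft1 <- gen_food_table(pool, n_private = c(a = 0, b = 0), n_shared = 6,
                        seed = 2)
  cmp <- compare_foods(ft1$table)
  expect_equal(cmp$jaccard["a", "b"], 1)
  # disjoint foods
  ft0 <- gen_food_table(pool, n_private = c(a = 5, b = 5), n_shared = 0,
                        seed = 2)
  expect_equal(compare_foods(ft0$table)$jaccard["a", "b"], 0)
  # ledger matrix equals recomputation
  ft <- gen_food_table(pool, n_private = c(a = 4, b = 3, c = 2),
                       n_shared = 3, seed = 5)
  expect_equal(compare_foods(ft$table)$jaccard, ft$ledger$jaccard)
  expect_error(gen_food_table(paste0("c", 1:5),
                              n_private = c(a = 4, b = 4), n_shared = 2),
               "parameter error")
})

test_that("a near-universal pair tops the Jaccard ranking", {
  pool <- paste0("c", 1:60)
  ft <- gen_food_table(
    pool, n_private = c(f1 = 4, f2 = 4, f3 = 3, f4 = 3, lemon = 2, lime = 2),
    n_shared = 4, supersets = c("lemon", "lime"), seed = 13)
  jac <- compare_foods(ft$table)$jaccard
  diag(jac) <- 0
  top <- which(jac == max(jac), arr.ind = TRUE)
  expect_setequal(rownames(jac)[top[, 1]], c("lemon", "lime"))
})
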