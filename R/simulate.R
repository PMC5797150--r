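## Seeded synthetic-data generators. Every generator is deterministic under a
## fixed seed and returns, besides its artifact, a ledger of the planted
## ground truth so downstream stages can be validated without external data.
## Sub-seeds are derived from one master seed by labelled hashing, so adding
## a generator does not shift the streams of the others.

derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)) * 131)
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483646) + 1L
}

## ---- compound library ----------------------------------------------------

# Decoration slots: nothing, hydroxy, methoxy, or a glucosyl residue.
# The glucosyl ring uses closure digit 9 so it can sit inside scaffold
# templates whose own ring digits (1-3) are still open.
.decorations <- c("", "(O)", "(OC)", "(OC9OC(CO)C(O)C(O)C9O)")
.decoration_p <- c(0.35, 0.35, 0.2, 0.1)

# Stereo-free scaffold templates with decoration slots {a}/{b}/{c}; each maps
# to the subclass its core scaffold defines.
.poly_templates <- list(
  list(subclass = "flavones",            template = "O=c1cc(-c2ccc{a}cc2)oc2cc{b}cc{c}c12"),
  list(subclass = "flavonols",           template = "O=c1c(O)c(-c2ccc{a}cc2)oc2cc{b}cc{c}c12"),
  list(subclass = "flavanones",          template = "O=C1CC(c2ccc{a}cc2)Oc2cc{b}cc{c}c12"),
  list(subclass = "isoflavonoids",       template = "O=c1c(-c2ccc{a}cc2)coc2cc{b}cc{c}c12"),
  list(subclass = "flavanols",           template = "OC1Cc2cc{b}cc{c}c2OC1c1ccc{a}cc1"),
  list(subclass = "dihydrochalcones",    template = "O=C(CCc1ccc{a}cc1)c1cc{b}cc{c}c1"),
  list(subclass = "stilbenes",           template = "C(=Cc1ccc{a}cc1)c1cc{b}cc{c}c1"),
  list(subclass = "hydroxycinnamic acids",    template = "OC(=O)C=Cc1cc{b}c(O)c{c}c1"),
  list(subclass = "hydroxybenzoic acids",     template = "OC(=O)c1cc{b}c(O)c{c}c1"),
  list(subclass = "hydroxyphenylpropanoic acids", template = "OC(=O)CCc1cc{b}c(O)c{c}c1"),
  list(subclass = "lignans",             template = "OCC(Cc1cc{a}c(O)cc1)C(CO)Cc1cc{b}c(O)cc1"),
  list(subclass = "tyrosols",            template = "OCCc1ccc(O)c{b}c1"),
  list(subclass = "methoxyphenols",      template = "COc1cc{a}ccc1O"),
  list(subclass = "hydroxycoumarins",    template = "O=c1ccc2cc{a}cc{b}c2o1")
)

.nitrogen_decoys <- c(
  "Cn1c(=O)c2c(ncn2C)n(C)c1=O",        # caffeine-like xanthine
  "CN1CCCC1c1cccnc1",                  # nicotine-like pyridine alkaloid
  "c1ccc2ncccc2c1",                    # quinoline
  "OC(=O)Cc1c[nH]c2ccccc12",           # indole acetic acid
  "CCCCCC1CCCCN1"                      # piperidine alkaloid
)
.steroid_decoys <- c(
  "CC(C)CCCC(C)C1CCC2C3CC=C4CC(O)CCC4(C)C3CCC12C",  # cholesterol (flat)
  "CC12CCC(=O)C=C1CCC1C2CCC2(C)C1CCC2O",            # testosterone (flat)
  "CC12CCC3c4ccc(O)cc4CCC3C1CCC2O"                  # estradiol (flat)
)
.plain_decoys <- c(
  "CCCCCC",                            # hexane
  "CCCCCCCCCCCCCCCCCC(=O)O",           # stearic acid
  "OC1OC(CO)C(O)C(O)C1O"               # a hexose
)

# Linear polyether chain of n oxyethylene units; n >= 28 exceeds 1200 Da.
# Acyclic on purpose: ring-dense macromolecules make canonicalization
# needlessly slow without adding anything to the mass-exclusion test.
polyether_smiles <- function(n) {
  paste0("C", strrep("OCC", n), "O")
}

fill_template <- function(template, slots) {
  for (s in names(slots)) {
    template <- gsub(paste0("{", s, "}"), slots[[s]], template, fixed = TRUE)
  }
  template
}

#' Generate a synthetic natural-product library
#'
#' Polyphenols are built by decorating class scaffolds (flavone, isoflavone,
#' stilbene, hydroxycinnamic acid, lignan, tyrosol, ...) with random
#' O-substituents (hydroxy, methoxy, glucosyl). Decoys cover the three
#' exclusion rules (nitrogen heterocycles, steroid cores, > 1200 Da chain
#' constructs) plus plain non-phenolic compounds.
#'
#' @param n library size (>= 1).
#' @param polyphenol_fraction fraction of true polyphenols in `[0, 1]`.
#' @param seed integer seed.
#' @param path optional path; when given the library is written as a SMILES
#'   file.
#' @return list with `compounds` (data.frame `compound_id`, `smiles`) and
#'   `ledger` (list: `planted_polyphenols` id -> intended subclass, `decoys`
#'   id -> intended exclusion reason, `"none"` for plain decoys).
#' @export
gen_compound_library <- function(n, polyphenol_fraction = 0.8, seed = 1L,
                                 path = NULL) {
  if (n < 1) stop("parameter error: n must be >= 1", call. = FALSE)
  if (polyphenol_fraction < 0 || polyphenol_fraction > 1) {
    stop("parameter error: polyphenol_fraction must lie in [0, 1]",
         call. = FALSE)
  }
  withr_seed(derive_seed(seed, "compounds"), {
    n_poly <- round(n * polyphenol_fraction)
    n_decoy <- n - n_poly
    poly <- lapply(seq_len(n_poly), function(i) {
      tpl <- .poly_templates[[((i - 1) %% length(.poly_templates)) + 1]]
      slots <- list(
        a = sample(.decorations, 1, prob = .decoration_p),
        b = sample(.decorations, 1, prob = .decoration_p),
        c = sample(.decorations, 1, prob = .decoration_p)
      )
      list(id = sprintf("pp_%04d", i),
           smiles = fill_template(tpl$template, slots),
           subclass = tpl$subclass)
    })
    decoy_kind <- rep(c("nitrogen", "steroid", "highmass", "plain"),
                      length.out = n_decoy)
    decoys <- lapply(seq_len(n_decoy), function(i) {
      kind <- decoy_kind[i]
      smi <- switch(kind,
        nitrogen = .nitrogen_decoys[((i - 1) %% length(.nitrogen_decoys)) + 1],
        steroid  = .steroid_decoys[((i - 1) %% length(.steroid_decoys)) + 1],
        highmass = polyether_smiles(28 + (i %% 3)),
        plain    = .plain_decoys[((i - 1) %% length(.plain_decoys)) + 1])
      reason <- switch(kind, nitrogen = "contains_nitrogen",
                       steroid = "steroid", highmass = "mass_gt_1200",
                       plain = "none")
      list(id = sprintf("dk_%04d", i), smiles = smi, reason = reason)
    })
    compounds <- data.frame(
      compound_id = c(vapply(poly, `[[`, character(1), "id"),
                      vapply(decoys, `[[`, character(1), "id")),
      smiles = c(vapply(poly, `[[`, character(1), "smiles"),
                 vapply(decoys, `[[`, character(1), "smiles")),
      stringsAsFactors = FALSE
    )
    # named lists, not named vectors: jsonlite keeps names only for lists
    ledger <- list(
      seed = seed,
      planted_polyphenols = as.list(stats::setNames(
        vapply(poly, `[[`, character(1), "subclass"),
        vapply(poly, `[[`, character(1), "id"))),
      decoys = as.list(stats::setNames(
        vapply(decoys, `[[`, character(1), "reason"),
        vapply(decoys, `[[`, character(1), "id")))
    )
    if (!is.null(path)) write_smiles_file(compounds, path)
    list(compounds = compounds, ledger = ledger)
  })
}

## ---- interaction databases ------------------------------------------------

.source_names <- c("bindingdb_like", "pathway_commons_like", "stitch_like")

# All non-empty source combinations, keyed as in source_overlap().
source_combos <- function() {
  combos <- unlist(lapply(1:3, function(k) {
    utils::combn(.source_names, k, paste, collapse = ";", simplify = FALSE)
  }))
  sort(combos)
}

#' Generate three synthetic interaction-table dialects
#'
#' Nodes are partitioned into source-combination cells (the planted
#' source-overlap structure); one filter-surviving "anchor" edge per node and
#' source guarantees the partition, and further STITCH-like records add
#' realistic evidence-channel structure, including a known fraction of
#' text-mining-only records and a planted hub compound of maximal degree.
#' Channel scores are sampled in [0.15, 0.999].
#'
#' @param compound_ids compounds available for wiring (non-empty).
#' @param n_proteins number of proteins (ids `P0001`...).
#' @param seed integer seed.
#' @param n_extra additional random STITCH-like records.
#' @param textmining_only_rate fraction of the extra records supported only
#'   by text mining.
#' @param compound_cells,protein_cells named integer vectors over the 7
#'   source combinations (names as in [source_overlap()]); defaults assign
#'   every node, mostly to single-source cells. Totals must not exceed the
#'   node pools.
#' @param dir optional output directory; when given, writes
#'   `stitch.tsv`, `interactions.sif`, `bindingdb.tsv`.
#' @return list with `stitch`, `sif`, `bindingdb` record data.frames (as the
#'   parsers return them), `files` (paths or NULL) and `ledger` (cell counts,
#'   text-mining-only count, hub id, record counts).
#' @export
gen_interaction_db <- function(compound_ids, n_proteins = 60, seed = 1L,
                               n_extra = 400, textmining_only_rate = 0.15,
                               compound_cells = NULL, protein_cells = NULL,
                               dir = NULL) {
  if (length(compound_ids) == 0) {
    stop("parameter error: compound_ids must be non-empty", call. = FALSE)
  }
  combos <- source_combos()
  default_cells <- function(total) {
    # mostly single-source, some pairwise, a small all-three core
    w <- stats::setNames(rep(0, length(combos)), combos)
    single <- combos[!grepl(";", combos)]
    pairs <- combos[lengths(strsplit(combos, ";")) == 2]
    all3 <- combos[lengths(strsplit(combos, ";")) == 3]
    w[single] <- 0.24; w[pairs] <- 0.06; w[all3] <- 0.10
    cells <- floor(w * total)
    cells[single[1]] <- cells[single[1]] + (total - sum(cells))
    cells
  }
  if (is.null(compound_cells)) compound_cells <- default_cells(length(compound_ids))
  if (is.null(protein_cells)) protein_cells <- default_cells(n_proteins)
  if (sum(compound_cells) > length(compound_ids)) {
    stop("parameter error: compound cells exceed the compound pool",
         call. = FALSE)
  }
  if (sum(protein_cells) > n_proteins) {
    stop("parameter error: protein cells exceed the protein pool",
         call. = FALSE)
  }
  withr_seed(derive_seed(seed, "interactions"), {
    proteins <- sprintf("P%04d", seq_len(n_proteins))
    assign_cells <- function(pool, cells) {
      pool <- sample(pool)
      out <- list(); at <- 1
      for (cb in names(cells)) {
        k <- cells[[cb]]
        out[[cb]] <- if (k > 0) pool[at:(at + k - 1)] else character(0)
        at <- at + k
      }
      out
    }
    c_cells <- assign_cells(compound_ids, compound_cells)
    p_cells <- assign_cells(proteins, protein_cells)
    in_source <- function(cells, src) {
      unlist(cells[vapply(names(cells),
                          function(cb) src %in% strsplit(cb, ";")[[1]],
                          logical(1))], use.names = FALSE)
    }
    stitch <- list(); sif <- list(); bdb <- list()
    add_stitch <- function(cpd, prt, channels, lst) {
      c(lst, list(data.frame(
        compound_id = cpd, protein_id = prt,
        experimental = channels[1], database = channels[2],
        prediction = channels[3], textmining = channels[4],
        combined_score = channels[5], stringsAsFactors = FALSE)))
    }
    anchor_channels <- function() {
      e <- stats::runif(1, 0.90, 0.999)
      c(round(e, 3), 0, 0, 0, round(e, 3))
    }
    # anchor edges: every node touched by every source of its cell
    for (src in .source_names) {
      cs <- in_source(c_cells, src); ps <- in_source(p_cells, src)
      if (length(cs) == 0 || length(ps) == 0) next
      for (cpd in cs) {
        prt <- sample(ps, 1)
        if (src == "stitch_like") stitch <- add_stitch(cpd, prt, anchor_channels(), stitch)
        else if (src == "pathway_commons_like") sif <- c(sif, list(c(cpd, prt)))
        else bdb <- c(bdb, list(c(cpd, prt)))
      }
      for (prt in ps) {
        cpd <- sample(cs, 1)
        if (src == "stitch_like") stitch <- add_stitch(cpd, prt, anchor_channels(), stitch)
        else if (src == "pathway_commons_like") sif <- c(sif, list(c(cpd, prt)))
        else bdb <- c(bdb, list(c(cpd, prt)))
      }
    }
    # extra stitch records with realistic channel structure
    st_c <- in_source(c_cells, "stitch_like")
    st_p <- in_source(p_cells, "stitch_like")
    n_tm_only <- 0L
    if (n_extra > 0 && length(st_c) && length(st_p)) {
      for (i in seq_len(n_extra)) {
        cpd <- sample(st_c, 1); prt <- sample(st_p, 1)
        if (stats::runif(1) < textmining_only_rate) {
          tm <- round(stats::runif(1, 0.15, 0.999), 3)
          stitch <- add_stitch(cpd, prt, c(0, 0, 0, tm, tm), stitch)
          n_tm_only <- n_tm_only + 1L
        } else {
          present <- stats::runif(3) < c(0.6, 0.5, 0.4)
          if (!any(present)) present[1] <- TRUE
          ch <- ifelse(present, round(stats::runif(3, 0.15, 0.999), 3), 0)
          tm <- if (stats::runif(1) < 0.3) round(stats::runif(1, 0.15, 0.999), 3) else 0
          comb <- round(min(0.999, 1 - prod(1 - c(ch, tm))), 3)
          stitch <- add_stitch(cpd, prt, c(ch, tm, comb), stitch)
        }
      }
    }
    # planted hub: an all-source compound wired to every protein through a
    # source that protein's cell allows. Its deduplicated degree is the full
    # protein pool, strictly above any cell-restricted compound.
    hub <- NULL
    all3 <- paste(sort(.source_names), collapse = ";")
    if (length(c_cells[[all3]])) {
      hub <- c_cells[[all3]][1]
      for (cb in names(p_cells)) {
        src <- strsplit(cb, ";")[[1]][1]
        for (prt in p_cells[[cb]]) {
          if (src == "stitch_like") {
            stitch <- add_stitch(hub, prt, anchor_channels(), stitch)
          } else if (src == "pathway_commons_like") {
            sif <- c(sif, list(c(hub, prt)))
          } else {
            bdb <- c(bdb, list(c(hub, prt)))
          }
        }
      }
    } else if (length(st_c) && length(st_p)) {
      hub <- st_c[1]
      for (prt in st_p) stitch <- add_stitch(hub, prt, anchor_channels(), stitch)
    }
    stitch_df <- do.call(rbind, stitch)
    sif_df <- if (length(sif)) data.frame(
      compound_id = vapply(sif, `[`, character(1), 1),
      relation = "interacts-with",
      protein_id = vapply(sif, `[`, character(1), 2),
      stringsAsFactors = FALSE) else NULL
    bdb_df <- if (length(bdb)) data.frame(
      compound_id = vapply(bdb, `[`, character(1), 1),
      protein_id = vapply(bdb, `[`, character(1), 2),
      affinity_nM = round(stats::rlnorm(length(bdb), 4, 1.5), 2),
      stringsAsFactors = FALSE) else NULL
    files <- NULL
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      raw <- stitch_df
      for (cc in c(.channels, "combined_score")) {
        raw[[cc]] <- as.integer(pmin(999, round(raw[[cc]] * 1000)))
      }
      files <- list(
        stitch = file.path(dir, "stitch.tsv"),
        sif = file.path(dir, "interactions.sif"),
        bindingdb = file.path(dir, "bindingdb.tsv")
      )
      utils::write.table(raw, files$stitch, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      writeLines(if (is.null(sif_df)) character(0) else
        paste(sif_df$compound_id, sif_df$relation, sif_df$protein_id,
              sep = "\t"), files$sif)
      utils::write.table(
        if (is.null(bdb_df)) data.frame(compound_id = character(0),
                                        protein_id = character(0),
                                        affinity_nM = numeric(0))
        else bdb_df,
        files$bindingdb, sep = "\t", quote = FALSE, row.names = FALSE)
    }
    cell_count <- function(cells) {
      out <- lengths(cells)
      out[out > 0]
    }
    to_records <- function(df, src) {
      if (is.null(df)) return(empty_records())
      out <- empty_records()[rep(1, nrow(df)), ]
      rownames(out) <- NULL
      out$compound_id <- df$compound_id
      out$protein_id <- toupper(df$protein_id)
      out$source_db <- src
      if (src == "stitch_like") {
        for (cc in c(.channels, "combined_score")) out[[cc]] <- df[[cc]]
      }
      if (src == "bindingdb_like") out$affinity_nM <- df$affinity_nM
      out
    }
    list(
      stitch = to_records(stitch_df, "stitch_like"),
      sif = to_records(sif_df, "pathway_commons_like"),
      bindingdb = to_records(bdb_df, "bindingdb_like"),
      files = files,
      ledger = list(
        seed = seed,
        compound_cells = as.list(cell_count(c_cells)),
        protein_cells = as.list(cell_count(p_cells)),
        n_textmining_only = n_tm_only,
        hub_compound = hub,
        n_stitch_records = nrow(stitch_df),
        n_sif_records = if (is.null(sif_df)) 0L else nrow(sif_df),
        n_bindingdb_records = if (is.null(bdb_df)) 0L else nrow(bdb_df)
      )
    )
  })
}

## ---- pathway collections ---------------------------------------------------

.category_pool <- list(
  "Metabolism" = c("Carbohydrate metabolism", "Lipid metabolism",
                   "Amino acid metabolism"),
  "Human Diseases" = c("Cardiovascular Diseases",
                       "Endocrine and Metabolic Diseases",
                       "Infectious Diseases"),
  "Genetic Information Processing" = c("Translation", "Transcription"),
  "Environmental Information Processing" = c("Signal transduction"),
  "Cellular Processes" = c("Cell growth and death"),
  "Organismal Systems" = c("Digestive system")
)

#' Generate a synthetic pathway collection (GMT + ontology)
#'
#' Pathway members are drawn uniformly from the universe, except for planted
#' pathways whose members are over-sampled from a designated query set at a
#' given odds ratio. Categories and subcategories are assigned round-robin
#' from a fixed ontology pool.
#'
#' @param universe protein universe (character vector).
#' @param n_pathways number of pathways.
#' @param size_range inclusive range of pathway sizes.
#' @param n_categories number of top-level categories used (2-6).
#' @param planted optional data.frame with columns `query_label`,
#'   `pathway_id` (e.g. `"pw_0003"`), `odds_ratio`, `size` (optional); the
#'   matching entry of `query_sets` supplies the query proteins.
#' @param query_sets named list of protein vectors referenced by `planted`.
#' @param seed integer seed.
#' @param dir optional output directory (writes `pathways.gmt`,
#'   `ontology.tsv`).
#' @return list with `gene_sets`, `ontology`, `files`, `ledger`.
#' @export
gen_pathway_collection <- function(universe, n_pathways = 20,
                                   size_range = c(10, 60), n_categories = 3,
                                   planted = NULL, query_sets = NULL,
                                   seed = 1L, dir = NULL) {
  if (max(size_range) > length(universe)) {
    stop("parameter error: pathway size exceeds universe", call. = FALSE)
  }
  if (!is.null(planted)) {
    bad <- setdiff(planted$query_label, names(query_sets))
    if (length(bad)) {
      stop("parameter error: planted query label(s) without query set: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  withr_seed(derive_seed(seed, "pathways"), {
    ids <- sprintf("pw_%04d", seq_len(n_pathways))
    cats <- names(.category_pool)[seq_len(min(n_categories, length(.category_pool)))]
    ontology <- data.frame(
      pathway_id = ids,
      category = rep(cats, length.out = n_pathways),
      stringsAsFactors = FALSE
    )
    ontology$subcategory <- vapply(seq_len(n_pathways), function(i) {
      subs <- .category_pool[[ontology$category[i]]]
      subs[((i - 1) %/% length(cats)) %% length(subs) + 1]
    }, character(1))
    sizes <- sample(seq(size_range[1], size_range[2]), n_pathways,
                    replace = TRUE)
    gene_sets <- vector("list", n_pathways)
    names(gene_sets) <- ids
    for (i in seq_len(n_pathways)) {
      pl <- if (!is.null(planted)) planted[planted$pathway_id == ids[i], ] else NULL
      if (!is.null(pl) && nrow(pl) == 1) {
        q <- unique(toupper(query_sets[[pl$query_label]]))
        sz <- if (!is.null(pl$size) && !is.na(pl$size)) pl$size else sizes[i]
        w <- ifelse(universe %in% q, pl$odds_ratio, 1)
        gene_sets[[i]] <- sort(sample(universe, sz, prob = w))
      } else {
        gene_sets[[i]] <- sort(sample(universe, sizes[i]))
      }
    }
    files <- NULL
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      files <- list(gmt = file.path(dir, "pathways.gmt"),
                    ontology = file.path(dir, "ontology.tsv"))
      write_gmt(gene_sets, files$gmt)
      utils::write.table(ontology, files$ontology, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }
    list(gene_sets = gene_sets, ontology = ontology, files = files,
         ledger = list(seed = seed,
                       planted_enrichments = planted,
                       n_pathways = n_pathways))
  })
}

## ---- food composition ------------------------------------------------------

#' Generate a synthetic food composition table with exact overlaps
#'
#' Every food contains a shared core of `n_shared` compounds plus its own
#' private compounds; foods listed in `supersets` additionally contain every
#' compound used by any food (the "contains almost all polyphenols" motif).
#' Pairwise Jaccard overlaps are therefore realized exactly and recorded in
#' the ledger.
#'
#' @param compounds pool of compound ids to draw from.
#' @param n_private named integer vector: food name -> number of private
#'   compounds.
#' @param n_shared size of the shared core.
#' @param supersets foods that receive the full compound union.
#' @param force_members optional named list food -> compound ids that must be
#'   present in that food (e.g. to wire a planted hub compound into a food).
#' @param seed integer seed.
#' @param path optional output TSV path.
#' @return list with `table` (data.frame `food`, `compound_id`), `file`,
#'   `ledger` (realized Jaccard matrix and per-food sizes).
#' @export
gen_food_table <- function(compounds, n_private, n_shared = 5,
                           supersets = character(0),
                           force_members = list(), seed = 1L, path = NULL) {
  need <- n_shared + sum(n_private)
  if (need > length(compounds)) {
    stop("parameter error: overlap spec needs ", need,
         " compounds but only ", length(compounds), " available",
         call. = FALSE)
  }
  if (!all(supersets %in% names(n_private))) {
    stop("parameter error: supersets must name foods in n_private",
         call. = FALSE)
  }
  withr_seed(derive_seed(seed, "foods"), {
    pool <- sample(compounds, need)
    shared <- if (n_shared > 0) pool[seq_len(n_shared)] else character(0)
    at <- n_shared
    sets <- list()
    for (f in names(n_private)) {
      k <- n_private[[f]]
      priv <- if (k > 0) pool[(at + 1):(at + k)] else character(0)
      at <- at + k
      sets[[f]] <- sort(unique(c(shared, priv)))
    }
    for (f in names(force_members)) {
      sets[[f]] <- sort(unique(c(sets[[f]], force_members[[f]])))
    }
    pool_all <- sort(unique(c(pool, unlist(force_members))))
    for (f in supersets) sets[[f]] <- pool_all
    tab <- do.call(rbind, lapply(names(sets), function(f) {
      data.frame(food = f, compound_id = sets[[f]], stringsAsFactors = FALSE)
    }))
    foods <- names(sets)
    jac <- matrix(1, length(foods), length(foods),
                  dimnames = list(foods, foods))
    for (i in seq_along(foods)) for (j in seq_along(foods)) {
      if (i == j) next
      u <- length(union(sets[[i]], sets[[j]]))
      jac[i, j] <- length(intersect(sets[[i]], sets[[j]])) / u
    }
    if (!is.null(path)) {
      utils::write.table(tab, path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }
    list(table = tab, file = path,
         ledger = list(seed = seed, jaccard = jac,
                       sizes = lengths(sets)))
  })
}

## ---- one-call emission -----------------------------------------------------

#' Emit every synthetic input the pipeline consumes
#'
#' Generates the compound library, the three interaction dialects, the
#' pathway collection (with one pathway planted for the flavonoid class) and
#' the food table, and writes them with a consolidated `ledger.json` under
#' `out_dir`.
#'
#' @param out_dir output directory (created).
#' @param seed integer master seed.
#' @param n_compounds,polyphenol_fraction,n_proteins,n_extra,n_pathways
#'   scale parameters (defaults sized to run the full pipeline in seconds).
#' @return invisible list of generator outputs plus the consolidated ledger.
#' @export
simulate_all <- function(out_dir, seed = 42L, n_compounds = 120,
                         polyphenol_fraction = 0.75, n_proteins = 300,
                         n_extra = 400, n_pathways = 20) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  lib <- gen_compound_library(n_compounds, polyphenol_fraction, seed,
                              path = file.path(out_dir, "compounds.smi"))
  std <- standardize(lib$compounds$smiles, lib$compounds$compound_id)
  classified <- classify_batch(std)
  idb <- gen_interaction_db(
    classified$compound_id[!classified$excluded & nzchar(classified$classes)],
    n_proteins = n_proteins, seed = seed, n_extra = n_extra, dir = out_dir)
  net <- merge_interactions(
    filter_interactions(idb$stitch), idb$sif, idb$bindingdb)
  # plant the class-level pathway for a class the hub does not carry: the
  # hub interacts with the whole protein pool, so its own class's query
  # saturates the universe and cannot be over-represented
  hub <- idb$ledger$hub_compound
  hub_classes <- strsplit(classified$classes[classified$compound_id == hub],
                          ";")[[1]]
  # food-level plant: anchor on the busiest non-hub compound, whose
  # interactor set is large but far from the whole universe
  deg <- table(net$edges$compound_id)
  nonhub <- setdiff(names(deg), hub)
  anchor <- nonhub[which.max(deg[nonhub])]
  anchor_prot <- unique(net$edges$protein_id[net$edges$compound_id == anchor])
  class_query <- function(cl) {
    cpds <- classified$compound_id[grepl(cl, classified$classes, fixed = TRUE)]
    unique(net$edges$protein_id[net$edges$compound_id %in% cpds])
  }
  prefs <- setdiff(c("flavonoids", "phenolic acids", "other polyphenols",
                     "stilbenes", "lignans"), hub_classes)
  target_class <- prefs[vapply(prefs, function(cl) length(class_query(cl)) > 0,
                               logical(1))][1]
  universe <- sprintf("P%04d", seq_len(n_proteins))
  planted <- data.frame(
    query_label = c(target_class, "anchor_interactors"),
    pathway_id = c("pw_0001", "pw_0002"),
    odds_ratio = c(8, 8),
    size = c(min(40, n_proteins %/% 2), min(30, n_proteins %/% 3)),
    stringsAsFactors = FALSE)
  query_sets <- list(class_query(target_class), anchor_prot)
  names(query_sets) <- c(target_class, "anchor_interactors")
  pw <- gen_pathway_collection(universe, n_pathways = n_pathways,
                               size_range = c(5, max(6, n_proteins %/% 3)),
                               n_categories = 3, planted = planted,
                               query_sets = query_sets,
                               seed = seed, dir = out_dir)
  citrus <- c(grapefruit = 4, lemon = 2, lime = 2, orange = 4,
              tangerine = 3, pomelo = 3)
  ft <- gen_food_table(net$compounds, n_private = citrus, n_shared = 4,
                       supersets = c("lemon", "lime"),
                       force_members = list(grapefruit = anchor), seed = seed,
                       path = file.path(out_dir, "foods.tsv"))
  ledger <- list(
    seed = seed,
    compounds = lib$ledger,
    interactions = idb$ledger,
    pathways = pw$ledger,
    foods = ft$ledger["sizes"],
    food_anchor = list(compound = anchor, food = "grapefruit")
  )
  jsonlite::write_json(ledger, file.path(out_dir, "ledger.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(library = lib, interactions = idb, pathways = pw,
                 foods = ft, ledger = ledger))
}
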