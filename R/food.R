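## Food-level analysis: composition tables, per-food sub-interactomes,
## per-compound enrichment networks (with the stricter coverage > 0.2
## criterion), and food-to-food comparison.

#' Read a food composition table
#'
#' Presence is binary: a listed compound is part of the food irrespective of
#' concentration.
#'
#' @param path TSV with columns `food`, `compound_id`.
#' @return data.frame.
#' @export
read_food_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("food", "compound_id") %in% names(tab))) {
    stop("format error in ", path, ": need columns food, compound_id",
         call. = FALSE)
  }
  unique(tab[, c("food", "compound_id")])
}

#' Resolve composition entries against a classified compound table
#'
#' Resolution is by exact compound id first, then by canonical-key match of
#' the entry name interpreted as SMILES. Unresolved names are reported via a
#' warning and returned in the `unresolved` attribute, never silently
#' dropped.
#'
#' @param food_table data.frame from [read_food_table()].
#' @param std standardized compound table ([standardize()]).
#' @return `food_table` with an added `resolved_id` column (NA when
#'   unresolved); unresolved names in `attr(, "unresolved")`.
#' @export
resolve_food_compounds <- function(food_table, std) {
  resolved <- ifelse(food_table$compound_id %in% std$compound_id,
                     food_table$compound_id, NA_character_)
  todo <- which(is.na(resolved) & smiles_valid(food_table$compound_id))
  if (length(todo)) {
    keys <- canonical_key(std$canonical_smiles, strict_stereo = TRUE)
    for (i in todo) {
      k <- tryCatch(canonical_key(standardize(food_table$compound_id[i])$canonical_smiles),
                    error = function(e) NA_character_)
      hit <- match(k, keys)
      if (!is.na(hit)) resolved[i] <- std$compound_id[hit]
    }
  }
  if (anyNA(resolved)) {
    warning("unresolved composition entries: ",
            paste(unique(food_table$compound_id[is.na(resolved)]),
                  collapse = ", "), call. = FALSE)
  }
  food_table$resolved_id <- resolved
  attr(food_table, "unresolved") <- unique(food_table$compound_id[is.na(resolved)])
  food_table
}

food_compound_set <- function(food_table, food) {
  if (!food %in% food_table$food) {
    stop("unknown food: ", food, call. = FALSE)
  }
  col <- if ("resolved_id" %in% names(food_table)) "resolved_id" else "compound_id"
  ids <- food_table[[col]][food_table$food == food]
  sort(unique(ids[!is.na(ids)]))
}

#' Sub-interactome induced by one food's compounds
#'
#' @param food food name present in `food_table`.
#' @param food_table data.frame from [read_food_table()].
#' @param interactome an [merge_interactions()] object.
#' @return list with `food`, `compounds` (those present in the interactome),
#'   `proteins` (their neighbours) and `edges` (induced edge table). A food
#'   with no compounds in the interactome yields empty sets (logged).
#' @export
food_interactome <- function(food, food_table, interactome) {
  cpds <- food_compound_set(food_table, food)
  edges <- interactome$edges[interactome$edges$compound_id %in% cpds, ,
                             drop = FALSE]
  rownames(edges) <- NULL
  if (nrow(edges) == 0) {
    message("food '", food, "' has no compounds in the interactome")
  }
  list(food = food,
       compounds = sort(unique(edges$compound_id)),
       proteins = sort(unique(edges$protein_id)),
       edges = edges)
}

#' Per-compound enrichment network for one food
#'
#' Enrichment is run individually for each of the food's compounds (never
#' pooled), against the shared universe. An edge compound -> pathway is drawn
#' exactly when that compound's interactors are significantly enriched in the
#' pathway under the food-level thresholds (BH p < `alpha`, coverage >
#' `min_coverage`, default 0.2).
#'
#' @param food food name.
#' @param food_table composition table.
#' @param interactome an [merge_interactions()] object.
#' @param gene_sets named list of pathway member vectors.
#' @param ontology pathway ontology ([read_pathway_ontology()]).
#' @param universe optional background (default: union of gene-set members).
#' @param alpha,min_coverage thresholds (defaults 0.1 and 0.2).
#' @return object of class `food_network`: list with `food`, `edges`
#'   (compound_id, pathway_id, category, p_bh, coverage), `compounds` (all
#'   food compounds in the interactome, including isolated ones), `pathways`
#'   (with categories), `proteins_by_category` (hit proteins per pathway
#'   category) and `results` (the full per-compound enrichment table).
#' @export
food_enrichment_network <- function(food, food_table, interactome, gene_sets,
                                    ontology, universe = NULL, alpha = 0.1,
                                    min_coverage = 0.2) {
  fi <- food_interactome(food, food_table, interactome)
  results <- lapply(fi$compounds, function(cpd) {
    prots <- unique(fi$edges$protein_id[fi$edges$compound_id == cpd])
    enrich(prots, gene_sets, universe, alpha, min_coverage, query_label = cpd)
  })
  results <- if (length(results)) do.call(rbind, results) else
    enrich(character(0), gene_sets, universe, alpha, min_coverage)[0, ]
  sig <- results[results$significant, , drop = FALSE]
  idx <- match(sig$pathway_id, ontology$pathway_id)
  if (anyNA(idx)) {
    stop("validation error: unmapped pathway id(s): ",
         paste(unique(sig$pathway_id[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  }
  edges <- data.frame(
    compound_id = sig$query_label, pathway_id = sig$pathway_id,
    category = ontology$category[idx], p_bh = sig$p_bh,
    coverage = sig$coverage, stringsAsFactors = FALSE
  )
  rownames(edges) <- NULL
  pathways <- unique(edges[, c("pathway_id", "category")])
  proteins_by_category <- lapply(split(sig$hits, ontology$category[idx]),
                                 function(h) sort(unique(unlist(strsplit(h, ";", fixed = TRUE)))))
  structure(list(food = food, edges = edges,
                 compounds = fi$compounds, pathways = pathways,
                 proteins_by_category = proteins_by_category,
                 results = results),
            class = "food_network")
}

#' @export
print.food_network <- function(x, ...) {
  cat("food_network for", x$food, "-", length(x$compounds), "compounds,",
      nrow(x$edges), "significant compound-pathway edges\n")
  invisible(x)
}

#' Export a food enrichment network as GraphML
#'
#' Tripartite layout: compound and pathway nodes joined by significant
#' enrichment edges; pathway nodes carry their category.
#'
#' @param network a [food_enrichment_network()] object.
#' @param path output path.
#' @export
write_food_network_graphml <- function(network, path) {
  nodes <- data.frame(
    name = c(network$compounds, network$pathways$pathway_id),
    type = c(rep("compound", length(network$compounds)),
             rep("pathway", nrow(network$pathways))),
    category = c(rep("", length(network$compounds)),
                 network$pathways$category),
    stringsAsFactors = FALSE
  )
  g <- igraph::graph_from_data_frame(
    network$edges[, c("compound_id", "pathway_id")],
    directed = FALSE, vertices = nodes
  )
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Compare foods by composition overlap and enrichment
#'
#' @param food_table composition table.
#' @param foods foods to compare (default: all; at least 2). Unknown names
#'   are an error.
#' @param interactome,gene_sets,ontology optional; when all are supplied, a
#'   per-food significant-pathway list is computed with
#'   [food_enrichment_network()].
#' @param ... further arguments passed to [food_enrichment_network()].
#' @return list with `jaccard` (pairwise Jaccard matrix of compound sets) and
#'   `pathways` (named list of significant pathway ids per food, or `NULL`).
#' @export
compare_foods <- function(food_table, foods = NULL, interactome = NULL,
                          gene_sets = NULL, ontology = NULL, ...) {
  if (is.null(foods)) foods <- sort(unique(food_table$food))
  if (length(foods) < 2) stop("need at least two foods", call. = FALSE)
  sets <- lapply(foods, function(f) food_compound_set(food_table, f))
  names(sets) <- foods
  jac <- matrix(1, length(foods), length(foods),
                dimnames = list(foods, foods))
  for (i in seq_along(foods)) for (j in seq_along(foods)) {
    if (i == j) next
    u <- length(union(sets[[i]], sets[[j]]))
    jac[i, j] <- if (u == 0) 0 else length(intersect(sets[[i]], sets[[j]])) / u
  }
  pathways <- NULL
  if (!is.null(interactome) && !is.null(gene_sets) && !is.null(ontology)) {
    pathways <- lapply(foods, function(f) {
      net <- food_enrichment_network(f, food_table, interactome, gene_sets,
                                     ontology, ...)
      sort(unique(net$edges$pathway_id))
    })
    names(pathways) <- foods
  }
  list(jaccard = jac, pathways = pathways)
}
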