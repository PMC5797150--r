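## Hypergeometric over-representation analysis of interacting-protein sets
## against pathway gene sets, with Benjamini-Hochberg control, the pathway
## coverage criterion, and category roll-ups.

#' Exact upper-tail hypergeometric p-value
#'
#' Probability of observing `k` or more query hits in a pathway of size `K`,
#' for a query of size `n` drawn from a universe of size `N`. Computed exactly
#' from log-binomial coefficients (no normal approximation).
#'
#' @param k observed hits.
#' @param K pathway size.
#' @param n query size.
#' @param N universe size.
#' @return the p-value `P[X >= k]`.
#' @export
hypergeometric_p <- function(k, K, n, N) {
  stopifnot(length(k) == 1, length(K) == 1, length(n) == 1, length(N) == 1)
  if (any(c(k, K, n, N) < 0) || K > N || n > N || k > min(K, n)) {
    stop("parameter error: need 0 <= k <= min(K, n) and K, n <= N",
         call. = FALSE)
  }
  if (k == 0) return(1)
  i <- k:min(K, n)
  terms <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  min(1, sum(exp(terms)))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment; output order matches input order.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("parameter error: p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file: one tab-separated line per set
#'   (`id`, `description`, members...).
#' @return named list of character vectors; descriptions kept as the
#'   `description` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) < 3)
  if (length(bad)) {
    stop("format error in ", path, ": GMT lines need id, description and at ",
         "least one member; offending line(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  sets <- lapply(parts, function(p) unique(toupper(p[-(1:2)])))
  names(sets) <- vapply(parts, `[`, character(1), 1)
  attr(sets, "description") <- stats::setNames(
    vapply(parts, `[`, character(1), 2), names(sets))
  sets
}

#' Write gene sets to a GMT file
#' @param sets named list of member vectors.
#' @param path output path.
#' @param description optional named descriptions (defaults to the set ids).
#' @export
write_gmt <- function(sets, path, description = NULL) {
  if (is.null(description)) description <- stats::setNames(names(sets), names(sets))
  lines <- vapply(names(sets), function(id) {
    paste(c(id, description[[id]], sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a pathway ontology table
#' @param path TSV with columns `pathway_id`, `category`, `subcategory`.
#' @return data.frame.
#' @export
read_pathway_ontology <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("pathway_id", "category", "subcategory")
  if (!all(need %in% names(tab))) {
    stop("format error in ", path, ": need columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  tab[, need]
}

#' Over-representation analysis of one protein query set
#'
#' Tests every gene set with the exact hypergeometric upper tail, adjusts over
#' the full tested family with Benjamini-Hochberg, and flags significance by
#' the dual criterion: adjusted p strictly below `alpha` and pathway coverage
#' `k/K` strictly above `min_coverage`.
#'
#' @param query_proteins character vector of protein identifiers.
#' @param gene_sets named list of member vectors (see [read_gmt()]).
#' @param universe background protein universe; default `NULL` uses the union
#'   of all gene-set members.
#' @param alpha adjusted-p threshold (default 0.1).
#' @param min_coverage coverage threshold (default 0.1).
#' @param query_label label recorded in the result rows.
#' @param use_raw_p if `TRUE`, significance is judged on the raw p-value
#'   instead of the BH-adjusted one (the looser reading; default `FALSE`).
#' @return data.frame with one row per pathway: `query_label`, `pathway_id`,
#'   `k`, `K`, `n`, `N`, `coverage`, `p_raw`, `p_bh`, `significant`, `hits`
#'   (semicolon-joined).
#' @export
enrich <- function(query_proteins, gene_sets, universe = NULL,
                   alpha = 0.1, min_coverage = 0.1, query_label = "query",
                   use_raw_p = FALSE) {
  if (is.null(universe)) universe <- unique(unlist(gene_sets))
  universe <- unique(toupper(universe))
  if (length(universe) == 0) {
    stop("parameter error: empty universe", call. = FALSE)
  }
  query_proteins <- unique(toupper(query_proteins))
  dropped <- setdiff(query_proteins, universe)
  if (length(dropped)) {
    message(length(dropped), " query protein(s) outside the universe dropped")
  }
  query <- intersect(query_proteins, universe)
  n <- length(query); N <- length(universe)
  rows <- lapply(names(gene_sets), function(id) {
    members <- intersect(unique(toupper(gene_sets[[id]])), universe)
    K <- length(members)
    hits <- intersect(query, members)
    k <- length(hits)
    p <- if (K == 0) 1 else hypergeometric_p(k, K, n, N)
    data.frame(
      query_label = query_label, pathway_id = id, k = k, K = K, n = n, N = N,
      coverage = if (K == 0) 0 else k / K, p_raw = p,
      hits = paste(sort(hits), collapse = ";"), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bh <- bh_adjust(out$p_raw)
  p_crit <- if (use_raw_p) out$p_raw else out$p_bh
  out$significant <- p_crit < alpha & out$coverage > min_coverage
  out[, c("query_label", "pathway_id", "k", "K", "n", "N", "coverage",
          "p_raw", "p_bh", "significant", "hits")]
}

#' Class-wise over-representation analysis
#'
#' For each polyphenol class, the query set is the union of proteins
#' interacting with any (non-excluded) compound carrying that class label.
#' Each class is tested independently; the BH family is the set of pathways
#' tested for that class.
#'
#' @param interactome an [merge_interactions()] object.
#' @param classified output of [classify_batch()].
#' @param gene_sets named list of member vectors.
#' @param universe background universe (default: union of gene-set members).
#' @param alpha,min_coverage significance thresholds (defaults 0.1 / 0.1).
#' @param use_raw_p judge significance on raw p-values (see [enrich()]).
#' @param classes classes to test; default: every class present in
#'   `classified`. An unknown class is an error.
#' @return data.frame of [enrich()] rows, `query_label` = class name. Classes
#'   with no interacting proteins contribute no rows (logged via `message()`).
#' @export
enrich_by_class <- function(interactome, classified, gene_sets,
                            universe = NULL, alpha = 0.1, min_coverage = 0.1,
                            use_raw_p = FALSE, classes = NULL) {
  class_map <- split_multi(classified$classes, classified$compound_id)
  present <- sort(unique(unlist(class_map)))
  if (is.null(classes)) classes <- present
  unknown <- setdiff(classes, present)
  if (length(unknown)) {
    stop("class absent from classifications: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  edges <- interactome$edges
  out <- lapply(classes, function(cl) {
    cpds <- names(class_map)[vapply(class_map, function(v) cl %in% v, logical(1))]
    prots <- unique(edges$protein_id[edges$compound_id %in% cpds])
    if (length(prots) == 0) {
      message("class '", cl, "' has no interacting proteins; skipped")
      return(NULL)
    }
    enrich(prots, gene_sets, universe, alpha, min_coverage,
           query_label = cl, use_raw_p = use_raw_p)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) out <- enrich(character(0), gene_sets, universe,
                                  alpha, min_coverage)[0, ]
  rownames(out) <- NULL
  out
}

#' Category roll-up of enrichment results
#'
#' Per (query, category): the percentage of that category's pathways that are
#' significantly enriched. A cardiometabolic super-category (`CMD`) is added
#' as the union of the `Cardiovascular Diseases` and `Endocrine and Metabolic
#' Diseases` subcategories. Also returns the coverage values of significant
#' pathways keyed by subcategory.
#'
#' @param results data.frame from [enrich()] / [enrich_by_class()].
#' @param ontology data.frame from [read_pathway_ontology()]. Every pathway in
#'   `results` must be mapped.
#' @return list with `percent` (data.frame `query_label`, `category`,
#'   `n_pathways`, `n_significant`, `percent`) and `coverage` (data.frame of
#'   significant results with `category`/`subcategory` attached).
#' @export
category_summary <- function(results, ontology) {
  idx <- match(results$pathway_id, ontology$pathway_id)
  if (anyNA(idx)) {
    stop("validation error: unmapped pathway id(s): ",
         paste(unique(results$pathway_id[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  }
  results$category <- ontology$category[idx]
  results$subcategory <- ontology$subcategory[idx]
  cmd_sub <- c("Cardiovascular Diseases", "Endocrine and Metabolic Diseases")
  blocks <- rbind(
    results[, c("query_label", "pathway_id", "category", "significant")],
    within(results[results$subcategory %in% cmd_sub,
                   c("query_label", "pathway_id", "category", "significant")],
           category <- "CMD")
  )
  agg <- stats::aggregate(significant ~ query_label + category, blocks,
                          function(v) c(n = length(v), s = sum(v)))
  percent <- data.frame(
    query_label = agg$query_label, category = agg$category,
    n_pathways = agg$significant[, "n"],
    n_significant = agg$significant[, "s"],
    stringsAsFactors = FALSE
  )
  percent$percent <- 100 * percent$n_significant / percent$n_pathways
  percent <- percent[order(percent$query_label, percent$category), ]
  rownames(percent) <- NULL
  coverage <- results[results$significant,
                      c("query_label", "pathway_id", "category", "subcategory",
                        "coverage")]
  rownames(coverage) <- NULL
  list(percent = percent, coverage = coverage)
}
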