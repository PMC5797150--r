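## Compound-protein interaction tables in three dialects, the evidence /
## confidence filters, the merged bipartite interactome, and its analytics
## (source-overlap partition, degree histograms).

.channels <- c("experimental", "database", "prediction", "textmining")

empty_records <- function() {
  data.frame(
    compound_id = character(0), protein_id = character(0),
    source_db = character(0),
    experimental = numeric(0), database = numeric(0), prediction = numeric(0),
    textmining = numeric(0), combined_score = numeric(0),
    affinity_nM = numeric(0), stringsAsFactors = FALSE
  )
}

#' Parse a STITCH-like interaction TSV
#'
#' Expected header columns: `compound_id`, `protein_id`, `experimental`,
#' `database`, `prediction`, `textmining`, `combined_score`. Raw scores are
#' integers 0-999 and are scaled by 1/1000 into `[0, 1)` (so the printed 0.9
#' confidence threshold corresponds to a raw score of 900).
#'
#' @param path file path.
#' @return data.frame of interaction records (`source_db = "stitch_like"`).
#' @export
parse_stitch_like <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("compound_id", "protein_id", .channels, "combined_score")
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    stop("format error in ", path, ": missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(tab) == 0) return(empty_records())
  score_cols <- c(.channels, "combined_score")
  bad <- rep(FALSE, nrow(tab))
  for (cc in score_cols) {
    v <- suppressWarnings(as.numeric(tab[[cc]]))
    bad <- bad | is.na(v) | v < 0 | v > 999 | v != floor(v)
    tab[[cc]] <- v
  }
  if (any(bad)) {
    stop("row error in ", path, ": raw scores must be integers in 0-999; ",
         "offending line(s): ",
         paste(which(bad) + 1L, collapse = ", "), call. = FALSE)
  }
  out <- data.frame(
    compound_id = as.character(tab$compound_id),
    protein_id = toupper(as.character(tab$protein_id)),
    source_db = "stitch_like",
    experimental = tab$experimental / 1000,
    database = tab$database / 1000,
    prediction = tab$prediction / 1000,
    textmining = tab$textmining / 1000,
    combined_score = tab$combined_score / 1000,
    affinity_nM = NA_real_, stringsAsFactors = FALSE
  )
  out
}

#' Parse a Pathway-Commons-like SIF file
#'
#' Whitespace-separated triples `compound relation protein`. Records carry no
#' evidence channels or confidence score.
#'
#' @param path file path.
#' @return data.frame of interaction records (`source_db = "pathway_commons_like"`).
#' @export
parse_sif_like <- function(path) {
  lines <- trimws(readLines(path))
  keep <- nzchar(lines) & !startsWith(lines, "#")
  parts <- strsplit(lines[keep], "[ \t]+")
  nf <- vapply(parts, length, integer(1))
  if (any(nf != 3)) {
    stop("row error in ", path, ": SIF lines must have 3 fields; ",
         "offending line(s): ",
         paste(which(keep)[nf != 3], collapse = ", "), call. = FALSE)
  }
  if (length(parts) == 0) return(empty_records())
  out <- empty_records()[rep(1L, 0), ]
  out <- data.frame(
    compound_id = vapply(parts, `[`, character(1), 1),
    protein_id = toupper(vapply(parts, `[`, character(1), 3)),
    source_db = "pathway_commons_like",
    experimental = NA_real_, database = NA_real_, prediction = NA_real_,
    textmining = NA_real_, combined_score = NA_real_, affinity_nM = NA_real_,
    stringsAsFactors = FALSE
  )
  out
}

#' Parse a BindingDB-like affinity TSV
#'
#' Expected header columns: `compound_id`, `protein_id`, `affinity_nM`.
#' All records are direct binding; no affinity cutoff is applied at parse
#' time.
#'
#' @param path file path.
#' @return data.frame of interaction records (`source_db = "bindingdb_like"`).
#' @export
parse_bindingdb_like <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("compound_id", "protein_id", "affinity_nM")
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    stop("format error in ", path, ": missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(tab) == 0) return(empty_records())
  aff <- suppressWarnings(as.numeric(tab$affinity_nM))
  if (any(is.na(aff) | aff < 0)) {
    stop("row error in ", path, ": affinity_nM must be non-negative; ",
         "offending line(s): ",
         paste(which(is.na(aff) | aff < 0) + 1L, collapse = ", "),
         call. = FALSE)
  }
  data.frame(
    compound_id = as.character(tab$compound_id),
    protein_id = toupper(as.character(tab$protein_id)),
    source_db = "bindingdb_like",
    experimental = NA_real_, database = NA_real_, prediction = NA_real_,
    textmining = NA_real_, combined_score = NA_real_, affinity_nM = aff,
    stringsAsFactors = FALSE
  )
}

#' Apply the evidence and confidence filters
#'
#' A STITCH-like record is removed when it is supported solely by text mining
#' (textmining > 0 and experimental = database = prediction = 0) or when its
#' combined confidence score is below `min_score` (strict `<`). Non-scored
#' dialects (SIF, BindingDB-like) pass the score test vacuously; an optional
#' affinity ceiling can be applied to BindingDB-like records.
#'
#' @param records data.frame of parsed interaction records.
#' @param min_score confidence threshold in `[0, 1]` (default 0.9; the looser
#'   0.7 setting mirrors the micronutrient analysis).
#' @param exclude_textmining_only drop records supported only by text mining
#'   (default `TRUE`).
#' @param max_affinity_nM optional ceiling on BindingDB-like affinities
#'   (default `NULL` = off).
#' @return the surviving records, input order preserved.
#' @export
filter_interactions <- function(records, min_score = 0.9,
                                exclude_textmining_only = TRUE,
                                max_affinity_nM = NULL) {
  if (!is.numeric(min_score) || length(min_score) != 1 ||
      is.na(min_score) || min_score < 0 || min_score > 1) {
    stop("parameter error: min_score must be a single value in [0, 1]",
         call. = FALSE)
  }
  if (nrow(records) == 0) return(records)
  keep <- rep(TRUE, nrow(records))
  st <- records$source_db == "stitch_like"
  if (exclude_textmining_only) {
    tm_only <- st & records$textmining > 0 &
      records$experimental == 0 & records$database == 0 &
      records$prediction == 0
    keep <- keep & !tm_only
  }
  keep <- keep & !(st & records$combined_score < min_score)
  if (!is.null(max_affinity_nM)) {
    bdb <- records$source_db == "bindingdb_like"
    keep <- keep & !(bdb & records$affinity_nM > max_affinity_nM)
  }
  records[keep, , drop = FALSE]
}

#' Merge filtered interaction records into a bipartite interactome
#'
#' Identical (compound, protein) pairs are deduplicated; each surviving edge
#' carries the set of supporting source databases. Node sets are induced from
#' the surviving edges.
#'
#' @param ... one or more record data.frames (already filtered).
#' @param provenance optional list echoing the filter settings used.
#' @return an object of class `interactome`: list with `edges` (data.frame
#'   `compound_id`, `protein_id`, `sources`, `n_sources`), `compounds`,
#'   `proteins`, `n_records` (raw record count before deduplication) and
#'   `provenance`.
#' @export
merge_interactions <- function(..., provenance = list()) {
  records <- do.call(rbind, list(...))
  if (is.null(records) || nrow(records) == 0) {
    edges <- data.frame(compound_id = character(0), protein_id = character(0),
                        sources = character(0), n_sources = integer(0),
                        stringsAsFactors = FALSE)
    return(structure(list(edges = edges, compounds = character(0),
                          proteins = character(0), n_records = 0L,
                          provenance = provenance),
                     class = "interactome"))
  }
  key <- paste(records$compound_id, records$protein_id, sep = "\r")
  src <- split(records$source_db, key)
  srcs <- vapply(src, function(s) paste(sort(unique(s)), collapse = ";"),
                 character(1))
  uniq <- !duplicated(key)
  edges <- data.frame(
    compound_id = records$compound_id[uniq],
    protein_id = records$protein_id[uniq],
    stringsAsFactors = FALSE
  )
  edges$sources <- srcs[key[uniq]]
  edges$n_sources <- lengths(strsplit(edges$sources, ";", fixed = TRUE))
  edges <- edges[order(edges$compound_id, edges$protein_id), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(
    edges = edges,
    compounds = sort(unique(edges$compound_id)),
    proteins = sort(unique(edges$protein_id)),
    n_records = nrow(records),
    provenance = provenance
  ), class = "interactome")
}

#' @export
print.interactome <- function(x, ...) {
  cat("interactome:", length(x$compounds), "compounds,",
      length(x$proteins), "proteins,", nrow(x$edges), "edges",
      paste0("(", x$n_records, " records before deduplication)\n"))
  invisible(x)
}

#' Source-combination overlap of interactome nodes
#'
#' Partitions the compound and protein sets by the exact combination of
#' source databases supporting their edges.
#'
#' @param interactome an [merge_interactions()] object.
#' @return data.frame with columns `sources`, `compounds`, `proteins`; the
#'   cells partition the node sets (column sums equal node counts).
#' @export
source_overlap <- function(interactome) {
  edges <- interactome$edges
  node_combo <- function(ids, edge_ids) {
    per <- split(edges$sources, edge_ids)
    vapply(per, function(s) {
      paste(sort(unique(unlist(strsplit(s, ";", fixed = TRUE)))), collapse = ";")
    }, character(1))
  }
  cc <- node_combo(interactome$compounds, edges$compound_id)
  pc <- node_combo(interactome$proteins, edges$protein_id)
  combos <- sort(unique(c(cc, pc)))
  data.frame(
    sources = combos,
    compounds = vapply(combos, function(k) sum(cc == k), integer(1)),
    proteins = vapply(combos, function(k) sum(pc == k), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

# Default degree bin schemes. Labels follow the conventional presentation of
# bipartite interactome degree distributions; a value shared by two printed
# bins goes to the higher bin, except where a label is explicitly closed
# ("<= 10" on the compound side) or explicitly open (">" bins).
compound_degree_bin <- function(d) {
  if (d <= 10) "<=10" else if (d < 20) "10-20" else if (d < 50) "20-50"
  else if (d < 100) "50-100" else if (d < 500) "100-500"
  else if (d < 1000) "500-1000" else if (d <= 2000) "1000-2000" else ">2000"
}
protein_degree_bin <- function(d) {
  if (d == 1) "1" else if (d < 5) "2-5" else if (d < 10) "5-10"
  else if (d < 25) "10-25" else if (d < 50) "25-50" else if (d <= 70) "50-70"
  else ">70"
}
.compound_bins <- c("<=10", "10-20", "20-50", "50-100", "100-500",
                    "500-1000", "1000-2000", ">2000")
.protein_bins <- c("1", "2-5", "5-10", "10-25", "25-50", "50-70", ">70")

#' Binned degree distribution of an interactome side
#'
#' @param interactome an [merge_interactions()] object.
#' @param side `"compound"` or `"protein"`.
#' @param breaks optional ascending numeric breaks for custom bins
#'   (left-closed `[a, b)` intervals, last bin open-ended); default `NULL`
#'   uses the side's standard scheme.
#' @return data.frame with columns `bin` and `count`; counts sum to the
#'   number of nodes on that side.
#' @export
degree_histogram <- function(interactome, side = c("compound", "protein"),
                             breaks = NULL) {
  side <- match.arg(side)
  edges <- interactome$edges
  ids <- if (side == "compound") edges$compound_id else edges$protein_id
  deg <- table(ids)
  if (!is.null(breaks)) {
    if (is.unsorted(breaks, strictly = TRUE)) {
      stop("parameter error: custom breaks must be strictly increasing",
           call. = FALSE)
    }
    labs <- c(paste0("[", breaks[-length(breaks)], ",", breaks[-1], ")"),
              paste0(">=", breaks[length(breaks)]))
    idx <- findInterval(as.integer(deg), breaks)
    idx[idx == 0] <- NA  # below first break: dropped with a warning
    if (anyNA(idx)) warning("degrees below the first break were dropped")
    counts <- table(factor(labs[idx], levels = labs))
  } else if (side == "compound") {
    b <- vapply(as.integer(deg), compound_degree_bin, character(1))
    counts <- table(factor(b, levels = .compound_bins))
  } else {
    b <- vapply(as.integer(deg), protein_degree_bin, character(1))
    counts <- table(factor(b, levels = .protein_bins))
  }
  data.frame(bin = names(counts), count = as.integer(counts),
             stringsAsFactors = FALSE)
}

#' Write an interactome edge list as TSV
#' @param interactome an [merge_interactions()] object.
#' @param path output path.
#' @export
write_edge_list <- function(interactome, path) {
  utils::write.table(interactome$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export an interactome as GraphML
#'
#' Builds a bipartite igraph (node attribute `type`: `"compound"` or
#' `"protein"`) and writes GraphML for network tools.
#'
#' @param interactome an [merge_interactions()] object.
#' @param path output path.
#' @export
write_interactome_graphml <- function(interactome, path) {
  g <- igraph::graph_from_data_frame(
    interactome$edges[, c("compound_id", "protein_id", "sources")],
    directed = FALSE,
    vertices = data.frame(
      name = c(interactome$compounds, interactome$proteins),
      type = c(rep("compound", length(interactome$compounds)),
               rep("protein", length(interactome$proteins))),
      stringsAsFactors = FALSE
    )
  )
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Map protein identifiers through a two-column table
#'
#' @param records interaction records.
#' @param mapping data.frame with columns `from`, `to`; unmapped identifiers
#'   are kept (uppercased).
#' @return records with `protein_id` rewritten.
#' @export
map_protein_ids <- function(records, mapping) {
  idx <- match(records$protein_id, toupper(mapping$from))
  hit <- !is.na(idx)
  records$protein_id[hit] <- toupper(mapping$to[idx[hit]])
  records
}
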