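## Classification of standardized structures against the substructure
## taxonomy, preceded by the exclusion filters (mass > 1200, nitrogen,
## steroid scaffold - checked in that order, first hit wins).

.exclusion_reasons <- c("none", "mass_gt_1200", "contains_nitrogen", "steroid")

#' Apply the exclusion filters to standardized structures
#'
#' A compound is removed when its average molecular mass exceeds 1200 Da, when
#' it contains nitrogen, or when it matches the steroid scaffold
#' ([steroid_pattern()]). Reasons are checked in that order; the first hit
#' wins.
#'
#' @param std data.frame from [standardize()] (needs `compound_id`,
#'   `canonical_smiles`, `formula`, `avg_mass`).
#' @return data.frame with columns `compound_id`, `kept`, `exclusion_reason`.
#' @export
apply_exclusion_filters <- function(std) {
  reasons <- vapply(seq_len(nrow(std)), function(i) {
    if (std$avg_mass[i] > 1200) return("mass_gt_1200")
    if (formula_has_nitrogen(std$formula[i])) return("contains_nitrogen")
    mol <- parse_mol(std$canonical_smiles[i])
    if (smarts_count(mol, .steroid_smarts) > 0) return("steroid")
    "none"
  }, character(1))
  data.frame(
    compound_id = std$compound_id,
    kept = reasons == "none",
    exclusion_reason = reasons,
    stringsAsFactors = FALSE
  )
}

classify_one <- function(canonical_smiles, library) {
  mol <- parse_mol(canonical_smiles)
  hits <- vapply(library$smarts, function(s) smarts_count(mol, s) > 0,
                 logical(1), USE.NAMES = FALSE)
  ids <- library$pattern_id[hits]
  subcl <- sort(unique(unlist(strsplit(library$subclasses[hits], ";", fixed = TRUE))))
  cls <- sort(unique(library$class[hits]))
  list(matched_pattern_ids = ids, subclasses = subcl, classes = cls)
}

#' Classify one standardized structure
#'
#' @param std one-row data.frame from [standardize()] (or a list with the same
#'   fields).
#' @param library pattern library from [load_pattern_library()].
#' @return list with fields `compound_id`, `matched_pattern_ids`,
#'   `subclasses`, `classes`, `excluded`, `exclusion_reason`.
#' @export
classify <- function(std, library = load_pattern_library()) {
  std <- as.data.frame(std, stringsAsFactors = FALSE)
  excl <- apply_exclusion_filters(std)
  if (!excl$kept[1]) {
    return(list(compound_id = std$compound_id[1],
                matched_pattern_ids = character(0),
                subclasses = character(0), classes = character(0),
                excluded = TRUE, exclusion_reason = excl$exclusion_reason[1]))
  }
  hit <- classify_one(std$canonical_smiles[1], library)
  c(list(compound_id = std$compound_id[1]), hit,
    list(excluded = FALSE, exclusion_reason = "none"))
}

#' Classify a batch of standardized structures
#'
#' @param std data.frame from [standardize()]; `compound_id` must be unique.
#' @param library pattern library from [load_pattern_library()].
#' @return data.frame with one row per input: `compound_id`, `excluded`,
#'   `exclusion_reason`, `matched_patterns`, `subclasses`, `classes`
#'   (semicolon-joined, alphabetically sorted). Summary tallies are available
#'   via [classification_summary()].
#' @export
classify_batch <- function(std, library = load_pattern_library()) {
  if (anyDuplicated(std$compound_id)) {
    stop("validation error: duplicate compound_id: ",
         paste(unique(std$compound_id[duplicated(std$compound_id)]),
               collapse = ", "), call. = FALSE)
  }
  if (nrow(std) == 0) {
    return(data.frame(compound_id = character(0), excluded = logical(0),
                      exclusion_reason = character(0),
                      matched_patterns = character(0),
                      subclasses = character(0), classes = character(0),
                      stringsAsFactors = FALSE))
  }
  excl <- apply_exclusion_filters(std)
  rows <- lapply(seq_len(nrow(std)), function(i) {
    if (!excl$kept[i]) {
      return(data.frame(
        compound_id = std$compound_id[i], excluded = TRUE,
        exclusion_reason = excl$exclusion_reason[i],
        matched_patterns = "", subclasses = "", classes = "",
        stringsAsFactors = FALSE))
    }
    hit <- classify_one(std$canonical_smiles[i], library)
    data.frame(
      compound_id = std$compound_id[i], excluded = FALSE,
      exclusion_reason = "none",
      matched_patterns = paste(hit$matched_pattern_ids, collapse = ";"),
      subclasses = paste(hit$subclasses, collapse = ";"),
      classes = paste(hit$classes, collapse = ";"),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-class and per-subclass tallies of a classification table
#'
#' @param classified output of [classify_batch()].
#' @return list with data.frames `classes`, `subclasses` and `exclusions`,
#'   each with a `count` column.
#' @export
classification_summary <- function(classified) {
  tally <- function(col) {
    vals <- unlist(strsplit(classified[[col]][!classified$excluded], ";",
                            fixed = TRUE))
    vals <- vals[nzchar(vals)]
    if (length(vals) == 0) {
      return(data.frame(label = character(0), count = integer(0),
                        stringsAsFactors = FALSE))
    }
    tab <- table(vals)
    data.frame(label = names(tab), count = as.integer(tab),
               stringsAsFactors = FALSE)
  }
  excl <- table(factor(classified$exclusion_reason, levels = .exclusion_reasons))
  list(
    classes = tally("classes"),
    subclasses = tally("subclasses"),
    exclusions = data.frame(reason = names(excl), count = as.integer(excl),
                            stringsAsFactors = FALSE)
  )
}

# Split a semicolon-joined column into a named list of character vectors.
split_multi <- function(x, ids) {
  out <- strsplit(x, ";", fixed = TRUE)
  out <- lapply(out, function(v) v[nzchar(v)])
  names(out) <- ids
  out
}
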