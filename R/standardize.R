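## Structure standardization and strict-stereochemistry list matching.
##
## The standardization scheme applies, in order: (i) fragment removal (largest
## organic fragment kept), (ii) charge neutralization, (iii) explicit-hydrogen
## suppression, (iv) deterministic tautomer normalization (acyclic keto-enol),
## (v) aromatization, and finally emits a unique canonical SMILES. Stereo
## descriptors present in the input are preserved.

#' Standardize raw SMILES structures
#'
#' Applies the five-step standardization pipeline and generates a unique
#' canonical SMILES per compound.
#'
#' @param smiles character vector of raw SMILES strings.
#' @param compound_id optional character vector of identifiers (defaults to
#'   names of `smiles`, else `cpd_1..n`). Must be unique.
#' @return a `data.frame` with columns `compound_id`, `input_smiles`,
#'   `canonical_smiles`, `formula`, `avg_mass`, `has_stereo`.
#' @examples
#' standardize("[Na+].[O-]C(=O)c1ccccc1O")   # neutral salicylic acid
#' @export
standardize <- function(smiles, compound_id = NULL) {
  if (is.null(compound_id)) {
    compound_id <- if (!is.null(names(smiles))) names(smiles)
                   else paste0("cpd_", seq_along(smiles))
  }
  if (length(compound_id) != length(smiles)) {
    stop("compound_id and smiles lengths differ", call. = FALSE)
  }
  if (anyDuplicated(compound_id)) {
    stop("duplicate compound_id: ",
         paste(unique(compound_id[duplicated(compound_id)]), collapse = ", "),
         call. = FALSE)
  }
  if (length(smiles) == 0) {
    return(data.frame(compound_id = character(0), input_smiles = character(0),
                      canonical_smiles = character(0), formula = character(0),
                      avg_mass = numeric(0), has_stereo = logical(0),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(seq_along(smiles), function(i) {
    s <- smiles[[i]]
    if (!smiles_valid(s)) {
      stop("structure error: cannot parse SMILES '", s,
           "' (compound ", compound_id[i], ")", call. = FALSE)
    }
    s1 <- largest_fragment(s)          # (i)
    s2 <- neutralize_smiles(s1)        # (ii)
    s3 <- suppress_hydrogens(s2)       # (iii)
    s4 <- canonical_tautomer(s3)       # (iv)
    p  <- smiles_props(s4)             # (v) canonical SMILES is aromatized
    data.frame(
      compound_id = compound_id[i],
      input_smiles = s,
      canonical_smiles = p$cansmi,
      formula = p$formula,
      avg_mass = p$mw,
      has_stereo = !identical(p$cansmi, p$cansmiNS),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Canonical matching key for a standardized structure
#'
#' @param canonical_smiles character vector of standardized canonical SMILES.
#' @param strict_stereo if `TRUE` (default) stereo descriptors are part of the
#'   key; if `FALSE` they are stripped before canonicalization.
#' @return character vector of keys.
#' @export
canonical_key <- function(canonical_smiles, strict_stereo = TRUE) {
  vapply(canonical_smiles, function(s) {
    p <- smiles_props(s)
    if (strict_stereo) p$cansmi else p$cansmiNS
  }, character(1), USE.NAMES = FALSE)
}

#' Match two standardized compound lists by canonical key
#'
#' Pairs every entry of `list_a` with every entry of `list_b` that shares its
#' canonical key. Under strict stereochemistry an entry with unspecified
#' stereocentres does not match one with specified stereocentres.
#'
#' @param list_a,list_b data.frames with columns `compound_id` and
#'   `canonical_smiles` (as produced by [standardize()]).
#' @param strict_stereo logical; see [canonical_key()].
#' @return a list with elements `pairs` (data.frame `id_a`, `id_b`,
#'   `canonical_key`), `unmatched_a` and `unmatched_b` (character vectors).
#' @export
match_lists <- function(list_a, list_b, strict_stereo = TRUE) {
  for (nm in c("compound_id", "canonical_smiles")) {
    if (!nm %in% names(list_a) || !nm %in% names(list_b)) {
      stop("inputs must carry columns compound_id and canonical_smiles",
           call. = FALSE)
    }
  }
  key_a <- canonical_key(list_a$canonical_smiles, strict_stereo)
  key_b <- canonical_key(list_b$canonical_smiles, strict_stereo)
  dedup <- function(ids, keys, label) {
    dup <- duplicated(keys)
    if (any(dup)) {
      warning("duplicate canonical keys in list ", label, ": ",
              paste(ids[dup], collapse = ", "), "; first occurrence used",
              call. = FALSE)
    }
    data.frame(compound_id = ids[!dup], key = keys[!dup],
               stringsAsFactors = FALSE)
  }
  a <- dedup(list_a$compound_id, key_a, "A")
  b <- dedup(list_b$compound_id, key_b, "B")
  hit <- merge(a, b, by = "key", suffixes = c("_a", "_b"))
  pairs <- data.frame(
    id_a = hit$compound_id_a, id_b = hit$compound_id_b,
    canonical_key = hit$key, stringsAsFactors = FALSE
  )
  pairs <- pairs[order(pairs$id_a, pairs$id_b), , drop = FALSE]
  rownames(pairs) <- NULL
  list(
    pairs = pairs,
    unmatched_a = sort(setdiff(list_a$compound_id, pairs$id_a)),
    unmatched_b = sort(setdiff(list_b$compound_id, pairs$id_b))
  )
}

#' Read a SMILES file
#'
#' One structure per line, `SMILES<whitespace>id`. Lines starting with `#`
#' are skipped.
#'
#' @param path file path.
#' @return data.frame with columns `compound_id`, `smiles`.
#' @export
read_smiles_file <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "[ \t]+")
  smi <- vapply(parts, `[`, character(1), 1)
  ids <- vapply(parts, function(p) if (length(p) > 1) p[2] else NA_character_,
                character(1))
  ids[is.na(ids)] <- paste0("cpd_", which(is.na(ids)))
  data.frame(compound_id = ids, smiles = smi, stringsAsFactors = FALSE)
}

#' Write a SMILES file
#' @param x data.frame with columns `compound_id`, `smiles`.
#' @param path output path.
#' @export
write_smiles_file <- function(x, path) {
  writeLines(paste(x$smiles, x$compound_id, sep = "\t"), path)
  invisible(path)
}
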