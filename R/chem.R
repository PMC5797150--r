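## Low-level chemistry layer on top of ChemmineOB (OpenBabel).
## All structure I/O in the package funnels through these helpers so that the
## standardization contract (one engine, one aromaticity model, one canonical
## serialization) holds everywhere.

#' Test whether SMILES strings parse
#'
#' @param smiles character vector of SMILES strings.
#' @return logical vector, `TRUE` where the string parses as a molecule.
#' @export
smiles_valid <- function(smiles) {
  vapply(smiles, function(s) {
    if (is.na(s) || !nzchar(trimws(s))) return(FALSE)
    out <- tryCatch(
      suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", s)),
      error = function(e) ""
    )
    nzchar(trimws(out))
  }, logical(1), USE.NAMES = FALSE)
}

# Parse one SMILES into an OpenBabel molecule handle; stop() on failure so the
# offending string is named in the error (structure-error contract).
parse_mol <- function(smiles) {
  if (!smiles_valid(smiles)) {
    stop("structure error: cannot parse SMILES '", smiles, "'", call. = FALSE)
  }
  ChemmineOB::forEachMol("SMILES", smiles, identity)
}

# Count of (unique) matches of one SMARTS pattern in one molecule.
smarts_count <- function(mol, smarts) {
  ChemmineOB::smartsSearch_OB(mol, smarts, uniqueMatches = TRUE)
}

# cansmi / cansmiNS / formula / average MW for one parsed molecule.
mol_props <- function(mol) {
  p <- ChemmineOB::prop_OB(mol)
  list(
    cansmi   = trimws(p$cansmi[1]),
    cansmiNS = trimws(p$cansmiNS[1]),
    formula  = trimws(p$formula[1]),
    mw       = as.numeric(p$MW[1])
  )
}

smiles_props <- function(smiles) mol_props(parse_mol(smiles))

# Parse a Hill-order molecular formula ("C15H10O7", "C6H5O-") into a named
# count vector. Charges and isotope prefixes are ignored.
parse_formula <- function(formula) {
  formula <- gsub("[+-]+[0-9]*$", "", formula)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  toks <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (length(toks) == 0) return(stats::setNames(integer(0), character(0)))
  el <- gsub("[0-9]*$", "", toks)
  ct <- as.integer(ifelse(gsub("^[A-Z][a-z]?", "", toks) == "", "1",
                          gsub("^[A-Z][a-z]?", "", toks)))
  tapply(ct, el, sum)
}

formula_has_nitrogen <- function(formula) {
  counts <- parse_formula(formula)
  "N" %in% names(counts) && counts[["N"]] > 0
}

heavy_atom_count <- function(formula) {
  counts <- parse_formula(formula)
  sum(counts[setdiff(names(counts), "H")])
}

# Keep the largest fragment of a dot-disconnected SMILES. Largest by heavy-atom
# count; ties broken by average mass, then lexicographically smallest canonical
# SMILES (all deterministic).
largest_fragment <- function(smiles) {
  parts <- strsplit(smiles, ".", fixed = TRUE)[[1]]
  parts <- parts[nzchar(parts)]
  if (length(parts) <= 1) return(smiles)
  props <- lapply(parts, smiles_props)
  heavy <- vapply(props, function(p) heavy_atom_count(p$formula), numeric(1))
  mw    <- vapply(props, function(p) p$mw, numeric(1))
  can   <- vapply(props, function(p) p$cansmi, character(1))
  ord <- order(-heavy, -mw, can)
  parts[ord[1]]
}

# OpenBabel's charge-neutralization transform (+1/-1 centres).
neutralize_smiles <- function(smiles) {
  out <- ChemmineOB::convertFormat(
    "SMI", "SMI", smiles,
    options = data.frame(names = "neutralize", args = "")
  )
  trimws(strsplit(out, "[ \t\n]")[[1]][1])
}

# Collapse explicit hydrogens to implicit ones (stereo-defining H survive as
# implicit H inside stereo atom brackets on re-serialization).
suppress_hydrogens <- function(smiles) {
  out <- ChemmineOB::convertFormat(
    "SMI", "SMI", smiles,
    options = data.frame(names = "d", args = "")
  )
  trimws(strsplit(out, "[ \t\n]")[[1]][1])
}

## ---- mol-block (V2000) helpers -------------------------------------------
## The tautomer normalizer and the atom-renumbering utility edit the fixed-
## width bond block of a V2000 mol block directly: this keeps every other
## record (charges, parities) byte-identical.

molblock_from_smiles <- function(smiles) {
  ChemmineOB::convertFormat("SMI", "SDF", smiles)
}

smiles_from_molblock <- function(molblock) {
  out <- ChemmineOB::convertFormat("SDF", "SMI", molblock)
  trimws(strsplit(out, "[ \t\n]")[[1]][1])
}

parse_molblock <- function(molblock) {
  lines <- strsplit(molblock, "\n", fixed = TRUE)[[1]]
  counts <- lines[4]
  na <- as.integer(substr(counts, 1, 3))
  nb <- as.integer(substr(counts, 4, 6))
  atom_lines <- lines[5:(4 + na)]
  bond_lines <- if (nb > 0) lines[(5 + na):(4 + na + nb)] else character(0)
  bonds <- if (nb > 0) {
    data.frame(
      a = as.integer(substr(bond_lines, 1, 3)),
      b = as.integer(substr(bond_lines, 4, 6)),
      order = as.integer(substr(bond_lines, 7, 9))
    )
  } else data.frame(a = integer(0), b = integer(0), order = integer(0))
  list(
    lines = lines, n_atoms = na, n_bonds = nb,
    elements = trimws(substr(atom_lines, 32, 34)),
    bonds = bonds,
    bond_offset = 4 + na
  )
}

# Is bond i (row of mb$bonds) a ring bond? True iff its endpoints stay
# connected when the bond is removed.
is_ring_bond <- function(mb, i) {
  from <- mb$bonds$a[i]; to <- mb$bonds$b[i]
  adj <- vector("list", mb$n_atoms)
  for (j in seq_len(mb$n_bonds)) {
    if (j == i) next
    a <- mb$bonds$a[j]; b <- mb$bonds$b[j]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  seen <- logical(mb$n_atoms)
  queue <- from; seen[from] <- TRUE
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) {
      if (w == to) return(TRUE)
      if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
    }
  }
  FALSE
}

set_bond_order <- function(mb, i, order) {
  ln <- mb$bond_offset + i
  old <- mb$lines[ln]
  mb$lines[ln] <- paste0(
    sprintf("%3d%3d%3d", mb$bonds$a[i], mb$bonds$b[i], order),
    substr(old, 10, nchar(old))
  )
  mb$bonds$order[i] <- order
  mb
}

# SMARTS gate for an acyclic enol (hydroxyl on a non-ring C=C).
.enol_gate <- "[OX2H][CX3;R0]=[CX3;R0]"

# Deterministic canonical-tautomer step: rewrite acyclic enols to their keto
# form, lowest atom index first, iterated to a fixed point. Ring and aromatic
# systems (phenols!) are never touched. Returns a SMILES string.
canonical_tautomer <- function(smiles, max_iter = 20L) {
  for (iter in seq_len(max_iter)) {
    mol <- parse_mol(smiles)
    if (smarts_count(mol, .enol_gate) == 0) return(smiles)
    mb <- parse_molblock(molblock_from_smiles(smiles))
    deg <- tabulate(c(mb$bonds$a, mb$bonds$b), nbins = mb$n_atoms)
    hit <- NULL
    for (i in seq_len(mb$n_bonds)) {
      # candidate O-C single bond with terminal O
      if (mb$bonds$order[i] != 1) next
      ends <- c(mb$bonds$a[i], mb$bonds$b[i])
      o <- ends[mb$elements[ends] == "O"]
      c1 <- ends[mb$elements[ends] == "C"]
      if (length(o) != 1 || length(c1) != 1 || deg[o] != 1) next
      for (j in seq_len(mb$n_bonds)) {
        if (mb$bonds$order[j] != 2) next
        e2 <- c(mb$bonds$a[j], mb$bonds$b[j])
        if (!(c1 %in% e2)) next
        c2 <- setdiff(e2, c1)
        if (mb$elements[c2] != "C") next
        if (is_ring_bond(mb, j)) next
        cand <- c(o = o, c1 = c1, oi = i, ci = j)
        if (is.null(hit) || cand["o"] < hit["o"] ||
            (cand["o"] == hit["o"] && cand["c1"] < hit["c1"])) hit <- cand
      }
    }
    if (is.null(hit)) return(smiles)  # gate hit but graph rule declined (safety)
    mb <- set_bond_order(mb, hit[["oi"]], 2L)
    mb <- set_bond_order(mb, hit[["ci"]], 1L)
    smiles <- smiles_from_molblock(paste(mb$lines, collapse = "\n"))
  }
  smiles
}

#' Rewrite a SMILES with a permuted atom order
#'
#' Produces a different, equally valid serialization of the same molecule by
#' permuting the atom numbering of its mol block. Used to exercise
#' canonicalization invariance. Restricted to stereo-free molecules because
#' mol-block stereo parity is defined relative to atom numbering.
#'
#' @param smiles a single SMILES string without stereo descriptors.
#' @param seed integer seed selecting the permutation.
#' @return a SMILES string describing the same molecule.
#' @export
renumber_smiles <- function(smiles, seed = 1L) {
  pr <- smiles_props(smiles)
  if (!identical(pr$cansmi, pr$cansmiNS)) {
    stop("renumber_smiles() only supports stereo-free molecules", call. = FALSE)
  }
  mb <- parse_molblock(molblock_from_smiles(smiles))
  perm <- withr_seed(seed, sample.int(mb$n_atoms))   # new index for old atom i
  lines <- mb$lines
  atom_lines <- lines[5:(4 + mb$n_atoms)]
  lines[5:(4 + mb$n_atoms)] <- atom_lines[order(perm)]
  if (mb$n_bonds > 0) {
    for (i in seq_len(mb$n_bonds)) {
      ln <- mb$bond_offset + i
      old <- lines[ln]
      lines[ln] <- paste0(
        sprintf("%3d%3d%3d", perm[mb$bonds$a[i]], perm[mb$bonds$b[i]],
                mb$bonds$order[i]),
        substr(old, 10, nchar(old))
      )
    }
  }
  smiles_from_molblock(paste(lines, collapse = "\n"))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
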