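## The polyphenol substructure taxonomy: 43 SMARTS scaffolds mapped to 31
## subclasses in 5 queryable classes (a 6th declared class, non-phenolic
## metabolites, has no fixed structural feature and cannot be queried).

.queryable_classes <- c("flavonoids", "phenolic acids", "lignans",
                        "stilbenes", "other polyphenols")

#' The declared polyphenol class taxonomy
#'
#' @return data.frame with columns `class` and `queryable`. Five classes carry
#'   substructure scaffolds; the sixth (non-phenolic metabolites of
#'   polyphenols) has no fixed structural feature.
#' @export
polyphenol_classes <- function() {
  data.frame(
    class = c(.queryable_classes, "non-phenolic metabolites"),
    queryable = c(rep(TRUE, 5), FALSE),
    stringsAsFactors = FALSE
  )
}

#' Load the polyphenol substructure pattern library
#'
#' Reads and validates a pattern library: a TSV with columns `pattern_id`,
#' `smarts`, `subclasses` (semicolon-joined) and `class`. With `path = NULL`
#' the library shipped with the package is used (43 patterns, 31 subclasses,
#' 5 classes).
#'
#' @param path optional path to a user library; default `NULL` loads the
#'   shipped library.
#' @return data.frame ordered by `pattern_id` with an added list-column-free
#'   representation (`subclasses` stays semicolon-joined).
#' @export
load_pattern_library <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "polyphenol_patterns.tsv",
                        package = "polyphenome")
  }
  if (!file.exists(path)) stop("pattern library not found: ", path, call. = FALSE)
  lib <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("pattern_id", "smarts", "subclasses", "class")
  if (!all(need %in% names(lib))) {
    stop("pattern library must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  lib <- lib[order(lib$pattern_id), need, drop = FALSE]
  rownames(lib) <- NULL
  validate_pattern_library(lib)
  lib
}

validate_pattern_library <- function(lib) {
  if (nrow(lib) != 43) {
    stop("validation error: pattern library must contain exactly 43 patterns, got ",
         nrow(lib), call. = FALSE)
  }
  subcl <- unique(unlist(strsplit(lib$subclasses, ";", fixed = TRUE)))
  if (length(subcl) != 31) {
    stop("validation error: pattern library must span exactly 31 subclasses, got ",
         length(subcl), call. = FALSE)
  }
  cls <- unique(lib$class)
  if (length(cls) != 5 || !setequal(cls, .queryable_classes)) {
    stop("validation error: pattern library must span the 5 queryable classes",
         call. = FALSE)
  }
  if (anyDuplicated(lib$pattern_id)) {
    stop("validation error: duplicate pattern_id", call. = FALSE)
  }
  # every expression must be usable as a substructure query
  probe <- parse_mol("c1ccccc1O")
  for (i in seq_len(nrow(lib))) {
    ok <- tryCatch({
      smarts_count(probe, lib$smarts[i]); TRUE
    }, error = function(e) FALSE)
    if (!ok) {
      stop("parse error in pattern '", lib$pattern_id[i], "': invalid SMARTS '",
           lib$smarts[i], "'", call. = FALSE)
    }
  }
  invisible(lib)
}

# Steroid exclusion scaffold: the gonane (cyclopenta[a]phenanthrene)
# tetracycle with any bond orders, so saturated, unsaturated and A-ring
# aromatic steroids all match.
.steroid_smarts <- paste0(
  "[#6]~1~[#6]~[#6]~[#6]~2~[#6](~[#6]~1)~[#6]~[#6]~[#6]~1~[#6]~3~[#6]~[#6]~",
  "[#6]~[#6]~3~[#6]~[#6]~[#6]~2~1"
)

#' SMARTS pattern used for steroid exclusion
#' @return a single SMARTS string (gonane tetracycle, any bond orders).
#' @export
steroid_pattern <- function() .steroid_smarts
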