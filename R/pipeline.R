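## End-to-end orchestration: standardize -> classify -> interactome ->
## enrichment -> food, from one validated configuration, with a run manifest
## echoing every threshold used. Identical config + inputs reproduce
## identical output trees.

#' Build and validate a pipeline configuration
#'
#' Defaults equal the published thresholds of the mining protocol: STITCH
#' confidence 0.9, BH alpha 0.1, class-level coverage 0.1, food-level
#' coverage 0.2, strict stereochemistry.
#'
#' @param compounds,stitch,sif,bindingdb,gmt,ontology,foods input file paths.
#' @param out_dir output directory.
#' @param min_score,alpha,min_coverage_class,min_coverage_food,strict_stereo
#'   thresholds.
#' @param seed integer seed recorded in the manifest.
#' @return a validated config (class `run_config`).
#' @export
run_config <- function(compounds, stitch, sif, bindingdb, gmt, ontology,
                       foods, out_dir, min_score = 0.9, alpha = 0.1,
                       min_coverage_class = 0.1, min_coverage_food = 0.2,
                       strict_stereo = TRUE, seed = 42L) {
  cfg <- list(
    inputs = list(compounds = compounds, stitch = stitch, sif = sif,
                  bindingdb = bindingdb, gmt = gmt, ontology = ontology,
                  foods = foods),
    out_dir = out_dir,
    min_score = min_score, alpha = alpha,
    min_coverage_class = min_coverage_class,
    min_coverage_food = min_coverage_food,
    strict_stereo = isTRUE(strict_stereo), seed = as.integer(seed)
  )
  for (p in c("min_score", "alpha", "min_coverage_class", "min_coverage_food")) {
    v <- cfg[[p]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1) {
      stop("config error: ", p, " must lie in [0, 1]", call. = FALSE)
    }
  }
  missing <- Filter(function(p) !file.exists(p), unlist(cfg$inputs))
  if (length(missing)) {
    stop("config error: missing input file(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  structure(cfg, class = "run_config")
}

#' Re-create a configuration from a run manifest
#' @param path `manifest.json` written by [run_pipeline()].
#' @param out_dir optional new output directory (defaults to the recorded one).
#' @return a `run_config`.
#' @export
config_from_manifest <- function(path, out_dir = NULL) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, c(
    as.list(m$inputs),
    list(out_dir = if (is.null(out_dir)) m$out_dir else out_dir,
         min_score = m$min_score, alpha = m$alpha,
         min_coverage_class = m$min_coverage_class,
         min_coverage_food = m$min_coverage_food,
         strict_stereo = m$strict_stereo, seed = m$seed)
  ))
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full mining pipeline
#'
#' Stage outputs are written under stage-named subdirectories of
#' `config$out_dir`; a failure aborts with the failing stage named; the
#' resolved configuration is echoed to `manifest.json`.
#'
#' @param config a [run_config()].
#' @return invisible list of in-memory stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  stage_dir <- function(s) {
    d <- file.path(out, s); dir.create(d, recursive = TRUE, showWarnings = FALSE); d
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  std <- stage("standardize", {
    raw <- read_smiles_file(config$inputs$compounds)
    s <- standardize(raw$smiles, raw$compound_id)
    write_tsv(s, file.path(stage_dir("standardize"), "standardized.tsv"))
    s
  })

  classified <- stage("classify", {
    cl <- classify_batch(std)
    d <- stage_dir("classify")
    write_tsv(cl, file.path(d, "classification.tsv"))
    summ <- classification_summary(cl)
    write_tsv(summ$classes, file.path(d, "class_counts.tsv"))
    write_tsv(summ$subclasses, file.path(d, "subclass_counts.tsv"))
    cl
  })

  net <- stage("interactome", {
    stitch <- filter_interactions(
      parse_stitch_like(config$inputs$stitch),
      min_score = config$min_score, exclude_textmining_only = TRUE)
    sif <- parse_sif_like(config$inputs$sif)
    bdb <- parse_bindingdb_like(config$inputs$bindingdb)
    net <- merge_interactions(stitch, sif, bdb, provenance = list(
      min_score = config$min_score, exclude_textmining_only = TRUE))
    d <- stage_dir("interactome")
    write_edge_list(net, file.path(d, "edges.tsv"))
    write_interactome_graphml(net, file.path(d, "interactome.graphml"))
    jsonlite::write_json(list(
      n_compounds = length(net$compounds), n_proteins = length(net$proteins),
      n_edges = nrow(net$edges), n_records = net$n_records,
      source_overlap = source_overlap(net),
      degree_compounds = degree_histogram(net, "compound"),
      degree_proteins = degree_histogram(net, "protein")
    ), file.path(d, "summary.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
    net
  })

  enr <- stage("enrichment", {
    gene_sets <- read_gmt(config$inputs$gmt)
    ontology <- read_pathway_ontology(config$inputs$ontology)
    res <- enrich_by_class(net, classified, gene_sets,
                           alpha = config$alpha,
                           min_coverage = config$min_coverage_class)
    d <- stage_dir("enrichment")
    write_tsv(res, file.path(d, "class_enrichment.tsv"))
    summ <- category_summary(res, ontology)
    write_tsv(summ$percent, file.path(d, "category_percent.tsv"))
    write_tsv(summ$coverage, file.path(d, "category_coverage.tsv"))
    list(results = res, summary = summ, gene_sets = gene_sets,
         ontology = ontology)
  })

  food <- stage("food", {
    ft <- read_food_table(config$inputs$foods)
    d <- stage_dir("food")
    cmp <- compare_foods(ft)
    write_tsv(data.frame(food = rownames(cmp$jaccard), cmp$jaccard,
                         check.names = FALSE), file.path(d, "jaccard.tsv"))
    nets <- lapply(sort(unique(ft$food)), function(f) {
      fn <- food_enrichment_network(
        f, ft, net, enr$gene_sets, enr$ontology,
        alpha = config$alpha, min_coverage = config$min_coverage_food)
      write_tsv(fn$edges, file.path(d, paste0(f, "_network_edges.tsv")))
      fn
    })
    names(nets) <- sort(unique(ft$food))
    list(table = ft, networks = nets, jaccard = cmp$jaccard)
  })

  manifest <- c(unclass(config)[c("inputs", "out_dir", "min_score", "alpha",
                                  "min_coverage_class", "min_coverage_food",
                                  "strict_stereo", "seed")])
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(standardized = std, classified = classified,
                 interactome = net, enrichment = enr, food = food))
}
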