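#' Read pipeline input tables
#'
#' Readers for the plain-TSV dialects the pipeline consumes: a phenotype
#' universe (one concept id per line), plant efficacy pairs
#' `(plant_id, concept_id)`, plant-compound pairs
#' `(plant_id, compound_id)` and a gold standard
#' `(compound_id, concept_id[, label])`. All files are headerless TSV.
#'
#' @param path file path.
#' @return `readUniverse`: character vector. `readEfficacy`,
#'   `readCatalog`: named list keyed by plant id. `readGoldStandard`:
#'   data.frame with `compound_id`, `concept_id`, `label`.
#' @export
readUniverse <- function(path) {
  u <- readLines(path)
  u <- u[nzchar(u)]
  if (anyDuplicated(u)) stop("duplicate concept ids in universe file")
  u
}

.readPairs <- function(path, what) {
  tab <- read.table(path, sep = "\t", header = FALSE, quote = "",
                    colClasses = "character")
  if (ncol(tab) < 2L)
    stop(what, " file must have 2 tab-separated columns: ", path)
  split(tab[[2]], tab[[1]])
}

#' @rdname readUniverse
#' @export
readEfficacy <- function(path) {
  lapply(.readPairs(path, "efficacy"), function(v) sort(unique(v)))
}

#' @rdname readUniverse
#' @export
readCatalog <- function(path) {
  lapply(.readPairs(path, "composition"), function(v) sort(unique(v)))
}

#' @rdname readUniverse
#' @export
readGoldStandard <- function(path) {
  tab <- read.table(path, sep = "\t", header = FALSE, quote = "",
                    colClasses = "character")
  if (ncol(tab) < 2L)
    stop("gold-standard file must have at least 2 columns: ", path)
  out <- data.frame(compound_id = tab[[1]], concept_id = tab[[2]],
                    label = if (ncol(tab) >= 3L) tab[[3]] else "therapeutic",
                    stringsAsFactors = FALSE)
  unique(out)
}

#' Write / read a phenotype matrix as TSV
#'
#' Plants as rows, universe concepts as columns; the header row of
#' concept ids makes the column order self-describing.
#'
#' @param X numeric matrix with dimnames.
#' @param path file path.
#' @return `writeMatrixTSV` returns `path` invisibly; `readMatrixTSV`
#'   the matrix.
#' @export
writeMatrixTSV <- function(X, path) {
  # 17 significant digits: doubles survive the text round-trip exactly,
  # so chained stage runs reproduce in-memory results byte for byte
  chr <- matrix(formatC(X, digits = 17, format = "g"), nrow = nrow(X),
                dimnames = dimnames(X))
  df <- data.frame(plant_id = rownames(X), chr, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeMatrixTSV
#' @export
readMatrixTSV <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  X <- as.matrix(df[, -1, drop = FALSE])
  rownames(X) <- df[[1]]
  X
}

#' Write / read a selected-cluster table as TSV
#'
#' Columns `cluster_id`, `au`, `members` (comma-joined plant ids); the
#' reader rebuilds the list-column [pickClusters()] produces so stages
#' can be run standalone on each other's files.
#'
#' @param clusters data.frame from [pickClusters()].
#' @param path file path.
#' @return `writeClusters` returns `path` invisibly; `readClusters` the
#'   cluster data.frame.
#' @export
writeClusters <- function(clusters, path) {
  tab <- data.frame(
    cluster_id = clusters$cluster_id, au = clusters$au,
    members = vapply(clusters$members, paste, character(1),
                     collapse = ","))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeClusters
#' @export
readClusters <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE,
                    colClasses = c("character", "numeric", "character"))
  out <- data.frame(cluster_id = tab$cluster_id, au = tab$au,
                    stringsAsFactors = FALSE)
  out$members <- strsplit(tab$members, ",", fixed = TRUE)
  out$n_members <- lengths(out$members)
  out[, c("cluster_id", "au", "n_members", "members")]
}

#' Pipeline configuration
#'
#' Builds the full configuration list with the pipeline defaults:
#' restart probability 0.7, RWR tolerance 1e-8, 1000 bootstrap
#' resamples, AU threshold 0.95, Fisher alpha 0.001, effect-score cutoff
#' 0.20, average linkage and the ten-scale grid 0.5-1.4. Configurations
#' round-trip through YAML losslessly via [saveConfig()] /
#' [loadConfig()].
#'
#' @param relations,efficacy,compounds,universe input file paths.
#' @param gold optional gold-standard path (enables evaluation).
#' @param r restart probability.
#' @param tol RWR convergence tolerance (L1).
#' @param n_boot bootstrap resamples per scale.
#' @param au_threshold AU p-value threshold for cluster selection.
#' @param fisher_alpha enrichment p-value threshold.
#' @param effect_cutoff score cutoff for the filtered association list.
#' @param linkage agglomeration method.
#' @param scales bootstrap scale grid.
#' @param fisher_sidedness `"greater"` or `"two.sided"`.
#' @param multi_cluster_combine `"max"` or `"mean"`.
#' @param rb_second_broader orientation convention of RB rows.
#' @param use_hierarchy `FALSE` switches to the binary no-hierarchy
#'   ablation vectors.
#' @param seed integer seed for all resampling.
#' @return named configuration list.
#' @export
pipelineConfig <- function(relations, efficacy, compounds, universe,
                           gold = NULL, r = 0.7, tol = 1e-8,
                           n_boot = 1000L, au_threshold = 0.95,
                           fisher_alpha = 0.001, effect_cutoff = 0.20,
                           linkage = "average",
                           scales = seq(0.5, 1.4, by = 0.1),
                           fisher_sidedness = "greater",
                           multi_cluster_combine = "max",
                           rb_second_broader = TRUE,
                           use_hierarchy = TRUE, seed = 1L) {
  cfg <- list(relations = relations, efficacy = efficacy,
              compounds = compounds, universe = universe, gold = gold,
              r = r, tol = tol, n_boot = as.integer(n_boot),
              au_threshold = au_threshold, fisher_alpha = fisher_alpha,
              effect_cutoff = effect_cutoff, linkage = linkage,
              scales = scales, fisher_sidedness = fisher_sidedness,
              multi_cluster_combine = multi_cluster_combine,
              rb_second_broader = rb_second_broader,
              use_hierarchy = use_hierarchy, seed = as.integer(seed))
  stopifnot(cfg$r > 0, cfg$r < 1, cfg$tol > 0, cfg$n_boot >= 1L,
            cfg$au_threshold > 0, cfg$au_threshold <= 1,
            cfg$fisher_alpha > 0, cfg$fisher_alpha <= 1,
            cfg$effect_cutoff >= 0)
  cfg
}

#' @rdname pipelineConfig
#' @param config a configuration list.
#' @param path YAML file path.
#' @export
saveConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname pipelineConfig
#' @export
loadConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipelineConfig, cfg)
}

#' Run the phenotype-oriented analysis end to end
#'
#' Executes the full pipeline: parse the concept hierarchy, weight it by
#' Wu-Palmer similarity, diffuse each plant's efficacy annotations by
#' random walk with restart, cluster the plant phenotype vectors with
#' multiscale-bootstrap support, extract compounds enriched in supported
#' clusters by Fisher's exact test, map averaged cluster vectors onto
#' them as predicted effects, and (when a gold standard is configured)
#' evaluate the ranked predictions. Every intermediate is written as a
#' human-diffable TSV, plus a deterministic run manifest; identical
#' configuration and seed reproduce the outputs byte for byte.
#'
#' @param config configuration list from [pipelineConfig()] or a YAML
#'   path for [loadConfig()].
#' @param outDir artifact directory (created if needed).
#' @return invisibly, a list with the in-memory stage results
#'   (`network`, `matrix`, `dendrogram`, `support`, `clusters`,
#'   `enriched`, `predictions`, `associations`, `evaluation`, `paths`).
#' @export
runPipeline <- function(config, outDir) {
  if (is.character(config)) config <- loadConfig(config)
  for (key in c("relations", "efficacy", "compounds", "universe")) {
    if (is.null(config[[key]]) || !file.exists(config[[key]]))
      stop("missing input file for '", key, "': ",
           if (is.null(config[[key]])) "(not set)" else config[[key]])
  }
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  message("[network] parsing relations from ", config$relations)
  edges <- readRelations(config$relations,
                         rbSecondBroader = config$rb_second_broader)
  network <- weightEdges(buildNetwork(edges))
  writeNetwork(network, file.path(outDir, "network.tsv"))
  universe <- readUniverse(config$universe)
  profiles <- readEfficacy(config$efficacy)
  message("[vectors] ", length(profiles), " plants, universe of ",
          length(universe), " phenotypes")
  X <- if (config$use_hierarchy)
    phenotypeVectors(network, profiles, universe, r = config$r,
                     tol = config$tol)
  else
    ablationVectors(profiles, universe)
  writeMatrixTSV(X, file.path(outDir, "phenotype_matrix.tsv"))
  message("[cluster] bootstrap with ", config$n_boot,
          " resamples x ", length(config$scales), " scales")
  hc <- plantDendrogram(X, linkage = config$linkage)
  exportNewick(hc, file.path(outDir, "dendrogram.nwk"))
  support <- multiscaleBootstrap(X, nBoot = config$n_boot,
                                 scales = config$scales,
                                 seed = config$seed,
                                 linkage = config$linkage)
  clusters <- pickClusters(hc, support, threshold = config$au_threshold)
  message("[cluster] ", nrow(clusters), " supported cluster(s)")
  writeClusters(clusters, file.path(outDir, "clusters.tsv"))
  catalog <- readCatalog(config$compounds)
  allPlants <- sort(union(names(catalog), rownames(X)))
  enriched <- enrichedCompounds(clusters, catalog,
                                alpha = config$fisher_alpha,
                                allPlants = allPlants,
                                alternative = config$fisher_sidedness)
  message("[enrich] ", nrow(enriched), " enriched (cluster, compound) pairs")
  write.table(enriched, file.path(outDir, "enrichment.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  predictions <- NULL; associations <- NULL; evaluation <- NULL
  if (nrow(enriched)) {
    predictions <- predictEffects(enriched, X, clusters,
                                  combine = config$multi_cluster_combine)
    writeMatrixTSV(predictions$scores,
                   file.path(outDir, "predictions.tsv"))
    associations <- filterEffects(predictions,
                                  cutoff = config$effect_cutoff)
    write.table(associations, file.path(outDir, "associations.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(config$gold) && file.exists(config$gold)) {
      gold <- readGoldStandard(config$gold)
      evaluation <- list(
        by_compound = averagedMetrics(predictions$scores, gold,
                                      axis = "compound"),
        by_phenotype = averagedMetrics(predictions$scores, gold,
                                       axis = "phenotype"),
        f1 = f1Scan(predictions$scores, gold))
      evalOut <- list(
        by_compound = evaluation$by_compound[
          c("auroc_mean", "auroc_sd", "aupr_mean", "aupr_sd",
            "n_units", "n_skipped")],
        by_phenotype = evaluation$by_phenotype[
          c("auroc_mean", "auroc_sd", "aupr_mean", "aupr_sd",
            "n_units", "n_skipped")],
        f1_best_threshold = evaluation$f1$best)
      jsonlite::write_json(evalOut, file.path(outDir, "evaluation.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
  }
  manifest <- list(
    config = config[setdiff(names(config), character())],
    package_version = as.character(utils::packageVersion("HerbPhenoNet")),
    counts = list(
      concepts = length(concepts(network)),
      plants = nrow(X),
      universe = ncol(X),
      clusters = nrow(clusters),
      enriched_pairs = nrow(enriched),
      associations = if (is.null(associations)) 0L else nrow(associations)))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(network = network, matrix = X, dendrogram = hc,
                 support = support, clusters = clusters,
                 enriched = enriched, predictions = predictions,
                 associations = associations, evaluation = evaluation,
                 paths = outDir))
}
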