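#' Recovery report of a pipeline run against planted truth
#'
#' Measures how well a pipeline run on a [SyntheticWorld-class]
#' recovered the planted structure: the fraction of themes returned as
#' selected clusters with exactly the theme's plant set, the fraction of
#' theme compounds significantly enriched in a selected cluster, and the
#' mean per-compound AUROC/AUPR of the predicted effect scores against
#' the planted compound-to-phenotype truth. Theme compounds that were
#' never enriched still enter the ranking evaluation with an all-zero
#' score vector (an uninformative ranking, AUROC 0.5), so dropped
#' compounds are penalised rather than skipped.
#'
#' @param world the [SyntheticWorld-class] the pipeline ran on.
#' @param clusters selected clusters from [pickClusters()].
#' @param enriched enrichment table from [enrichedCompounds()].
#' @param predictions result of [predictEffects()] (or `NULL` when
#'   nothing was enriched).
#' @return list with `theme_recovery`, `compound_enrichment`,
#'   `mean_auroc`, `mean_aupr` (and the per-compound table
#'   `per_compound`).
#' @export
recoveryReport <- function(world, clusters, enriched, predictions) {
  themes <- world@themes
  themeSets <- lapply(themes, function(t) sort(t$plants))
  exact <- vapply(themeSets, function(tp)
    any(vapply(clusters$members, identical, logical(1), tp)), logical(1))
  themeCompounds <- names(world@truth)
  enrichedIds <- unique(enriched$compound_id)
  hit <- themeCompounds %in% enrichedIds
  universe <- world@universe
  scores <- matrix(0, nrow = length(themeCompounds),
                   ncol = length(universe),
                   dimnames = list(themeCompounds, universe))
  if (!is.null(predictions)) {
    got <- intersect(rownames(predictions$scores), themeCompounds)
    scores[got, ] <- predictions$scores[got, universe, drop = FALSE]
  }
  perCompound <- do.call(rbind, lapply(themeCompounds, function(cmp) {
    pos <- intersect(world@truth[[cmp]], universe)
    data.frame(compound_id = cmp,
               enriched = cmp %in% enrichedIds,
               auroc = aurocScore(scores[cmp, ], pos),
               aupr = auprScore(scores[cmp, ], pos),
               stringsAsFactors = FALSE)
  }))
  list(theme_recovery = mean(exact),
       compound_enrichment = mean(hit),
       mean_auroc = mean(perCompound$auroc),
       mean_aupr = mean(perCompound$aupr),
       per_compound = perCompound)
}

#' Run the analysis pipeline in memory on a synthetic world
#'
#' Convenience wrapper chaining [phenotypeVectors()] (or
#' [ablationVectors()]), [plantDendrogram()], [multiscaleBootstrap()],
#' [pickClusters()], [enrichedCompounds()] and [predictEffects()] on an
#' in-memory [SyntheticWorld-class], without touching the filesystem.
#'
#' @param world a [SyntheticWorld-class].
#' @param nBoot bootstrap resamples per scale.
#' @param seed seed for the bootstrap resampling.
#' @param useHierarchy `FALSE` switches to the binary ablation vectors.
#' @param auThreshold,alpha,combine thresholds as in [pipelineConfig()].
#' @param r,tol RWR parameters.
#' @return list with `matrix`, `dendrogram`, `support`, `clusters`,
#'   `enriched`, `predictions`, `report` (a [recoveryReport()]).
#' @export
runSyntheticPipeline <- function(world, nBoot = 1000L, seed = 1L,
                                 useHierarchy = TRUE, auThreshold = 0.95,
                                 alpha = 0.001, combine = "max",
                                 r = 0.7, tol = 1e-8) {
  X <- if (useHierarchy)
    phenotypeVectors(world@network, world@profiles, world@universe,
                     r = r, tol = tol)
  else
    ablationVectors(world@profiles, world@universe)
  hc <- plantDendrogram(X)
  support <- multiscaleBootstrap(X, nBoot = nBoot, seed = seed)
  clusters <- pickClusters(hc, support, threshold = auThreshold)
  enriched <- enrichedCompounds(clusters, world@catalog, alpha = alpha,
                                allPlants = names(world@catalog))
  predictions <- if (nrow(enriched))
    predictEffects(enriched, X, clusters, combine = combine) else NULL
  list(matrix = X, dendrogram = hc, support = support,
       clusters = clusters, enriched = enriched,
       predictions = predictions,
       report = recoveryReport(world, clusters, enriched, predictions))
}
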