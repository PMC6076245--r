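#' Precision and recall of a predicted association set
#'
#' @param predicted character vector (or set) of predicted items.
#' @param positives character vector of true-positive items.
#' @param universe item universe; both arguments must lie inside it.
#' @return named numeric `c(precision, recall)`; a ratio with a zero
#'   denominator is reported as 0 with attribute `degenerate` naming it.
#' @export
precisionRecall <- function(predicted, positives, universe) {
  predicted <- unique(predicted); positives <- unique(positives)
  stopifnot(all(predicted %in% universe), all(positives %in% universe))
  tp <- length(intersect(predicted, positives))
  degenerate <- character()
  if (length(predicted) == 0L) degenerate <- c(degenerate, "precision")
  if (length(positives) == 0L) degenerate <- c(degenerate, "recall")
  out <- c(
    precision = if (length(predicted)) tp / length(predicted) else 0,
    recall = if (length(positives)) tp / length(positives) else 0)
  if (length(degenerate)) attr(out, "degenerate") <- degenerate
  out
}

#' Area under the ROC curve of a scored ranking
#'
#' Trapezoidal AUROC, computed as the tie-corrected Mann-Whitney
#' statistic: the probability that a random positive outscores a random
#' negative, ties counting one half.
#'
#' @param scores named numeric vector of prediction scores.
#' @param positives names of the positive items; the rest are negatives.
#' @return AUROC in [0, 1].
#' @export
aurocScore <- function(scores, positives) {
  isPos <- names(scores) %in% positives
  P <- sum(isPos); N <- sum(!isPos)
  if (P == 0L || N == 0L)
    stop("AUROC needs at least one positive and one negative")
  rk <- rank(scores)                      # midranks handle ties
  (sum(rk[isPos]) - P * (P + 1) / 2) / (P * N)
}

#' Area under the precision-recall curve of a scored ranking
#'
#' Non-interpolated step rule: the mean, over the positive items, of the
#' precision at the rank where each is retrieved. Items are ranked by
#' score descending with deterministic lexicographic tie-breaking.
#'
#' @inheritParams aurocScore
#' @return AUPR in (0, 1].
#' @export
auprScore <- function(scores, positives) {
  isPos <- names(scores) %in% positives
  P <- sum(isPos)
  if (P == 0L) stop("AUPR needs at least one positive")
  ord <- order(-scores, names(scores))
  hit <- isPos[ord]
  prec <- cumsum(hit) / seq_along(hit)
  sum(prec[hit]) / P
}

#' Per-compound or per-phenotype averaged ranking metrics
#'
#' Evaluates a prediction score matrix against known associations,
#' ranking within each unit of the chosen axis: per compound, the
#' phenotypes are ranked by that compound's scores; per phenotype, the
#' compounds are ranked by their score on that phenotype. Negatives are
#' all universe items not positive for the unit. Units without at least
#' one positive and one negative are skipped (counted in the report).
#'
#' @param scores compounds x phenotypes score matrix.
#' @param gold data.frame with columns `compound_id`, `concept_id` (and
#'   optionally `label`) of known positive associations.
#' @param axis `"compound"` (default) or `"phenotype"`.
#' @param labels if given, restrict `gold` to these labels.
#' @return list with `auroc_mean`, `auroc_sd`, `aupr_mean`, `aupr_sd`,
#'   `n_units`, `n_skipped` and the per-unit data.frame `per_unit`.
#' @export
averagedMetrics <- function(scores, gold, axis = c("compound", "phenotype"),
                            labels = NULL) {
  axis <- match.arg(axis)
  if (!is.null(labels) && "label" %in% names(gold))
    gold <- gold[gold$label %in% labels, , drop = FALSE]
  gold <- gold[gold$compound_id %in% rownames(scores) &
               gold$concept_id %in% colnames(scores), , drop = FALSE]
  units <- if (axis == "compound") rownames(scores) else colnames(scores)
  rows <- list(); skipped <- 0L
  for (u in units) {
    if (axis == "compound") {
      s <- scores[u, ]
      pos <- gold$concept_id[gold$compound_id == u]
    } else {
      s <- scores[, u]
      pos <- gold$compound_id[gold$concept_id == u]
    }
    pos <- unique(pos)
    if (length(pos) == 0L || length(pos) == length(s)) {
      skipped <- skipped + 1L
      next
    }
    rows[[u]] <- data.frame(
      unit = u,
      auroc = aurocScore(s, pos),
      aupr = auprScore(s, pos),
      n_positives = length(pos),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    stop("no evaluable unit on axis ", axis)
  perUnit <- do.call(rbind, rows)
  rownames(perUnit) <- NULL
  list(auroc_mean = mean(perUnit$auroc), auroc_sd = sd(perUnit$auroc),
       aupr_mean = mean(perUnit$aupr), aupr_sd = sd(perUnit$aupr),
       n_units = nrow(perUnit), n_skipped = skipped, per_unit = perUnit)
}

#' F1 scan over score cutoffs
#'
#' Binarizes the prediction matrix at each threshold and computes the F1
#' measure (harmonic mean of precision and recall) against the known
#' associations; reports the full curve and the best cutoff (smallest
#' threshold on ties).
#'
#' @inheritParams averagedMetrics
#' @param thresholds score cutoffs to scan (default `seq(0, 0.95,
#'   by = 0.05)`).
#' @return list with `best` (the arg-max threshold) and `table`
#'   (data.frame `threshold`, `precision`, `recall`, `f1`).
#' @export
f1Scan <- function(scores, gold, thresholds = seq(0, 0.95, by = 0.05)) {
  gold <- gold[gold$compound_id %in% rownames(scores) &
               gold$concept_id %in% colnames(scores), , drop = FALSE]
  posIdx <- cbind(match(gold$compound_id, rownames(scores)),
                  match(gold$concept_id, colnames(scores)))
  posIdx <- posIdx[!duplicated(posIdx), , drop = FALSE]
  nPos <- nrow(posIdx)
  if (nPos == 0L) stop("no gold-standard pair maps onto the score matrix")
  posScores <- scores[posIdx]
  rows <- lapply(thresholds, function(t) {
    nPred <- sum(scores >= t)
    tp <- sum(posScores >= t)
    prec <- if (nPred) tp / nPred else 0
    rec <- tp / nPos
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    data.frame(threshold = t, precision = prec, recall = rec, f1 = f1)
  })
  tab <- do.call(rbind, rows)
  list(best = tab$threshold[which.max(tab$f1)], table = tab)
}

#' Spearman rank correlation between two scored lists
#'
#' Ranks are compared on the items shared by both lists, ties midranked.
#'
#' @param scoresA,scoresB named numeric score vectors.
#' @return Spearman correlation in [-1, 1].
#' @export
rankCorrelation <- function(scoresA, scoresB) {
  shared <- intersect(names(scoresA), names(scoresB))
  if (length(shared) < 2L)
    stop("rank correlation needs at least two shared items")
  cor(scoresA[shared], scoresB[shared], method = "spearman")
}

.topSet <- function(scores, fraction) {
  k <- max(1L, floor(fraction * length(scores)))
  names(scores)[order(-scores, names(scores))][seq_len(k)]
}

#' Tanimoto overlap of two methods' top predictions
#'
#' Extracts the top `fraction` of items from each score vector
#' (deterministic tie-breaking) and returns
#' \eqn{T_c = |A \cap B| / |A \cup B|}. For two score matrices the
#' coefficient is computed per shared row (compound) and reported as
#' mean and sd.
#'
#' @param scoresA,scoresB named numeric vectors over one item universe,
#'   or score matrices with matching column universe.
#' @param fraction the top fraction to extract (default 0.10).
#' @return a single coefficient for vectors; `c(mean, sd)` plus the
#'   per-compound vector (attribute `per_compound`) for matrices.
#' @export
topFractionTanimoto <- function(scoresA, scoresB, fraction = 0.10) {
  stopifnot(fraction > 0, fraction < 1)
  if (is.matrix(scoresA)) {
    shared <- intersect(rownames(scoresA), rownames(scoresB))
    if (length(shared) == 0L) stop("no shared compounds")
    tc <- vapply(shared, function(cmp)
      topFractionTanimoto(scoresA[cmp, ], scoresB[cmp, ], fraction),
      numeric(1))
    out <- c(mean = mean(tc), sd = sd(tc))
    attr(out, "per_compound") <- tc
    return(out)
  }
  shared <- intersect(names(scoresA), names(scoresB))
  if (length(shared) == 0L) stop("no shared items")
  a <- .topSet(scoresA[shared], fraction)
  b <- .topSet(scoresB[shared], fraction)
  length(intersect(a, b)) / length(union(a, b))
}

#' Target-closeness baseline on a protein-interaction network
#'
#' Scores a compound-phenotype pair by the average, over the compound's
#' target genes, of the shortest-path distance to the nearest phenotype
#' gene in the interaction network (restricted to its largest connected
#' component). Significance is assessed by permutation: the fraction of
#' `nPerm` random target-gene sets of the same size achieving an average
#' distance at most the observed one.
#'
#' @param compoundGenes character vector of the compound's target genes.
#' @param phenotypeGenes character vector of the phenotype's genes.
#' @param ppi two-column data.frame (or matrix) of undirected
#'   protein-interaction edges.
#' @param nPerm permutation count (default 1000).
#' @param seed integer seed for the permutation draw.
#' @return list with `distance` (observed average shortest distance),
#'   `p_value`, and the gene counts actually mapped.
#' @export
targetCloseness <- function(compoundGenes, phenotypeGenes, ppi,
                            nPerm = 1000L, seed = 1L) {
  g <- igraph::graph_from_data_frame(ppi[, 1:2], directed = FALSE)
  comp <- igraph::components(g)
  keep <- names(comp$membership)[comp$membership == which.max(comp$csize)]
  g <- igraph::induced_subgraph(g, keep)
  vs <- igraph::V(g)$name
  cg <- intersect(unique(compoundGenes), vs)
  pg <- intersect(unique(phenotypeGenes), vs)
  if (length(cg) == 0L || length(pg) == 0L)
    stop("gene set(s) do not map onto the network's largest component")
  D <- igraph::distances(g, v = cg, to = pg)
  obs <- mean(apply(D, 1, min))
  set.seed(seed)
  permD <- igraph::distances(g, v = vs, to = pg)
  minTo <- apply(permD, 1, min)
  permScores <- vapply(seq_len(nPerm), function(i)
    mean(minTo[sample.int(length(vs), length(cg))]), numeric(1))
  list(distance = obs, p_value = mean(permScores <= obs),
       n_compound_genes = length(cg), n_phenotype_genes = length(pg))
}
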