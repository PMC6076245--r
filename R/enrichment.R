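#' Contingency table of a compound in a plant cluster
#'
#' Counts plants by cluster membership and compound presence:
#' `a` in-cluster plants containing the compound, `b` in-cluster plants
#' lacking it, `c` out-of-cluster plants containing it, `d` the rest.
#'
#' @param members character vector of in-cluster plant ids.
#' @param compoundId the compound to count.
#' @param catalog named list: plant id -> character vector of compounds.
#' @param allPlants character vector of every plant id in the analysis
#'   (defaults to `names(catalog)`).
#' @return named integer vector `c(a, b, c, d)`.
#' @export
contingencyTable <- function(members, compoundId, catalog,
                             allPlants = names(catalog)) {
  stopifnot(all(members %in% allPlants))
  has <- vapply(allPlants, function(p)
    compoundId %in% catalog[[p]], logical(1))
  if (!any(has))
    stop("compound ", compoundId, " is absent from the catalog")
  inC <- allPlants %in% members
  c(a = sum(inC & has), b = sum(inC & !has),
    c = sum(!inC & has), d = sum(!inC & !has))
}

#' Fisher's exact test for compound enrichment
#'
#' One-sided (enrichment) exact test on a 2x2 contingency table: the
#' hypergeometric upper-tail probability \eqn{P(X \ge a)} with
#' \eqn{X \sim \mathrm{Hypergeom}(N = a+b+c+d,\, K = a+c,\, n = a+b)}.
#' The two-sided alternative (which would also flag depletion) is
#' available for comparison.
#'
#' @param a,b,c,d non-negative integer cell counts, or `a` may be the
#'   4-vector from [contingencyTable()].
#' @param alternative `"greater"` (default, enrichment) or
#'   `"two.sided"`.
#' @return the p-value, in (0, 1].
#' @examples
#' fisherExact(3, 1, 1, 3)   # 17/70
#' @export
fisherExact <- function(a, b = NULL, c = NULL, d = NULL,
                        alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (length(a) == 4L && is.null(b)) {
    d <- a[[4]]; c <- a[[3]]; b <- a[[2]]; a <- a[[1]]
  }
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  if (alternative == "two.sided") {
    tab <- matrix(c(a, b, c, d), nrow = 2)
    return(stats::fisher.test(tab, alternative = "two.sided")$p.value)
  }
  # P(X >= a), X ~ Hypergeom(N, K = a + c, draws n = a + b)
  phyper(a - 1, m = a + c, n = b + d, k = a + b, lower.tail = FALSE)
}

#' Compounds significantly enriched in plant clusters
#'
#' Tests, for every selected cluster, each compound present in at least
#' one member plant, and keeps those with a Fisher p-value below `alpha`.
#' Raw p-values are used (no multiplicity correction): the significance
#' level is treated as a tuned selection threshold, not an error rate.
#'
#' @param clusters data.frame from [pickClusters()] (needs `cluster_id`
#'   and list-column `members`).
#' @param catalog named list: plant id -> compounds.
#' @param alpha p-value threshold (default 0.001).
#' @param allPlants plant universe (defaults to `names(catalog)`).
#' @param alternative sidedness passed to [fisherExact()].
#' @return data.frame `(cluster_id, compound_id, a, b, c, d, p_value)`
#'   with one row per surviving (cluster, compound) pair, ordered by
#'   cluster then p-value.
#' @export
enrichedCompounds <- function(clusters, catalog, alpha = 0.001,
                              allPlants = names(catalog),
                              alternative = "greater") {
  rows <- list()
  for (i in seq_len(nrow(clusters))) {
    members <- clusters$members[[i]]
    inCluster <- sort(unique(unlist(catalog[members], use.names = FALSE)))
    for (cmp in inCluster) {
      tab <- contingencyTable(members, cmp, catalog, allPlants)
      p <- fisherExact(tab, alternative = alternative)
      if (p < alpha)
        rows[[length(rows) + 1L]] <- data.frame(
          cluster_id = clusters$cluster_id[i], compound_id = cmp,
          a = tab[["a"]], b = tab[["b"]], c = tab[["c"]], d = tab[["d"]],
          p_value = p, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(cluster_id = character(), compound_id = character(),
                      a = integer(), b = integer(), c = integer(),
                      d = integer(), p_value = numeric(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(out$cluster_id, out$p_value, out$compound_id), ]
  rownames(out) <- NULL
  out
}

#' Predicted pharmacological effects of enriched compounds
#'
#' Each enriched compound inherits the arithmetic mean of the phenotype
#' vectors of its cluster's member plants. A compound enriched in
#' several clusters combines the cluster means element-wise by `max`
#' (default, preserving every cluster's signal) or `mean`.
#'
#' @param enriched data.frame from [enrichedCompounds()].
#' @param X phenotype matrix (plants x universe) covering all members.
#' @param clusters the cluster data.frame from [pickClusters()].
#' @param combine how to merge multiple cluster means per compound.
#' @return list with `scores` (compounds x universe matrix, values in
#'   [0, 1]) and `clusters` (named list: compound -> contributing
#'   cluster ids).
#' @export
predictEffects <- function(enriched, X, clusters,
                           combine = c("max", "mean")) {
  combine <- match.arg(combine)
  clusterMeans <- list()
  for (i in seq_len(nrow(clusters))) {
    members <- clusters$members[[i]]
    miss <- setdiff(members, rownames(X))
    if (length(miss))
      stop("cluster member(s) missing from the phenotype matrix: ",
           paste(miss, collapse = ", "))
    clusterMeans[[clusters$cluster_id[i]]] <-
      colMeans(X[members, , drop = FALSE])
  }
  compoundIds <- sort(unique(enriched$compound_id))
  scores <- matrix(0, nrow = length(compoundIds), ncol = ncol(X),
                   dimnames = list(compoundIds, colnames(X)))
  contrib <- setNames(vector("list", length(compoundIds)), compoundIds)
  for (cmp in compoundIds) {
    cids <- enriched$cluster_id[enriched$compound_id == cmp]
    mat <- do.call(rbind, clusterMeans[cids])
    scores[cmp, ] <- if (combine == "max") apply(mat, 2, max)
                     else colMeans(mat)
    contrib[[cmp]] <- cids
  }
  list(scores = scores, clusters = contrib)
}

#' Filter predicted effects by score cutoff
#'
#' Flattens a prediction score matrix into the (compound, phenotype,
#' score) pairs at or above the cutoff, sorted by score descending with
#' deterministic (compound, phenotype) tie-breaking.
#'
#' @param predictions the list from [predictEffects()], or a bare score
#'   matrix.
#' @param cutoff minimum phenotype score to keep (default 0.20, the
#'   F1-optimal operating point of the effect-score scale).
#' @return data.frame `(compound_id, concept_id, score)`.
#' @export
filterEffects <- function(predictions, cutoff = 0.20) {
  S <- if (is.list(predictions)) predictions$scores else predictions
  keep <- which(S >= cutoff, arr.ind = TRUE)
  out <- data.frame(
    compound_id = rownames(S)[keep[, 1]],
    concept_id = colnames(S)[keep[, 2]],
    score = S[keep],
    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$compound_id, out$concept_id), ]
  rownames(out) <- NULL
  out
}
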