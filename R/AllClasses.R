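#' @import methods
#' @importFrom stats as.dist cor dnorm hclust pnorm qnorm phyper setNames sd
#' @importFrom utils read.table write.table head
NULL

#' PhenotypeNetwork: a rooted DAG of phenotype concepts
#'
#' Holds the concept hierarchy used for semantic-similarity weighting and
#' network propagation. Concepts are opaque string identifiers (CUI-like
#' tokens); hierarchy edges point from the broader concept (parent) to the
#' narrower one (child). After [weightEdges()] each edge carries the
#' Wu-Palmer similarity of its endpoints, used as the propagation weight.
#'
#' @slot concepts character vector of concept identifiers (unique).
#' @slot edges data.frame with columns `parent`, `child`, `weight`
#'   (`weight` is `NA` until [weightEdges()] is applied).
#' @slot root identifier of the root concept; a virtual root is inserted
#'   when the input hierarchy has several parentless concepts.
#' @slot virtualRoot logical, `TRUE` if the root was synthesised.
#' @slot depths named integer vector: shortest root-to-concept path length
#'   counted in nodes, so `depths[root] == 1L`.
#' @slot childIndex,parentIndex named lists mapping each concept to its
#'   children / parents (adjacency, precomputed for traversal).
#'
#' @seealso [buildNetwork()], [wupSimilarity()], [transitionMatrix()]
#' @export
setClass("PhenotypeNetwork",
  representation(
    concepts = "character",
    edges = "data.frame",
    root = "character",
    virtualRoot = "logical",
    depths = "integer",
    childIndex = "list",
    parentIndex = "list"
  )
)

setValidity("PhenotypeNetwork", function(object) {
  msg <- character()
  if (anyDuplicated(object@concepts))
    msg <- c(msg, "concept identifiers must be unique")
  if (length(object@root) != 1L || !object@root %in% object@concepts)
    msg <- c(msg, "root must be a single concept of the network")
  e <- object@edges
  if (!all(c("parent", "child", "weight") %in% names(e)))
    msg <- c(msg, "edges must have columns parent, child, weight")
  else {
    if (any(e$parent == e$child))
      msg <- c(msg, "self-edges are not allowed")
    bad <- !e$parent %in% object@concepts | !e$child %in% object@concepts
    if (any(bad))
      msg <- c(msg, "edge endpoints must be network concepts")
    w <- e$weight[!is.na(e$weight)]
    if (length(w) && (any(w <= 0) || any(w > 1)))
      msg <- c(msg, "edge weights must lie in (0, 1]")
  }
  if (!all(object@concepts %in% names(object@depths)))
    msg <- c(msg, "every concept needs a depth entry")
  if (length(msg)) msg else TRUE
})

#' ClusterSupport: multiscale bootstrap support for a dendrogram
#'
#' Per internal node of a plant dendrogram, the bootstrap probability (BP)
#' observed at each resampling scale and the approximately unbiased (AU)
#' p-value extrapolated from them by the two-parameter normal-quantile fit.
#'
#' @slot bp numeric matrix, internal nodes x scales; entry = fraction of
#'   resampled dendrograms containing the node's exact member set.
#' @slot scales numeric vector of scale factors (resample size =
#'   `round(scale * P)` columns).
#' @slot nBoot integer, resamples per scale.
#' @slot au numeric vector of AU p-values, one per internal node.
#' @slot fitError weighted residual sum of squares of each z-fit.
#' @slot flags per-node fit flag: `""` (regular fit), `"upper"`/`"lower"`
#'   (all BP values at a clamp bound, AU set to that bound's limit).
#' @slot members list of sorted member-label vectors per internal node.
#'
#' @seealso [multiscaleBootstrap()], [auFit()], [pickClusters()]
#' @export
setClass("ClusterSupport",
  representation(
    bp = "matrix",
    scales = "numeric",
    nBoot = "integer",
    au = "numeric",
    fitError = "numeric",
    flags = "character",
    members = "list"
  )
)

setValidity("ClusterSupport", function(object) {
  msg <- character()
  if (ncol(object@bp) != length(object@scales))
    msg <- c(msg, "bp must have one column per scale")
  if (nrow(object@bp) != length(object@members))
    msg <- c(msg, "bp must have one row per internal node")
  if (length(object@au) && any(!is.na(object@au) &
      (object@au < 0 | object@au > 1)))
    msg <- c(msg, "AU p-values must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' SyntheticWorld: a generated ontology, plants, compounds and truth
#'
#' A self-contained synthetic dataset with planted structure: a complete
#' rooted phenotype tree, `K` latent efficacy themes (disjoint subtrees),
#' plants annotated from their theme with noise, theme compounds present
#' preferentially in theme plants, background compounds, and the planted
#' compound-to-phenotype ground truth.
#'
#' @slot network the [PhenotypeNetwork-class] (weighted).
#' @slot universe character vector, ordered phenotype universe (all
#'   non-root concepts).
#' @slot profiles named list: plant id -> character vector of annotated
#'   efficacy concepts.
#' @slot catalog named list: plant id -> character vector of compounds.
#' @slot truth named list: theme compound id -> planted effect phenotypes
#'   (its theme's subtree).
#' @slot themes list of per-theme descriptors (subtree root, phenotypes,
#'   plants, compounds).
#' @slot params the generating parameter list (see [synthParams()]).
#'
#' @seealso [simulateWorld()]
#' @export
setClass("SyntheticWorld",
  representation(
    network = "PhenotypeNetwork",
    universe = "character",
    profiles = "list",
    catalog = "list",
    truth = "list",
    themes = "list",
    params = "list"
  )
)

setValidity("SyntheticWorld", function(object) {
  msg <- character()
  if (!all(object@universe %in% object@network@concepts))
    msg <- c(msg, "universe must be a subset of network concepts")
  if (any(lengths(object@profiles) == 0L))
    msg <- c(msg, "every plant must carry at least one annotation")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PhenotypeNetwork", function(object) {
  cat("PhenotypeNetwork with", length(object@concepts), "concepts and",
      nrow(object@edges), "hierarchy edges\n")
  cat("  root:", object@root,
      if (object@virtualRoot) "(virtual)" else "", "\n")
  cat("  max depth:", max(object@depths), "\n")
  cat("  weighted:", !anyNA(object@edges$weight), "\n")
})

setMethod("show", "ClusterSupport", function(object) {
  cat("ClusterSupport for", nrow(object@bp), "internal nodes,",
      length(object@scales), "scales,", object@nBoot, "resamples/scale\n")
  if (length(object@au) && !anyNA(object@au))
    cat("  AU >= 0.95 at", sum(object@au >= 0.95), "nodes\n")
  else
    cat("  AU p-values not yet fitted (run auFit)\n")
})

setMethod("show", "SyntheticWorld", function(object) {
  cat("SyntheticWorld:", length(object@profiles), "plants,",
      length(object@themes), "themes,",
      length(unique(unlist(object@catalog))), "compounds,",
      length(object@universe), "universe phenotypes\n")
})

#' @describeIn PhenotypeNetwork-class concept identifiers of a network.
#' @param object a `PhenotypeNetwork`
#' @export
setGeneric("concepts", function(object) standardGeneric("concepts"))

#' @describeIn PhenotypeNetwork-class the root concept identifier.
#' @export
setGeneric("rootConcept", function(object) standardGeneric("rootConcept"))

#' @describeIn PhenotypeNetwork-class hierarchy edges as a data.frame
#'   (parent, child, weight).
#' @export
setGeneric("hierarchyEdges", function(object) standardGeneric("hierarchyEdges"))

#' @describeIn ClusterSupport-class AU p-values per internal node.
#' @export
setGeneric("auValues", function(object) standardGeneric("auValues"))

#' @describeIn ClusterSupport-class BP matrix (nodes x scales).
#' @export
setGeneric("bpValues", function(object) standardGeneric("bpValues"))

#' @describeIn ClusterSupport-class member label sets per internal node.
#' @export
setGeneric("nodeMembers", function(object) standardGeneric("nodeMembers"))

#' @describeIn SyntheticWorld-class the ordered phenotype universe.
#' @export
setGeneric("phenotypeUniverse",
           function(object) standardGeneric("phenotypeUniverse"))

#' @describeIn SyntheticWorld-class plant efficacy profiles (named list).
#' @export
setGeneric("plantProfiles", function(object) standardGeneric("plantProfiles"))

#' @describeIn SyntheticWorld-class plant-to-compound catalog (named list).
#' @export
setGeneric("compoundCatalog",
           function(object) standardGeneric("compoundCatalog"))

#' @describeIn SyntheticWorld-class planted compound-to-phenotype truth.
#' @export
setGeneric("plantedTruth", function(object) standardGeneric("plantedTruth"))

setMethod("concepts", "PhenotypeNetwork", function(object) object@concepts)
setMethod("rootConcept", "PhenotypeNetwork", function(object) object@root)
setMethod("hierarchyEdges", "PhenotypeNetwork", function(object) object@edges)
setMethod("auValues", "ClusterSupport", function(object) object@au)
setMethod("bpValues", "ClusterSupport", function(object) object@bp)
setMethod("nodeMembers", "ClusterSupport", function(object) object@members)
setMethod("phenotypeUniverse", "SyntheticWorld",
          function(object) object@universe)
setMethod("plantProfiles", "SyntheticWorld", function(object) object@profiles)
setMethod("compoundCatalog", "SyntheticWorld", function(object) object@catalog)
setMethod("plantedTruth", "SyntheticWorld", function(object) object@truth)
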