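#' Cosine distance between two vectors
#'
#' \eqn{1 - u \cdot v / (\|u\| \|v\|)}; ranges over [0, 2] and is 0
#' exactly for positive scalar multiples. Zero vectors have no direction
#' and are rejected.
#'
#' @param u,v numeric vectors of equal length.
#' @return the cosine distance.
#' @export
cosineDistance <- function(u, v) {
  stopifnot(length(u) == length(v))
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0)
    stop("cosine distance is undefined for a zero vector")
  1 - sum(u * v) / (nu * nv)
}

# Pairwise cosine distance of matrix rows. zero = "error" rejects
# zero-norm rows; zero = "neutral" places them at distance 1 from
# everything (used inside column resampling, where a row can lose all
# its support).
.cosineDistMatrix <- function(X, zero = c("error", "neutral")) {
  zero <- match.arg(zero)
  nrm <- sqrt(rowSums(X^2))
  if (any(nrm == 0)) {
    if (zero == "error")
      stop("cosine distance is undefined for zero rows: ",
           paste(head(rownames(X)[nrm == 0], 5), collapse = ", "))
    nrm[nrm == 0] <- Inf   # unit-free row: similarity 0 to everything
  }
  S <- tcrossprod(X / nrm)
  D <- 1 - S
  diag(D) <- 0
  D[D < 0] <- 0
  as.dist(D)
}

#' Hierarchical clustering of plant phenotype vectors
#'
#' Agglomerative clustering of the rows of a phenotype matrix on cosine
#' distance, average linkage by default (the support machinery assumes
#' the same linkage when reclustering resamples).
#'
#' @param X numeric matrix, plants (rows) x phenotypes (columns); row
#'   names identify plants.
#' @param linkage agglomeration method passed to [stats::hclust()].
#' @return an object of class `hclust`.
#' @export
plantDendrogram <- function(X, linkage = "average") {
  stopifnot(is.matrix(X), nrow(X) >= 2L)
  if (is.null(rownames(X)))
    rownames(X) <- paste0("row", seq_len(nrow(X)))
  hclust(.cosineDistMatrix(X, zero = "error"), method = linkage)
}

# member leaf-index sets of the n-1 internal nodes, each sorted
.mergeMembers <- function(merge) {
  n1 <- nrow(merge)
  out <- vector("list", n1)
  for (i in seq_len(n1)) {
    m <- merge[i, ]
    left <- if (m[1] < 0) -m[1] else out[[m[1]]]
    right <- if (m[2] < 0) -m[2] else out[[m[2]]]
    out[[i]] <- sort(c(left, right))
  }
  out
}

.memberKeys <- function(merge) {
  vapply(.mergeMembers(merge), paste, character(1), collapse = ",")
}

#' Multiscale bootstrap support for a plant dendrogram
#'
#' For each scale factor `s`, draws `nBoot` resamples of
#' `round(s * ncol(X))` phenotype columns with replacement, reclusters
#' the plants, and records per internal node of the observed dendrogram
#' the fraction of resampled dendrograms containing the identical member
#' set (the bootstrap probability, BP). Varying the resample size across
#' scales is what lets [auFit()] remove the bootstrap's size bias.
#'
#' All randomness derives from `seed`; per-scale substreams are drawn
#' deterministically so scales can be reproduced independently. Scales
#' whose resample size would fall below 2 columns are skipped with a
#' message.
#'
#' @param X phenotype matrix (plants x phenotypes).
#' @param nBoot resamples per scale (default 1000).
#' @param scales numeric vector of scale factors (default `seq(0.5, 1.4,
#'   by = 0.1)`).
#' @param seed integer seed governing all resampling (required).
#' @param linkage agglomeration method (must match the dendrogram's).
#' @return a [ClusterSupport-class] with the BP matrix filled and AU
#'   p-values fitted via [auFit()].
#' @export
multiscaleBootstrap <- function(X, nBoot = 1000L,
                                scales = seq(0.5, 1.4, by = 0.1),
                                seed, linkage = "average") {
  stopifnot(is.matrix(X), nrow(X) >= 2L, nBoot >= 1L)
  if (missing(seed)) stop("a seed is required for reproducible resampling")
  P <- ncol(X)
  sizes <- round(scales * P)
  usable <- sizes >= 2L
  if (any(!usable))
    message("multiscaleBootstrap: skipped scale(s) ",
            paste(scales[!usable], collapse = ", "),
            " (resample size < 2)")
  scales <- scales[usable]; sizes <- sizes[usable]
  if (length(scales) < 2L)
    stop("need at least two usable scales for the AU fit")
  hc <- plantDendrogram(X, linkage = linkage)
  origKeys <- .memberKeys(hc$merge)
  members <- lapply(.mergeMembers(hc$merge),
                    function(ix) sort(rownames(X)[ix]))
  set.seed(seed)
  scaleSeeds <- sample.int(2147483646L, length(scales))
  bp <- matrix(0, nrow = length(origKeys), ncol = length(scales),
               dimnames = list(NULL, paste0("s", scales)))
  for (k in seq_along(scales)) {
    set.seed(scaleSeeds[k])
    counts <- numeric(length(origKeys))
    for (b in seq_len(nBoot)) {
      idx <- sample.int(P, sizes[k], replace = TRUE)
      d <- .cosineDistMatrix(X[, idx, drop = FALSE], zero = "neutral")
      bootKeys <- .memberKeys(hclust(d, method = linkage)$merge)
      counts <- counts + (origKeys %in% bootKeys)
    }
    bp[, k] <- counts / nBoot
  }
  support <- new("ClusterSupport", bp = bp, scales = scales,
                 nBoot = as.integer(nBoot),
                 au = rep(NA_real_, length(origKeys)),
                 fitError = rep(NA_real_, length(origKeys)),
                 flags = rep("", length(origKeys)),
                 members = members)
  auFit(support)
}

#' Fit an AU p-value from a bootstrap probability curve
#'
#' Transforms the per-scale bootstrap probabilities to normal quantiles,
#' \eqn{z_s = \Phi^{-1}(1 - bp_s)}, and fits the two-parameter model
#' \eqn{z_s = v \sqrt{s} + c / \sqrt{s}} by weighted least squares, the
#' weights coming from the binomial variance of each BP estimate. The
#' approximately unbiased p-value is \eqn{AU = 1 - \Phi(v - c)}: the
#' extrapolation to scale \eqn{-1} that removes the bootstrap's
#' sample-size bias. BP values are clamped to
#' \eqn{[1/(B+1),\; B/(B+1)]} to keep the quantile transform finite; a
#' curve stuck entirely at one clamp bound cannot be fitted and gets
#' that bound's limit as its AU, with a flag.
#'
#' @param bp numeric vector of bootstrap probabilities per scale, or a
#'   [ClusterSupport-class] (then every node is fitted).
#' @param scales scale factors matching `bp`.
#' @param nBoot resamples per scale.
#' @return for a vector: a list with `au`, `v`, `c`, `fitError`, `flag`.
#'   For a `ClusterSupport`: the object with `au`, `fitError`, `flags`
#'   filled.
#' @export
auFit <- function(bp, scales = NULL, nBoot = NULL) {
  if (is(bp, "ClusterSupport")) {
    obj <- bp
    for (i in seq_len(nrow(obj@bp))) {
      f <- auFit(obj@bp[i, ], scales = obj@scales, nBoot = obj@nBoot)
      obj@au[i] <- f$au
      obj@fitError[i] <- f$fitError
      obj@flags[i] <- f$flag
    }
    validObject(obj)
    return(obj)
  }
  stopifnot(length(bp) == length(scales), length(bp) >= 2L, nBoot >= 1L)
  lo <- 1 / (nBoot + 1); hi <- nBoot / (nBoot + 1)
  bpc <- pmin(pmax(bp, lo), hi)
  if (all(bp >= hi))
    return(list(au = hi, v = NA_real_, c = NA_real_,
                fitError = NA_real_, flag = "upper"))
  if (all(bp <= lo))
    return(list(au = lo, v = NA_real_, c = NA_real_,
                fitError = NA_real_, flag = "lower"))
  z <- qnorm(1 - bpc)
  w <- nBoot * dnorm(z)^2 / (bpc * (1 - bpc))   # delta-method 1/Var(z)
  M <- cbind(sqrt(scales), 1 / sqrt(scales))
  fit <- stats::lm.wfit(M, z, w)
  v <- fit$coefficients[1]; cc <- fit$coefficients[2]
  list(au = unname(1 - pnorm(v - cc)), v = unname(v), c = unname(cc),
       fitError = sum(w * fit$residuals^2), flag = "")
}

#' Select significantly supported plant clusters
#'
#' Returns the maximal internal nodes whose AU p-value reaches the
#' threshold: a supported node nested inside a supported ancestor is
#' absorbed by the ancestor, so the selected clusters are mutually
#' disjoint. The root node (all plants) and singleton leaves are never
#' reported.
#'
#' @param hc the observed dendrogram (`hclust`) the support refers to.
#' @param support a fitted [ClusterSupport-class].
#' @param threshold minimum AU p-value (default 0.95).
#' @return data.frame with columns `cluster_id`, `au`, `n_members` and a
#'   list-column `members` of plant-id vectors; zero rows when nothing
#'   reaches the threshold.
#' @export
pickClusters <- function(hc, support, threshold = 0.95) {
  au <- support@au
  if (anyNA(au)) stop("support has unfitted AU values; run auFit() first")
  nInt <- nrow(hc$merge)
  stopifnot(length(au) == nInt)
  parent <- rep(NA_integer_, nInt)
  for (j in seq_len(nInt))
    for (m in hc$merge[j, ]) if (m > 0) parent[m] <- j
  sig <- au >= threshold
  sig[nInt] <- FALSE                       # root carries no information
  maximal <- logical(nInt)
  for (i in seq_len(nInt)) {
    if (!sig[i]) next
    anc <- parent[i]; top <- TRUE
    while (!is.na(anc)) {
      if (sig[anc]) { top <- FALSE; break }
      anc <- parent[anc]
    }
    maximal[i] <- top
  }
  idx <- which(maximal)
  out <- data.frame(
    cluster_id = if (length(idx)) paste0("cluster", seq_along(idx))
                 else character(),
    au = au[idx],
    n_members = lengths(support@members[idx]),
    stringsAsFactors = FALSE
  )
  out$members <- support@members[idx]
  out
}

#' Export a dendrogram in Newick format
#'
#' @param hc an `hclust` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
exportNewick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}
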