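#' Parameters of the synthetic world
#'
#' Assembles and validates the parameter list for [simulateWorld()].
#' The defaults describe a small world with clearly recoverable planted
#' structure: a complete 4-level ternary phenotype tree, five latent
#' efficacy themes (disjoint subtrees), eight plants per theme carrying
#' four theme annotations each with 10% noise, three theme compounds per
#' theme present in 90% of theme plants versus 5% of others, and thirty
#' background compounds at 30% presence everywhere.
#'
#' @param treeDepth number of levels of the complete phenotype tree
#'   (root is level 1).
#' @param branching children per internal node.
#' @param nThemes number of latent efficacy themes (disjoint subtrees).
#' @param plantsPerTheme plants generated per theme.
#' @param annotationsPerPlant efficacy annotations drawn per plant.
#' @param annotationNoise probability that an annotation is replaced by
#'   a uniform draw from the whole universe.
#' @param compoundsPerTheme theme-linked compounds per theme.
#' @param pIn,pOut presence probability of a theme compound in theme /
#'   non-theme plants (`pIn > pOut` for recoverable signal).
#' @param nBackgroundCompounds number of theme-free compounds.
#' @param backgroundPresence presence probability of a background
#'   compound in any plant.
#' @param crossEdgeRate probability of giving a deep concept a second
#'   parent (turns the tree into a DAG; stress-testing only, default 0).
#' @param seed integer master seed; stage substreams (themes, plants,
#'   compounds) are derived from it deterministically.
#' @return named list of validated parameters.
#' @export
synthParams <- function(treeDepth = 4L, branching = 3L, nThemes = 5L,
                        plantsPerTheme = 8L, annotationsPerPlant = 4L,
                        annotationNoise = 0.1, compoundsPerTheme = 3L,
                        pIn = 0.9, pOut = 0.05,
                        nBackgroundCompounds = 30L,
                        backgroundPresence = 0.3,
                        crossEdgeRate = 0, seed = 1L) {
  p <- list(treeDepth = as.integer(treeDepth),
            branching = as.integer(branching),
            nThemes = as.integer(nThemes),
            plantsPerTheme = as.integer(plantsPerTheme),
            annotationsPerPlant = as.integer(annotationsPerPlant),
            annotationNoise = annotationNoise,
            compoundsPerTheme = as.integer(compoundsPerTheme),
            pIn = pIn, pOut = pOut,
            nBackgroundCompounds = as.integer(nBackgroundCompounds),
            backgroundPresence = backgroundPresence,
            crossEdgeRate = crossEdgeRate,
            seed = as.integer(seed))
  if (p$treeDepth < 3L) stop("treeDepth must be at least 3")
  if (p$branching < 2L) stop("branching must be at least 2")
  probs <- c(p$annotationNoise, p$pIn, p$pOut, p$backgroundPresence,
             p$crossEdgeRate)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  counts <- c(p$nThemes, p$plantsPerTheme, p$annotationsPerPlant,
              p$compoundsPerTheme)
  if (any(counts < 1L)) stop("counts must be positive")
  p
}

#' Generate the synthetic phenotype ontology
#'
#' A complete rooted tree with `treeDepth` levels and `branching`
#' children per internal node, concept identifiers assigned level by
#' level (`C0001` is the root). The phenotype universe is every non-root
#' concept. With `crossEdgeRate > 0` some concepts at depth 3 or below
#' gain a second parent from the level above, producing a proper DAG for
#' stress tests.
#'
#' @param params parameter list from [synthParams()].
#' @return list with elements `network` (weighted
#'   [PhenotypeNetwork-class]) and `universe`.
#' @export
makeOntology <- function(params) {
  b <- params$branching
  levels <- lapply(seq_len(params$treeDepth), function(d) b^(d - 1L))
  total <- sum(unlist(levels))
  ids <- sprintf("C%04d", seq_len(total))
  parent <- character(); child <- character()
  offset <- 0L
  for (d in seq_len(params$treeDepth - 1L)) {
    nd <- b^(d - 1L)
    parents <- ids[offset + seq_len(nd)]
    kids <- ids[offset + nd + seq_len(nd * b)]
    parent <- c(parent, rep(parents, each = b))
    child <- c(child, kids)
    offset <- offset + nd
  }
  edges <- data.frame(parent = parent, child = child,
                      stringsAsFactors = FALSE)
  if (params$crossEdgeRate > 0) {
    set.seed(params$seed + 101L)
    depthOf <- setNames(rep(seq_len(params$treeDepth),
                            times = unlist(levels)), ids)
    for (v in ids[depthOf >= 3L]) {
      if (stats::runif(1) < params$crossEdgeRate) {
        cands <- setdiff(ids[depthOf == depthOf[v] - 1L],
                         edges$parent[edges$child == v])
        if (length(cands))
          edges <- rbind(edges, data.frame(
            parent = sample(cands, 1L), child = v,
            stringsAsFactors = FALSE))
      }
    }
  }
  network <- weightEdges(buildNetwork(edges))
  list(network = network, universe = setdiff(ids, ids[1L]))
}

# subtree concepts (root included) below a node
.subtreeConcepts <- function(network, node) {
  seen <- node
  frontier <- node
  while (length(frontier)) {
    kids <- setdiff(
      unique(unlist(network@childIndex[frontier], use.names = FALSE)), seen)
    seen <- c(seen, kids)
    frontier <- kids
  }
  sort(seen)
}

#' Assign latent efficacy themes to disjoint subtrees
#'
#' Theme subtree roots are drawn (seeded) from the shallowest tree level
#' wide enough to host `nThemes` disjoint subtrees, so themes never
#' overlap. Each theme owns the full phenotype set of its subtree.
#'
#' @param network the synthetic [PhenotypeNetwork-class].
#' @param params parameter list from [synthParams()].
#' @return list of themes, each a list with `id`, `root`, `phenotypes`.
#' @export
plantThemes <- function(network, params) {
  depths <- network@depths
  level <- NA_integer_
  for (d in 2:max(depths)) {
    if (sum(depths == d) >= params$nThemes) { level <- d; break }
  }
  if (is.na(level))
    stop("no tree level is wide enough for ", params$nThemes, " themes")
  candidates <- sort(names(depths)[depths == level])
  set.seed(params$seed + 1L)
  roots <- sort(sample(candidates, params$nThemes))
  lapply(seq_along(roots), function(k)
    list(id = paste0("theme", k), root = roots[k],
         phenotypes = .subtreeConcepts(network, roots[k])))
}

#' Generate plant efficacy profiles from themes
#'
#' Each theme contributes `plantsPerTheme` plants whose annotations are
#' `annotationsPerPlant` concepts drawn uniformly from the theme's
#' subtree -- without replacement while the subtree is large enough, so
#' an annotation profile is a set of distinct concepts, as real efficacy
#' records are. With probability `annotationNoise` each draw is replaced
#' by a uniform draw from the whole universe, after which profiles are
#' deduplicated.
#'
#' @param themes theme list from [plantThemes()].
#' @param universe the phenotype universe.
#' @param params parameter list from [synthParams()].
#' @return list with `profiles` (named list plant -> concepts) and
#'   `themePlants` (named list theme id -> plant ids).
#' @export
makePlants <- function(themes, universe, params) {
  set.seed(params$seed + 2L)
  profiles <- list()
  themePlants <- list()
  idx <- 0L
  for (th in themes) {
    ids <- character(params$plantsPerTheme)
    for (j in seq_len(params$plantsPerTheme)) {
      idx <- idx + 1L
      pid <- sprintf("P%03d", idx)
      ann <- sample(th$phenotypes, params$annotationsPerPlant,
                    replace = params$annotationsPerPlant >
                              length(th$phenotypes))
      noisy <- stats::runif(length(ann)) < params$annotationNoise
      if (any(noisy))
        ann[noisy] <- sample(universe, sum(noisy), replace = TRUE)
      profiles[[pid]] <- sort(unique(ann))
      ids[j] <- pid
    }
    themePlants[[th$id]] <- ids
  }
  list(profiles = profiles, themePlants = themePlants)
}

#' Generate compound composition and planted truth
#'
#' Every theme receives `compoundsPerTheme` compounds, present in each
#' of its plants with probability `pIn` and in every other plant with
#' probability `pOut`; `nBackgroundCompounds` theme-free compounds are
#' present in any plant with probability `backgroundPresence`. The
#' planted truth maps each theme compound to its theme's full phenotype
#' set.
#'
#' @param themes theme list from [plantThemes()].
#' @param plants result of [makePlants()].
#' @param params parameter list from [synthParams()].
#' @return list with `catalog` (named list plant -> compounds) and
#'   `truth` (named list compound -> phenotypes).
#' @export
makeCompounds <- function(themes, plants, params) {
  set.seed(params$seed + 3L)
  allPlants <- names(plants$profiles)
  catalog <- setNames(vector("list", length(allPlants)), allPlants)
  truth <- list()
  for (k in seq_along(themes)) {
    th <- themes[[k]]
    inTheme <- allPlants %in% plants$themePlants[[th$id]]
    for (i in seq_len(params$compoundsPerTheme)) {
      cmp <- sprintf("TC%d_%d", k, i)
      pr <- ifelse(inTheme, params$pIn, params$pOut)
      present <- stats::runif(length(allPlants)) < pr
      for (p in allPlants[present])
        catalog[[p]] <- c(catalog[[p]], cmp)
      truth[[cmp]] <- th$phenotypes
    }
  }
  for (i in seq_len(params$nBackgroundCompounds)) {
    cmp <- sprintf("BG%03d", i)
    present <- stats::runif(length(allPlants)) < params$backgroundPresence
    for (p in allPlants[present])
      catalog[[p]] <- c(catalog[[p]], cmp)
  }
  catalog <- lapply(catalog, function(v) sort(unique(v)))
  list(catalog = catalog, truth = truth)
}

#' Simulate a complete synthetic world
#'
#' Runs [makeOntology()], [plantThemes()], [makePlants()] and
#' [makeCompounds()] under one master seed and packs the result into a
#' [SyntheticWorld-class]. Identical parameters give byte-identical
#' worlds.
#'
#' @param params parameter list from [synthParams()] (or arguments
#'   passed through to it).
#' @param ... used when `params` is missing: forwarded to
#'   [synthParams()].
#' @return a [SyntheticWorld-class].
#' @examples
#' world <- simulateWorld(synthParams(seed = 7))
#' world
#' @export
simulateWorld <- function(params = synthParams(...), ...) {
  ont <- makeOntology(params)
  themes <- plantThemes(ont$network, params)
  plants <- makePlants(themes, ont$universe, params)
  cmp <- makeCompounds(themes, plants, params)
  for (k in seq_along(themes)) {
    themes[[k]]$plants <- plants$themePlants[[themes[[k]]$id]]
    themes[[k]]$compounds <- grep(paste0("^TC", k, "_"), names(cmp$truth),
                                  value = TRUE)
  }
  new("SyntheticWorld", network = ont$network, universe = ont$universe,
      profiles = plants$profiles, catalog = cmp$catalog,
      truth = cmp$truth, themes = themes, params = params)
}

#' Write a synthetic world in the pipeline's input dialects
#'
#' Emits exactly the TSV formats the real pipeline reads: a relations
#' file (`child RB parent` rows under the default orientation), plant
#' efficacy pairs, plant-compound pairs, the universe list, a
#' gold-standard table derived from the planted truth, and the
#' generating parameters as JSON.
#'
#' @param world a [SyntheticWorld-class].
#' @param dir output directory (created if needed).
#' @return named character vector of the written file paths, invisibly.
#' @export
writeWorld <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(relations = file.path(dir, "relations.tsv"),
             efficacy = file.path(dir, "efficacy.tsv"),
             compounds = file.path(dir, "compounds.tsv"),
             universe = file.path(dir, "universe.txt"),
             gold = file.path(dir, "gold_standard.tsv"),
             params = file.path(dir, "params.json"))
  e <- world@network@edges
  write.table(data.frame(e$child, "RB", e$parent), paths["relations"],
              sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  eff <- data.frame(
    plant_id = rep(names(world@profiles), lengths(world@profiles)),
    concept_id = unlist(world@profiles, use.names = FALSE))
  write.table(eff, paths["efficacy"], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  cmp <- data.frame(
    plant_id = rep(names(world@catalog), lengths(world@catalog)),
    compound_id = unlist(world@catalog, use.names = FALSE))
  write.table(cmp, paths["compounds"], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  writeLines(world@universe, paths["universe"])
  gold <- data.frame(
    compound_id = rep(names(world@truth), lengths(world@truth)),
    concept_id = unlist(world@truth, use.names = FALSE),
    label = "therapeutic")
  write.table(gold, paths["gold"], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(world@params, paths["params"], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
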