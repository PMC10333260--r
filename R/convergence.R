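#' @include AllClasses.R AllGenerics.R interactome-io.R
NULL

#' Configure a resampling null model
#'
#' @param reps Monte-Carlo replicates; 10000 gives an empirical-p
#'   resolution of 1e-4 and is the default for analyses, while tests and
#'   simulations typically scale this down.
#' @param seed mandatory integer RNG seed.
#' @param sampling `"uniform"` node sampling (the written procedure:
#'   proteins drawn with equal weight from the pool) or
#'   `"degree_weighted"` (pool nodes weighted by their reference-interactome
#'   degree, for sensitivity analysis against hub bias).
#' @param floorDisplay string reported when no null replicate reaches the
#'   observed statistic; the convention at 10000 replicates is `"<0.001"`.
#' @return a [RewiringConfig-class].
#' @export
rewiringConfig <- function(reps = 10000L, seed, sampling = "uniform",
                           floorDisplay = "<0.001") {
  new("RewiringConfig", reps = as.integer(reps), seed = as.integer(seed),
      sampling = sampling, floorDisplay = floorDisplay)
}

## Resolve the sampling pool and (optional) degree weights.
resolvePool <- function(pool, ref = NULL, cfg) {
  if (is(pool, "ReferenceInteractome")) {
    ref <- pool
    pool <- interactomeNodes(pool)
  }
  pool <- unique(as.character(pool))
  if (length(pool) < 1L) stop("sampling pool is empty")
  w <- NULL
  if (cfg@sampling == "degree_weighted") {
    if (is.null(ref))
      stop("degree_weighted sampling needs a ReferenceInteractome pool")
    w <- referenceDegrees(ref)[pool]
    w[is.na(w) | w == 0] <- 1L  # isolated pool nodes keep minimal weight
  }
  list(nodes = pool, weights = w)
}

## Draw reps x n node indices with replacement; returns integer vector of
## length reps*n laid out replicate-by-replicate.
drawIndices <- function(npool, n, reps, weights = NULL) {
  sample.int(npool, n * reps, replace = TRUE, prob = weights)
}

## Unique count per replicate chunk of length n.
chunkUniqueCounts <- function(draws, n, reps) {
  vapply(seq_len(reps), function(i)
    length(unique.default(draws[((i - 1L) * n + 1L):(i * n)])), 1L)
}

makeResult <- function(observed, nullDraws, tail, cfg) {
  qualifying <- if (tail == "lower") sum(nullDraws < observed)
                else sum(nullDraws > observed)
  p <- qualifying / length(nullDraws)
  new("RewiringResult", observed = as.integer(observed),
      nullDraws = as.integer(nullDraws), pValue = p,
      isFloor = qualifying == 0L, tail = tail, config = cfg)
}

#' Intraspecies target convergence test
#'
#' Tests whether one organism's effectors converge on fewer unique host
#' targets than expected by chance. The observed statistic is the number of
#' unique host targets. Under the null, N proteins (N = total number of
#' effector-host interactions) are drawn with replacement from the
#' reference pool, and the number of unique proteins drawn is recorded;
#' this is repeated `reps` times. The empirical p-value is the fraction of
#' replicates whose unique count falls strictly below the observed count
#' (lower tail: convergence means unexpectedly few unique targets). When no
#' replicate qualifies the result carries a floor flag and prints as the
#' configured floor string.
#'
#' @param net an [EffectorHostNetwork-class].
#' @param pool the sampling pool: a [ReferenceInteractome-class] (all its
#'   nodes) or an explicit character vector of proteins, typically the
#'   reference-interactome nodes intersected with the experiment's search
#'   space.
#' @param cfg a [RewiringConfig-class].
#' @return a [RewiringResult-class] (lower tail).
#' @examples
#' net <- effectorHostNetwork(
#'   data.frame(effector = c("E1", "E2", "E3"),
#'              target = c("AT1G01010", "AT1G01010", "AT1G01020")),
#'   "Si", "demo")
#' intraspeciesConvergence(net, paste0("P", 1:50),
#'                         rewiringConfig(reps = 1000, seed = 1))
#' @export
intraspeciesConvergence <- function(net, pool, cfg) {
  p <- resolvePool(pool, cfg = cfg)
  e <- networkEdges(net)
  n <- nrow(e)
  if (n == 0L) stop("network has no interactions")
  observed <- length(unique(e$target))
  set.seed(cfg@seed)
  draws <- drawIndices(length(p$nodes), n, cfg@reps, p$weights)
  nullDraws <- chunkUniqueCounts(draws, n, cfg@reps)
  makeResult(observed, nullDraws, "lower", cfg)
}

#' Interspecies target convergence test
#'
#' Tests whether effectors of two or more organisms share more common host
#' targets than expected by chance, within a common search space. The
#' observed statistic is the size of the intersection of the organisms'
#' unique-target sets. Under the null, each organism draws N_org proteins
#' with replacement from the pool (N_org = its observed number of unique
#' targets), the draws are deduplicated, and the size of the intersection
#' across all organisms is recorded; the empirical p-value is the fraction
#' of replicates whose common count exceeds the observed count (upper
#' tail).
#'
#' @param nets named list of [EffectorHostNetwork-class], one per organism
#'   (two or more; pass the relevant subset for two-way or higher-order
#'   comparisons).
#' @param commonSpace a [SearchSpace-class] all networks are restricted to
#'   before comparison, or `NULL` if they already are.
#' @param pool sampling pool as in [intraspeciesConvergence()].
#' @param cfg a [RewiringConfig-class].
#' @param dropHormoneSpaceOnly drop edges flagged as found only in a
#'   hormone-protein space extension before comparing (default `TRUE` for
#'   cross-organism analyses, to reduce bias from unequally interrogated
#'   proteins).
#' @return a [RewiringResult-class] (upper tail). The observed common
#'   target set is attached as attribute `"commonTargets"`.
#' @export
interspeciesConvergence <- function(nets, commonSpace = NULL, pool, cfg,
                                    dropHormoneSpaceOnly = TRUE) {
  if (length(nets) < 2L) stop("need at least two organisms")
  if (!is.null(commonSpace))
    nets <- lapply(nets, restrictToSpace, space = commonSpace,
                   dropHormoneSpaceOnly = dropHormoneSpaceOnly)
  else if (dropHormoneSpaceOnly)
    nets <- lapply(nets, function(x) {
      e <- networkEdges(x)
      if ("hormone_space_only" %in% names(e)) {
        e <- e[!(e$hormone_space_only %in% TRUE), , drop = FALSE]
        new("EffectorHostNetwork", edges = e, organism = organism(x),
            searchSpace = searchSpaceName(x))
      } else x
    })
  targetSets <- lapply(nets, function(x) unique(networkEdges(x)$target))
  sizes <- lengths(targetSets)
  if (any(sizes == 0L))
    stop("organism(s) with zero targets in the common space: ",
         paste(names(nets)[sizes == 0L], collapse = ", "))
  observedSet <- Reduce(intersect, targetSets)
  observed <- length(observedSet)

  p <- resolvePool(pool, cfg = cfg)
  npool <- length(p$nodes)
  set.seed(cfg@seed)
  allDraws <- lapply(sizes, function(n)
    drawIndices(npool, n, cfg@reps, p$weights))
  nullDraws <- vapply(seq_len(cfg@reps), function(i) {
    common <- NULL
    for (k in seq_along(allDraws)) {
      n <- sizes[[k]]
      u <- unique.default(allDraws[[k]][((i - 1L) * n + 1L):(i * n)])
      common <- if (is.null(common)) u else common[common %in% u]
      if (length(common) == 0L) break
    }
    length(common)
  }, 1L)
  res <- makeResult(observed, nullDraws, "upper", cfg)
  attr(res, "commonTargets") <- sort(observedSet)
  res
}

#' Annotated-target excess test
#'
#' Tests whether an organism's unique host targets contain more proteins
#' from an annotated set (e.g. hormone-annotated proteins) than expected in
#' random networks with the same number of unique targets. Each null
#' replicate draws U proteins without replacement from the pool (U = the
#' observed number of unique targets) and counts how many are annotated;
#' the empirical p-value is the fraction of replicates with a count at
#' least the observed one (non-strict upper tail, the conservative choice).
#'
#' @param net an [EffectorHostNetwork-class].
#' @param annotated character vector of annotated proteins; members outside
#'   the pool trigger a warning.
#' @param pool sampling pool as in [intraspeciesConvergence()].
#' @param cfg a [RewiringConfig-class].
#' @return a [RewiringResult-class] (upper tail).
#' @export
annotatedTargetExcess <- function(net, annotated, pool, cfg) {
  p <- resolvePool(pool, cfg = cfg)
  annotated <- unique(normalizeHostId(annotated))
  outside <- setdiff(annotated, p$nodes)
  if (length(outside))
    warning(length(outside), " annotated protein(s) outside the pool")
  tgt <- unique(networkEdges(net)$target)
  U <- length(tgt)
  if (U > length(p$nodes))
    stop("more unique targets (", U, ") than pool proteins")
  observed <- sum(tgt %in% annotated)
  isAnn <- p$nodes %in% annotated
  set.seed(cfg@seed)
  nullDraws <- vapply(seq_len(cfg@reps), function(i)
    sum(isAnn[sample.int(length(isAnn), U, prob = p$weights)]), 1L)
  qualifying <- sum(nullDraws >= observed)
  new("RewiringResult", observed = as.integer(observed),
      nullDraws = as.integer(nullDraws),
      pValue = qualifying / cfg@reps, isFloor = qualifying == 0L,
      tail = "upper", config = cfg)
}

#' Classify a focal organism's targets as exclusive or shared
#'
#' Labels each host target of the focal organism as exclusive (no other
#' organism's effector interacts with it) or shared (with the list of
#' sharing organisms). The exclusive and shared sets partition the focal
#' target set exactly.
#'
#' @param focal focal organism's [EffectorHostNetwork-class].
#' @param others named list of the other organisms' networks.
#' @param space optional [SearchSpace-class]; all networks are restricted
#'   to it first (focal hormone-space-only edges are dropped via
#'   `dropHormoneSpaceOnly`).
#' @param dropHormoneSpaceOnly see [interspeciesConvergence()].
#' @return data.frame with columns `protein`, `status`
#'   (`"exclusive_to_focal"` / `"shared"`), `sharingOrganisms`
#'   (comma-separated), `nSharing`.
#' @export
classifySharedExclusive <- function(focal, others, space = NULL,
                                    dropHormoneSpaceOnly = TRUE) {
  if (!is.null(space)) {
    focal <- restrictToSpace(focal, space,
                             dropHormoneSpaceOnly = dropHormoneSpaceOnly)
    others <- lapply(others, restrictToSpace, space = space)
  }
  tg <- sort(unique(networkEdges(focal)$target))
  otherSets <- lapply(others, function(x) unique(networkEdges(x)$target))
  sharing <- lapply(tg, function(p)
    names(otherSets)[vapply(otherSets, function(s) p %in% s, TRUE)])
  data.frame(
    protein = tg,
    status = ifelse(lengths(sharing) > 0L, "shared", "exclusive_to_focal"),
    sharingOrganisms = vapply(sharing, paste, "", collapse = ","),
    nSharing = lengths(sharing),
    stringsAsFactors = FALSE)
}

#' Target-set overlaps for every organism subset
#'
#' Venn-style intersection cardinalities of the organisms' unique-target
#' sets, for every subset of two or more organisms, after restriction to a
#' common space.
#'
#' @param nets named list of [EffectorHostNetwork-class] (two or more).
#' @param space optional common [SearchSpace-class].
#' @param dropHormoneSpaceOnly see [interspeciesConvergence()].
#' @return data.frame with columns `organisms` (comma-separated subset),
#'   `k` (subset size), `intersection` (cardinality of the intersection of
#'   the subset's target sets).
#' @export
pairwiseOverlap <- function(nets, space = NULL,
                            dropHormoneSpaceOnly = TRUE) {
  if (length(nets) < 2L) stop("need at least two organisms")
  if (!is.null(space))
    nets <- lapply(nets, restrictToSpace, space = space,
                   dropHormoneSpaceOnly = dropHormoneSpaceOnly)
  sets <- lapply(nets, function(x) unique(networkEdges(x)$target))
  orgs <- names(sets)
  rows <- list()
  for (k in 2:length(orgs)) {
    combos <- utils::combn(orgs, k, simplify = FALSE)
    for (cc in combos)
      rows[[length(rows) + 1L]] <- data.frame(
        organisms = paste(cc, collapse = ","), k = k,
        intersection = length(Reduce(intersect, sets[cc])),
        stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Render a resampling p-value the way reports print it
#'
#' @param result a [RewiringResult-class].
#' @return the numeric p formatted as a string, or the floor string (e.g.
#'   `"<0.001"`) when no null replicate reached the observed statistic.
#' @export
formatPValue <- function(result) {
  if (isFloor(result)) result@config@floorDisplay
  else format(pValue(result))
}
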