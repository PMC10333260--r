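#' @include AllClasses.R AllGenerics.R
NULL

#' Degree and count summary of an effector-host network
#'
#' Computes edge/node counts, degree histograms for both sides of the
#' bipartite network, and the specific/convergent partition on each side
#' (degree exactly 1 vs degree two or more). The partition counts always
#' sum to the side totals and each side's degrees sum to the edge count.
#'
#' @param net an [EffectorHostNetwork-class].
#' @return a list with elements `nEdges`, `nEffectors`, `nTargets`,
#'   `effectorDegrees` (named integer vector), `targetDegrees`,
#'   `effectorDegreeHistogram` and `targetDegreeHistogram` (tables),
#'   `effectorsDegree1`, `effectorsDegree2plus`, `targetsDegree1`,
#'   `targetsDegree2plus`.
#' @examples
#' net <- effectorHostNetwork(
#'   data.frame(effector = c("E1", "E1", "E2"),
#'              target = c("AT1G01010", "AT1G01020", "AT1G01010")),
#'   organism = "Si", space = "demo")
#' networkSummary(net)$targetsDegree2plus  # AT1G01010 hit by both effectors
#' @export
networkSummary <- function(net) {
  e <- networkEdges(net)
  effDeg <- if (nrow(e)) table(e$effector) else table(character())
  tgtDeg <- if (nrow(e)) table(e$target) else table(character())
  effDeg <- stats::setNames(as.integer(effDeg), names(effDeg))
  tgtDeg <- stats::setNames(as.integer(tgtDeg), names(tgtDeg))
  list(
    nEdges = nrow(e),
    nEffectors = length(effDeg),
    nTargets = length(tgtDeg),
    effectorDegrees = effDeg,
    targetDegrees = tgtDeg,
    effectorDegreeHistogram = table(effDeg),
    targetDegreeHistogram = table(tgtDeg),
    effectorsDegree1 = sum(effDeg == 1L),
    effectorsDegree2plus = sum(effDeg >= 2L),
    targetsDegree1 = sum(tgtDeg == 1L),
    targetsDegree2plus = sum(tgtDeg >= 2L)
  )
}

#' Neighbours of proteins in a reference interactome
#'
#' @param ref a [ReferenceInteractome-class].
#' @param proteins character vector.
#' @return named list: protein -> sorted character vector of neighbours
#'   (empty for proteins absent from the map).
#' @export
neighborsOf <- function(ref, proteins) {
  e <- networkEdges(ref)
  adj <- split(c(e$b, e$a), c(e$a, e$b))
  lapply(stats::setNames(proteins, proteins), function(p) {
    n <- adj[[p]]
    if (is.null(n)) character() else sort(unique(n))
  })
}

#' Node degrees in a reference interactome
#'
#' @param ref a [ReferenceInteractome-class].
#' @return named integer vector over all interactome nodes.
#' @export
referenceDegrees <- function(ref) {
  e <- networkEdges(ref)
  d <- table(factor(c(e$a, e$b), levels = interactomeNodes(ref)))
  stats::setNames(as.integer(d), names(d))
}
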