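#' @include AllClasses.R
NULL

#' Accessors for network and result classes
#'
#' Small accessor generics so downstream code never touches slots directly:
#' `networkEdges` returns the edge table, `organism` the organism tag,
#' `searchSpaceName` the declared space, `spaceMembers` a space's member
#' set, `effectors` / `targets` the unique node sets of either side,
#' `observedStat`, `nullDraws`, `pValue`, `isFloor` the components of a
#' resampling result, and `hormonesOf` the hormone label set of a protein.
#'
#' @param x object.
#' @param ... further arguments for methods.
#' @return the accessed component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))
#' @rdname accessors
#' @export
setGeneric("organism", function(x) standardGeneric("organism"))
#' @rdname accessors
#' @export
setGeneric("searchSpaceName", function(x) standardGeneric("searchSpaceName"))
#' @rdname accessors
#' @export
setGeneric("spaceMembers", function(x) standardGeneric("spaceMembers"))
#' @rdname accessors
#' @export
setGeneric("effectors", function(x) standardGeneric("effectors"))
#' @rdname accessors
#' @export
setGeneric("targets", function(x) standardGeneric("targets"))
#' @rdname accessors
#' @export
setGeneric("interactomeNodes", function(x) standardGeneric("interactomeNodes"))
#' @rdname accessors
#' @export
setGeneric("observedStat", function(x) standardGeneric("observedStat"))
#' @rdname accessors
#' @export
setGeneric("nullDraws", function(x) standardGeneric("nullDraws"))
#' @rdname accessors
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))
#' @rdname accessors
#' @export
setGeneric("isFloor", function(x) standardGeneric("isFloor"))
#' @rdname accessors
#' @param protein character vector of protein ids.
#' @export
setGeneric("hormonesOf", function(x, protein) standardGeneric("hormonesOf"))

#' @rdname accessors
#' @export
setMethod("networkEdges", "EffectorHostNetwork", function(x) x@edges)
#' @rdname accessors
#' @export
setMethod("networkEdges", "ReferenceInteractome", function(x) x@edges)
#' @rdname accessors
#' @export
setMethod("networkEdges", "FiSpinNetwork", function(x) x@edges)
#' @rdname accessors
#' @export
setMethod("organism", "EffectorHostNetwork", function(x) x@organism)
#' @rdname accessors
#' @export
setMethod("searchSpaceName", "EffectorHostNetwork", function(x) x@searchSpace)
#' @rdname accessors
#' @export
setMethod("searchSpaceName", "SearchSpace", function(x) x@name)
#' @rdname accessors
#' @export
setMethod("spaceMembers", "SearchSpace", function(x) x@members)
#' @rdname accessors
#' @export
setMethod("effectors", "EffectorHostNetwork",
          function(x) sort(unique(x@edges$effector)))
#' @rdname accessors
#' @export
setMethod("targets", "EffectorHostNetwork",
          function(x) sort(unique(x@edges$target)))
#' @rdname accessors
#' @export
setMethod("effectors", "FiSpinNetwork",
          function(x) sort(unique(x@edges$effector)))
#' @rdname accessors
#' @export
setMethod("targets", "FiSpinNetwork",
          function(x) sort(unique(x@edges$target)))
#' @rdname accessors
#' @export
setMethod("interactomeNodes", "ReferenceInteractome", function(x) x@nodes)
#' @rdname accessors
#' @export
setMethod("observedStat", "RewiringResult", function(x) x@observed)
#' @rdname accessors
#' @export
setMethod("nullDraws", "RewiringResult", function(x) x@nullDraws)
#' @rdname accessors
#' @export
setMethod("pValue", "RewiringResult", function(x) x@pValue)
#' @rdname accessors
#' @export
setMethod("isFloor", "RewiringResult", function(x) x@isFloor)
#' @rdname accessors
#' @export
setMethod("hormonesOf", "HormoneAnnotation", function(x, protein) {
  t <- x@table
  lapply(stats::setNames(protein, protein),
         function(p) sort(unique(t$hormone[t$protein == p])))
})

setMethod("show", "SearchSpace", function(object) {
  cat("SearchSpace '", object@name, "': ", length(object@members),
      " proteins", sep = "")
  if (!is.na(object@subsetOf))
    cat(" (subset of '", object@subsetOf, "')", sep = "")
  cat("\n")
})

setMethod("show", "EffectorHostNetwork", function(object) {
  e <- object@edges
  cat("EffectorHostNetwork [", object@organism, " in ", object@searchSpace,
      "]: ", nrow(e), " interactions, ",
      length(unique(e$effector)), " effectors, ",
      length(unique(e$target)), " host targets\n", sep = "")
})

setMethod("show", "ReferenceInteractome", function(object) {
  cat("ReferenceInteractome: ", nrow(object@edges), " edges, ",
      length(object@nodes), " proteins\n", sep = "")
})

setMethod("show", "RewiringResult", function(object) {
  p <- if (object@isFloor) object@config@floorDisplay
       else format(object@pValue)
  cat("RewiringResult (", object@tail, " tail): observed = ",
      object@observed, ", null mean = ",
      round(mean(object@nullDraws), 2), " (sd ",
      round(stats::sd(object@nullDraws), 2), "), p = ", p, " [",
      object@config@reps, " replicates]\n", sep = "")
})

setMethod("show", "HormoneAnnotation", function(object) {
  cat("HormoneAnnotation: ", length(unique(object@table$protein)),
      " proteins, ", nrow(object@table), " labels\n", sep = "")
})

setMethod("show", "AnnotationMap", function(object) {
  cat("AnnotationMap: ", length(object@gene2term), " genes, ",
      length(object@term2gene), " terms\n", sep = "")
})

setMethod("show", "FiSpinNetwork", function(object) {
  cat("FiSpinNetwork: ", nrow(object@edges), " edges, ",
      length(unique(object@edges$effector)), " effectors, ",
      length(unique(object@edges$target)), " targets\n", sep = "")
})
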