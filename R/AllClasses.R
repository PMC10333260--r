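#' @import methods
NULL

#' Controlled vocabulary of phytohormone labels
#'
#' The nine hormone pathways recognised by the annotation machinery:
#' abscisic acid (ABA), auxin (AUX), cytokinin (CK), jasmonic acid (JA),
#' salicylic acid (SA), ethylene (ET), brassinosteroid (BR), gibberellin
#' (GA) and strigolactone (SL).
#'
#' @export
HORMONE_LABELS <- c("ABA", "AUX", "CK", "JA", "SA", "ET", "BR", "GA", "SL")

#' The five hormones covered by the protoplast reporter screen
#' @export
SCREEN_HORMONES <- c("ABA", "AUX", "CK", "JA", "SA")

#' SearchSpace: the set of host proteins interrogated in a screen
#'
#' A named set of host protein identifiers defining which proteins an
#' interaction screen could in principle have detected. Comparative analyses
#' between organisms must be carried out within a common search space.
#' A space may be declared a subset of another (e.g. an 8k space fully
#' contained in a 12k space); the containment is verified at construction.
#'
#' @slot name single string naming the space (e.g. `"8k_space"`).
#' @slot members character vector of host protein ids (upper-cased).
#' @slot subsetOf optional name of a declared superset, `NA` if none.
#' @export
setClass("SearchSpace",
  representation(name = "character", members = "character",
                 subsetOf = "character"),
  prototype(subsetOf = NA_character_))

setValidity("SearchSpace", function(object) {
  msg <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "'name' must be a single non-empty string")
  if (length(object@members) == 0L)
    msg <- c(msg, "a search space must have at least one member")
  if (anyDuplicated(object@members))
    msg <- c(msg, "duplicate members in search space")
  if (any(!nzchar(object@members)))
    msg <- c(msg, "empty member identifiers")
  if (length(msg)) msg else TRUE
})

#' EffectorHostNetwork: bipartite effector-to-host interaction set
#'
#' Holds the deduplicated set of effector-host protein contacts found for
#' one organism in one search space. Extra per-edge logical flags (for
#' example `hormone_space_only` marking interactions only detectable in a
#' hormone-protein extension of the space, or `out_of_space` set at load
#' time) travel with the edges.
#'
#' @slot edges data.frame with columns `effector`, `target` plus any flag
#'   columns; one row per unique (effector, target) pair.
#' @slot organism single string, e.g. `"Si"`.
#' @slot searchSpace name of the search space the screen used.
#' @export
setClass("EffectorHostNetwork",
  representation(edges = "data.frame", organism = "character",
                 searchSpace = "character"))

setValidity("EffectorHostNetwork", function(object) {
  e <- object@edges
  msg <- character()
  if (!all(c("effector", "target") %in% names(e)))
    msg <- c(msg, "edges must have 'effector' and 'target' columns")
  else {
    if (anyDuplicated(e[, c("effector", "target")]))
      msg <- c(msg, "duplicate effector-target pairs")
    if (nrow(e) && any(!nzchar(e$effector) | !nzchar(e$target)))
      msg <- c(msg, "empty identifiers in edges")
  }
  if (length(object@organism) != 1L)
    msg <- c(msg, "'organism' must be a single string")
  if (length(msg)) msg else TRUE
})

#' ReferenceInteractome: undirected host-host interaction map
#'
#' A systematic host protein-protein interactome (an AI-1_MAIN-like map)
#' used both as the sampling pool for resampling null models and as the
#' mediator graph for second-degree hormone-interaction-point detection.
#' Edges are stored once with endpoints in sorted order; self-interactions
#' are excluded by default and retained only when explicitly flagged.
#'
#' @slot edges data.frame with columns `a`, `b` (a <= b lexicographically).
#' @slot nodes character vector of all proteins appearing in edges.
#' @slot selfLoops logical, whether self-interactions were retained.
#' @export
setClass("ReferenceInteractome",
  representation(edges = "data.frame", nodes = "character",
                 selfLoops = "logical"),
  prototype(selfLoops = FALSE))

setValidity("ReferenceInteractome", function(object) {
  e <- object@edges
  msg <- character()
  if (!all(c("a", "b") %in% names(e)))
    msg <- c(msg, "edges must have columns 'a' and 'b'")
  else {
    if (nrow(e) && any(e$a > e$b))
      msg <- c(msg, "edge endpoints must be stored in sorted order")
    if (anyDuplicated(e[, c("a", "b")]))
      msg <- c(msg, "duplicate edges")
    if (!object@selfLoops && nrow(e) && any(e$a == e$b))
      msg <- c(msg, "self-loops present but selfLoops flag is FALSE")
  }
  if (length(msg)) msg else TRUE
})

#' RewiringConfig: settings for a resampling null model
#'
#' @slot reps number of Monte-Carlo replicates (default 10000).
#' @slot seed integer RNG seed; mandatory so that results are reproducible.
#' @slot sampling `"uniform"` or `"degree_weighted"` node sampling.
#' @slot floorDisplay string rendered when no replicate reaches the observed
#'   statistic (default `"<0.001"`).
#' @export
setClass("RewiringConfig",
  representation(reps = "integer", seed = "integer", sampling = "character",
                 floorDisplay = "character"))

setValidity("RewiringConfig", function(object) {
  msg <- character()
  if (length(object@reps) != 1L || is.na(object@reps) || object@reps < 1L)
    msg <- c(msg, "'reps' must be a single integer >= 1")
  if (length(object@seed) != 1L || is.na(object@seed))
    msg <- c(msg, "'seed' is mandatory (reproducibility)")
  if (!object@sampling %in% c("uniform", "degree_weighted"))
    msg <- c(msg, "'sampling' must be 'uniform' or 'degree_weighted'")
  if (length(msg)) msg else TRUE
})

#' RewiringResult: observed statistic, null distribution and empirical p
#'
#' @slot observed observed integer statistic (unique-target count,
#'   common-interactor count, or annotated-target count).
#' @slot nullDraws integer vector of per-replicate null statistics.
#' @slot pValue empirical p: qualifying replicates / reps.
#' @slot isFloor TRUE when no replicate qualified (p reported as a floor
#'   string such as "<0.001" rather than 0).
#' @slot tail `"lower"` or `"upper"`.
#' @slot config the RewiringConfig used.
#' @export
setClass("RewiringResult",
  representation(observed = "integer", nullDraws = "integer",
                 pValue = "numeric", isFloor = "logical", tail = "character",
                 config = "RewiringConfig"))

setValidity("RewiringResult", function(object) {
  msg <- character()
  if (object@observed < 0L) msg <- c(msg, "'observed' must be >= 0")
  if (object@pValue < 0 || object@pValue > 1)
    msg <- c(msg, "'pValue' must lie in [0, 1]")
  if (!object@tail %in% c("lower", "upper"))
    msg <- c(msg, "'tail' must be 'lower' or 'upper'")
  if (object@isFloor && object@pValue != 0)
    msg <- c(msg, "floor flag implies pValue == 0")
  if (length(msg)) msg else TRUE
})

#' HormoneAnnotation: protein-to-hormone label map
#'
#' Maps host proteins to sets of hormone pathway labels drawn from the
#' nine-label controlled vocabulary ([HORMONE_LABELS]), with a provenance
#' tag per label (curated database vs GO-derived). Proteins absent from the
#' map are un-annotated.
#'
#' @slot table data.frame with columns `protein`, `hormone`, `source`.
#' @export
setClass("HormoneAnnotation", representation(table = "data.frame"))

setValidity("HormoneAnnotation", function(object) {
  t <- object@table
  msg <- character()
  if (!all(c("protein", "hormone", "source") %in% names(t)))
    msg <- c(msg, "table needs columns protein, hormone, source")
  else if (nrow(t) && !all(t$hormone %in% HORMONE_LABELS))
    msg <- c(msg, paste0("unknown hormone labels: ",
                         paste(setdiff(unique(t$hormone), HORMONE_LABELS),
                               collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' AnnotationMap: gene-to-term and term-to-gene indices
#'
#' Bidirectional gene/term annotation index used by term enrichment. The
#' two indices are kept mutually consistent by construction.
#'
#' @slot gene2term named list: gene -> character vector of term ids.
#' @slot term2gene named list: term -> character vector of genes.
#' @slot termLabels optional named character vector of term descriptions.
#' @export
setClass("AnnotationMap",
  representation(gene2term = "list", term2gene = "list",
                 termLabels = "character"),
  prototype(termLabels = character()))

#' FiSpinNetwork: functionally informed symbiont-plant interaction network
#'
#' The subnetwork of effectors that modulated at least one hormone reporter
#' in the functional screen, together with their host targets. Each effector
#' carries its screen-derived modulated-hormone set, each target its
#' database/GO hormone annotation set, and each edge a type:
#' type I (effector hormone set and target annotation overlap),
#' type II (target un-annotated), type III (both annotated, no overlap).
#'
#' @slot edges data.frame with columns `effector`, `target`.
#' @slot effectorHormones named list: effector -> modulated hormone labels.
#' @slot targetAnnotations named list: target -> annotation labels
#'   (possibly empty character vector).
#' @export
setClass("FiSpinNetwork",
  representation(edges = "data.frame", effectorHormones = "list",
                 targetAnnotations = "list"))

setValidity("FiSpinNetwork", function(object) {
  msg <- character()
  e <- object@edges
  if (!all(c("effector", "target") %in% names(e)))
    msg <- c(msg, "edges must have 'effector' and 'target' columns")
  else {
    if (nrow(e) && !all(e$effector %in% names(object@effectorHormones)))
      msg <- c(msg, "every effector needs a screen-derived hormone set")
    if (nrow(e) && !all(vapply(object@effectorHormones, length, 1L) >= 1L))
      msg <- c(msg, "every effector must have >= 1 significant screen call")
  }
  if (length(msg)) msg else TRUE
})
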