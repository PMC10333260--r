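#' @include AllClasses.R AllGenerics.R interactome-summary.R
NULL

#' Build a hormone annotation map
#'
#' @param table data.frame with columns `protein`, `hormone` and
#'   optionally `source` (provenance: e.g. `"database"` or `"GO"`), or a
#'   path to a TSV with those columns. Hormone labels must come from the
#'   nine-label controlled vocabulary ([HORMONE_LABELS]); unknown labels
#'   are rejected.
#' @return a [HormoneAnnotation-class].
#' @export
hormoneAnnotation <- function(table) {
  if (is.character(table) && length(table) == 1L)
    table <- utils::read.table(table, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
  stopifnot(all(c("protein", "hormone") %in% names(table)))
  if (!"source" %in% names(table))
    table$source <- rep("database", nrow(table))
  table$protein <- toupper(trimws(table$protein))
  table <- unique(table[, c("protein", "hormone", "source")])
  rownames(table) <- NULL
  new("HormoneAnnotation", table = table)
}

annotatedProteins <- function(ann) unique(ann@table$protein)

hormoneSet <- function(ann, protein) {
  t <- ann@table
  sort(unique(t$hormone[t$protein %in% protein]))
}

#' Find hormone interaction points (SHIPs)
#'
#' Propagates hormone annotations over the combined effector/host
#' interactome. A first-degree record is emitted for every effector
#' interaction with a hormone-annotated host target. For interactions with
#' un-annotated targets, the target acts as a mediator: a second-degree
#' record is emitted for each hormone-annotated neighbour of the target in
#' the reference interactome (one record per annotated "hormone protein"
#' reached, a path of length two from the effector). First- and
#' second-degree records are disjoint by construction since second degree
#' requires an un-annotated target.
#'
#' Effectors are partitioned into `has_1st` (at least one first-degree
#' record, regardless of second-degree records), `only_2nd`, and `none`.
#'
#' @param net an [EffectorHostNetwork-class].
#' @param ref a [ReferenceInteractome-class] (mediator graph).
#' @param ann a [HormoneAnnotation-class].
#' @return list with:
#'   * `records`: data.frame `effector`, `target`, `degree` (1 or 2),
#'     `hormones` (comma-joined labels), `reached` (the annotated
#'     neighbour for degree-2 records, `NA` for degree 1);
#'   * `effectorClass`: named character vector over all effectors in the
#'     network with values `has_1st` / `only_2nd` / `none`;
#'   * `firstDegreeTargets`: unique annotated targets contacted directly;
#'   * `secondDegreeHormoneProteins`: unique annotated proteins reached
#'     through un-annotated mediators.
#' @export
findShips <- function(net, ref, ann) {
  e <- networkEdges(net)
  annSet <- annotatedProteins(ann)
  isAnn <- e$target %in% annSet

  rec1 <- if (any(isAnn)) {
    d1 <- e[isAnn, c("effector", "target"), drop = FALSE]
    d1$degree <- 1L
    d1$hormones <- vapply(d1$target, function(p)
      paste(hormoneSet(ann, p), collapse = ","), "")
    d1$reached <- NA_character_
    d1
  } else NULL

  rec2 <- NULL
  un <- e[!isAnn, c("effector", "target"), drop = FALSE]
  if (nrow(un)) {
    nb <- neighborsOf(ref, unique(un$target))
    rows <- lapply(seq_len(nrow(un)), function(i) {
      reached <- intersect(nb[[un$target[i]]], annSet)
      if (length(reached) == 0L) return(NULL)
      data.frame(effector = un$effector[i], target = un$target[i],
                 degree = 2L,
                 hormones = vapply(reached, function(p)
                   paste(hormoneSet(ann, p), collapse = ","), ""),
                 reached = reached, stringsAsFactors = FALSE)
    })
    rec2 <- do.call(rbind, rows)
  }
  records <- rbind(rec1, rec2)
  if (is.null(records))
    records <- data.frame(effector = character(), target = character(),
                          degree = integer(), hormones = character(),
                          reached = character(), stringsAsFactors = FALSE)
  records <- records[order(records$degree, records$effector,
                           records$target, records$reached), , drop = FALSE]
  rownames(records) <- NULL

  allEff <- sort(unique(e$effector))
  has1 <- unique(records$effector[records$degree == 1L])
  has2 <- unique(records$effector[records$degree == 2L])
  cls <- stats::setNames(rep("none", length(allEff)), allEff)
  cls[allEff %in% has2] <- "only_2nd"
  cls[allEff %in% has1] <- "has_1st"

  list(records = records,
       effectorClass = cls,
       firstDegreeTargets =
         sort(unique(records$target[records$degree == 1L])),
       secondDegreeHormoneProteins =
         sort(unique(records$reached[records$degree == 2L])))
}

#' Assemble the functionally informed interaction network
#'
#' Combines the physical interaction map with the functional reporter
#' screen: keeps only effectors that significantly modulated at least one
#' hormone reporter and that have at least one host target. Each retained
#' effector carries its screen-derived modulated-hormone set; each target
#' carries its database/GO hormone annotation set.
#'
#' @param net an [EffectorHostNetwork-class].
#' @param screenCalls data.frame with columns `effector`, `hormone`,
#'   `call` (values `induced` / `suppressed` / `ns`), e.g. the output of
#'   [screenAnalysis()]. Both modulation directions count.
#' @param ann a [HormoneAnnotation-class].
#' @return a [FiSpinNetwork-class]. Effectors with significant calls but
#'   no targets in `net` are skipped with a warning.
#' @export
buildFispin <- function(net, screenCalls, ann) {
  stopifnot(all(c("effector", "hormone", "call") %in% names(screenCalls)))
  sig <- screenCalls[screenCalls$call %in% c("induced", "suppressed"), ,
                     drop = FALSE]
  hormoneSets <- lapply(split(sig$hormone, sig$effector),
                        function(x) sort(unique(x)))
  e <- networkEdges(net)
  missing <- setdiff(names(hormoneSets), e$effector)
  if (length(missing))
    warning(length(missing), " effector(s) with screen calls but no ",
            "interactome targets skipped: ",
            paste(utils::head(missing, 5L), collapse = ", "))
  keep <- e$effector %in% names(hormoneSets)
  edges <- e[keep, c("effector", "target"), drop = FALSE]
  edges <- edges[order(edges$effector, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  tgts <- unique(edges$target)
  targetAnnotations <- lapply(stats::setNames(tgts, tgts),
                              function(p) hormoneSet(ann, p))
  new("FiSpinNetwork", edges = edges,
      effectorHormones = hormoneSets[intersect(names(hormoneSets),
                                               edges$effector)],
      targetAnnotations = targetAnnotations)
}

#' Classify edges of a functionally informed network into SHIP types
#'
#' Every edge receives exactly one type:
#' * type II when the target carries no hormone annotation;
#' * type I when the effector's screen-derived hormone set and the
#'   target's annotation set overlap (matching assignment);
#' * type III otherwise (both sides annotated, no overlap).
#' The three fractions partition the edge set and sum to 100%.
#'
#' @param fispin a [FiSpinNetwork-class].
#' @return list with `edges` (the edge table plus a `type` column) and
#'   `fractions` (named numeric vector, percent of edges of type I, II,
#'   III).
#' @export
classifyShipTypes <- function(fispin) {
  e <- networkEdges(fispin)
  effH <- fispin@effectorHormones
  tgtA <- fispin@targetAnnotations
  type <- vapply(seq_len(nrow(e)), function(i) {
    ta <- tgtA[[e$target[i]]]
    if (length(ta) == 0L) return("II")
    if (length(intersect(effH[[e$effector[i]]], ta))) "I" else "III"
  }, "")
  e$type <- type
  frac <- vapply(c(I = "I", II = "II", III = "III"),
                 function(t) 100 * mean(type == t), 1)
  if (nrow(e) == 0L) frac[] <- NaN
  list(edges = e, fractions = frac)
}

#' Write SHIP records to a TSV file
#'
#' @param records the `records` element of [findShips()] (optionally with
#'   a `type` column).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeShips <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
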