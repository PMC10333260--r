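#' @include AllClasses.R AllGenerics.R
NULL

normalizeHostId <- function(x) toupper(trimws(x))

#' Construct a search space
#'
#' @param name space name, e.g. `"12k_space"`.
#' @param members character vector of host protein ids; upper-cased and
#'   deduplicated.
#' @param subsetOf optional `SearchSpace` this one must be contained in;
#'   containment is verified and an error raised on violation.
#' @return a [SearchSpace-class] object.
#' @examples
#' big <- searchSpace("12k", c("AT1G01010", "AT1G01020", "AT1G01030"))
#' searchSpace("8k", c("at1g01010", "AT1G01020"), subsetOf = big)
#' @export
searchSpace <- function(name, members, subsetOf = NULL) {
  members <- sort(unique(normalizeHostId(members)))
  parent <- NA_character_
  if (!is.null(subsetOf)) {
    stopifnot(is(subsetOf, "SearchSpace"))
    extra <- setdiff(members, spaceMembers(subsetOf))
    if (length(extra))
      stop("space '", name, "' declared subset of '",
           searchSpaceName(subsetOf), "' but has ", length(extra),
           " members outside it (e.g. ", extra[1L], ")")
    parent <- searchSpaceName(subsetOf)
  }
  new("SearchSpace", name = name, members = members, subsetOf = parent)
}

#' Load a search space membership list
#'
#' One protein id per line (or first column of a TSV).
#'
#' @param path file path.
#' @inheritParams searchSpace
#' @return a [SearchSpace-class].
#' @export
loadSearchSpace <- function(path, name, subsetOf = NULL) {
  d <- utils::read.table(path, header = FALSE, sep = "\t",
                         stringsAsFactors = FALSE)
  searchSpace(name, d[[1L]], subsetOf = subsetOf)
}

#' Construct an effector-host network from an edge table
#'
#' @param edges data.frame with columns `effector` and `target` (extra
#'   logical flag columns preserved). Duplicate pairs are collapsed; for
#'   flag columns the collapse takes `any()`.
#' @param organism organism tag.
#' @param space a [SearchSpace-class] or space name. When a full space
#'   object is given, targets outside it are flagged `out_of_space` (they
#'   are retained; see [restrictToSpace()] for dropping).
#' @return an [EffectorHostNetwork-class].
#' @export
effectorHostNetwork <- function(edges, organism, space) {
  stopifnot(all(c("effector", "target") %in% names(edges)))
  edges$effector <- trimws(as.character(edges$effector))
  edges$target <- normalizeHostId(edges$target)
  flagCols <- setdiff(names(edges), c("effector", "target"))
  key <- paste(edges$effector, edges$target, sep = "\r")
  if (anyDuplicated(key)) {
    keep <- !duplicated(key)
    for (fc in flagCols)
      edges[[fc]] <- as.logical(stats::ave(as.logical(edges[[fc]]), key,
                                           FUN = any))
    edges <- edges[keep, , drop = FALSE]
  }
  spaceName <- if (is(space, "SearchSpace")) searchSpaceName(space)
               else as.character(space)
  if (is(space, "SearchSpace"))
    edges$out_of_space <- !(edges$target %in% spaceMembers(space))
  rownames(edges) <- NULL
  new("EffectorHostNetwork", edges = edges, organism = organism,
      searchSpace = spaceName)
}

#' Load an effector-host interaction table
#'
#' Reads a tab-separated interaction table with header columns
#' `effector_id` and `host_protein` (an `organism` column and any extra
#' columns are carried along; extra columns are interpreted as per-edge
#' flags). Host ids are upper-cased, duplicate pairs collapsed, and targets
#' outside the declared search space flagged `out_of_space` but retained.
#'
#' @param path path to the TSV file.
#' @param organism organism tag; when `NULL`, taken from the file's
#'   `organism` column (which must then be single-valued).
#' @param space [SearchSpace-class] the screen interrogated.
#' @return an [EffectorHostNetwork-class].
#' @export
loadInteractionTable <- function(path, organism = NULL, space) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("effector_id", "host_protein")
  if (!all(need %in% names(d)))
    stop("interaction table must have columns ",
         paste(need, collapse = ", "), "; found: ",
         paste(names(d), collapse = ", "))
  if (nrow(d) == 0L)
    stop("empty interaction table: ", path)
  if (is.null(organism)) {
    if (!"organism" %in% names(d))
      stop("no 'organism' argument and no organism column in ", path)
    org <- unique(d$organism)
    if (length(org) != 1L)
      stop("multiple organisms in file; pass 'organism' explicitly")
    organism <- org
  }
  flags <- d[, setdiff(names(d), c("effector_id", "organism",
                                   "host_protein")), drop = FALSE]
  edges <- data.frame(effector = d$effector_id, target = d$host_protein,
                      stringsAsFactors = FALSE)
  for (fc in names(flags)) edges[[fc]] <- as.logical(flags[[fc]])
  effectorHostNetwork(edges, organism, space)
}

#' Construct a reference interactome from an edge list
#'
#' @param edges data.frame or 2-column matrix of protein pairs. Reversed
#'   duplicates are collapsed to a single undirected edge.
#' @param selfLoops keep self-interactions? Default `FALSE` (dropped with a
#'   warning); systematic interactome maps are used here as resampling
#'   pools and mediator graphs, where self-edges carry no information.
#' @return a [ReferenceInteractome-class].
#' @export
referenceInteractome <- function(edges, selfLoops = FALSE) {
  a <- normalizeHostId(edges[[1L]])
  b <- normalizeHostId(edges[[2L]])
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  self <- lo == hi
  if (any(self) && !selfLoops) {
    warning(sum(self), " self-interaction(s) dropped")
    lo <- lo[!self]; hi <- hi[!self]
  }
  e <- unique(data.frame(a = lo, b = hi, stringsAsFactors = FALSE))
  e <- e[order(e$a, e$b), , drop = FALSE]
  rownames(e) <- NULL
  new("ReferenceInteractome", edges = e,
      nodes = sort(unique(c(e$a, e$b))), selfLoops = selfLoops)
}

#' Load a reference host-host interactome
#'
#' Two-column tab-separated edge list (header optional, detected from the
#' first line). Reversed duplicates collapse to one undirected edge.
#'
#' @inheritParams referenceInteractome
#' @param path file path.
#' @return a [ReferenceInteractome-class].
#' @export
loadReferenceInteractome <- function(path, selfLoops = FALSE) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop("empty interactome file: ", path)
  hasHeader <- grepl("protein|node|interactor|^a\tb$", tolower(first))
  d <- utils::read.table(path, header = hasHeader, sep = "\t",
                         stringsAsFactors = FALSE)
  if (nrow(d) == 0L) stop("empty interactome file: ", path)
  if (ncol(d) < 2L) stop("interactome edge list needs two columns")
  referenceInteractome(d[, 1:2], selfLoops = selfLoops)
}

#' Restrict a network to a search space
#'
#' Keeps only interactions whose host target belongs to the space;
#' effectors left with no interactions drop out of the interacting set.
#' Idempotent.
#'
#' @param net an [EffectorHostNetwork-class].
#' @param space a [SearchSpace-class].
#' @param dropHormoneSpaceOnly also drop edges flagged
#'   `hormone_space_only` (interactions only found in a hormone-protein
#'   extension of the space). Default `FALSE`; comparative cross-organism
#'   analyses turn this on to avoid biasing towards hormone proteins.
#' @return the restricted [EffectorHostNetwork-class].
#' @export
restrictToSpace <- function(net, space, dropHormoneSpaceOnly = FALSE) {
  e <- networkEdges(net)
  keep <- e$target %in% spaceMembers(space)
  if (dropHormoneSpaceOnly && "hormone_space_only" %in% names(e))
    keep <- keep & !(e$hormone_space_only %in% TRUE)
  e <- e[keep, , drop = FALSE]
  if ("out_of_space" %in% names(e)) e$out_of_space <- FALSE
  rownames(e) <- NULL
  new("EffectorHostNetwork", edges = e, organism = organism(net),
      searchSpace = searchSpaceName(space))
}

#' Export a network to file
#'
#' Supported formats: `"edge-table"` (TSV, round-trip stable with
#' [loadInteractionTable()]), `"SIF"` (Cytoscape simple interaction
#' format, relation token `pp`), `"GraphML"` (via igraph).
#'
#' @param net an [EffectorHostNetwork-class].
#' @param path output file path.
#' @param format one of `"edge-table"`, `"SIF"`, `"GraphML"`.
#' @return `path`, invisibly.
#' @export
exportNetwork <- function(net, path,
                          format = c("edge-table", "SIF", "GraphML")) {
  format <- match.arg(format)
  e <- networkEdges(net)
  if (format == "edge-table") {
    out <- data.frame(effector_id = e$effector, organism = organism(net),
                      host_protein = e$target, stringsAsFactors = FALSE)
    extra <- setdiff(names(e), c("effector", "target"))
    for (fc in extra) out[[fc]] <- e[[fc]]
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else if (format == "SIF") {
    writeLines(paste(e$effector, "pp", e$target, sep = "\t"), path)
  } else {
    g <- igraph::graph_from_data_frame(
      e[, c("effector", "target")], directed = FALSE)
    igraph::V(g)$type <- igraph::V(g)$name %in% e$target
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}
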