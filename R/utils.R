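#' @importFrom stats setNames
#' @importFrom utils head read.table write.table combn
#' @importFrom igraph sample_gnm sample_degseq as_edgelist
#'   graph_from_data_frame write_graph
NULL

#' Landmark screen bookkeeping
#'
#' Arithmetic helper for screen design summaries: the number of effector x
#' reporter combinations, the total number of assays (each combination
#' measured under both mock and stimulated conditions), and the percentage
#' of effectors with at least one significant call.
#'
#' @param nEffectors number of effector candidates tested.
#' @param nHormones number of hormone reporters.
#' @param nConditions conditions per combination (default 2: mock and
#'   treated).
#' @param nModulating optional number of effectors with >= 1 significant
#'   call, to compute the modulating percentage.
#' @return list with `nCombinations`, `nAssays`, and (when `nModulating`
#'   is given) `percentModulating`.
#' @examples
#' screenDesign(106, 5, nModulating = 86)
#' @export
screenDesign <- function(nEffectors, nHormones, nConditions = 2L,
                         nModulating = NULL) {
  out <- list(nCombinations = nEffectors * nHormones,
              nAssays = nEffectors * nHormones * nConditions)
  if (!is.null(nModulating))
    out$percentModulating <- 100 * nModulating / nEffectors
  out
}
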