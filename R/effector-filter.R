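#' @include AllClasses.R
NULL

#' Configuration for effector-candidate filtering
#'
#' @param requireComplete require a complete open reading frame.
#' @param requireSignalPeptide require a predicted secretion signal.
#' @param maxTmDomains maximum transmembrane domains outside the signal
#'   peptide (default 0: secreted proteins should have none).
#' @param minLog2fc minimum expression log2 fold-change during
#'   colonisation, evaluated as the maximum over `timepoints`. Default 1
#'   (at least 2-fold up-regulation at some colonisation stage).
#' @param timepoints names of the fold-change columns to consider
#'   (any-of semantics).
#' @return a list of class `"FilterConfig"`.
#' @export
filterConfig <- function(requireComplete = TRUE,
                         requireSignalPeptide = TRUE,
                         maxTmDomains = 0L, minLog2fc = 1,
                         timepoints = c("log2fc_3dai", "log2fc_10dai")) {
  structure(list(requireComplete = requireComplete,
                 requireSignalPeptide = requireSignalPeptide,
                 maxTmDomains = as.integer(maxTmDomains),
                 minLog2fc = minLog2fc, timepoints = timepoints),
            class = "FilterConfig")
}

#' Rule-based filtering of effector candidates
#'
#' Applies the candidate-selection rules to a precomputed feature table
#' (signal-peptide and transmembrane predictions and expression
#' fold-changes are inputs; the external predictors are not run here). A
#' gene is retained iff it has a complete ORF, a signal peptide, at most
#' `maxTmDomains` transmembrane domains outside the signal peptide, and a
#' maximum log2 fold-change over the configured colonisation timepoints of
#' at least `minLog2fc`. Rules are evaluated in that order and each
#' rejection is annotated with the first failing rule, so
#' retained + rejected partition the input. Relaxing any threshold never
#' shrinks the retained set. Presence of functional domains is carried
#' through but is not a rejection criterion.
#'
#' @param features data.frame with columns `gene`, `complete_orf`,
#'   `signal_peptide`, `tm_domains` and the fold-change columns named in
#'   the config (e.g. `log2fc_3dai`, `log2fc_10dai`).
#' @param cfg a [filterConfig()].
#' @return list with `retained` (feature rows of surviving genes) and
#'   `rejected` (data.frame `gene`, `reason` with reasons
#'   `incomplete_orf`, `no_signal_peptide`, `tm_domains`,
#'   `low_expression`).
#' @export
filterCandidates <- function(features, cfg = filterConfig()) {
  need <- c("gene", "complete_orf", "signal_peptide", "tm_domains",
            cfg$timepoints)
  miss <- setdiff(need, names(features))
  if (length(miss))
    stop("feature table missing column(s): ", paste(miss, collapse = ", "))
  for (col in need) {
    bad <- is.na(features[[col]])
    if (any(bad))
      stop("missing '", col, "' for gene ",
           features$gene[which(bad)[1L]])
  }
  maxFc <- do.call(pmax, features[cfg$timepoints])
  reason <- rep(NA_character_, nrow(features))
  reason[cfg$requireComplete & !features$complete_orf] <- "incomplete_orf"
  fail <- is.na(reason) & cfg$requireSignalPeptide &
    !features$signal_peptide
  reason[fail] <- "no_signal_peptide"
  fail <- is.na(reason) & features$tm_domains > cfg$maxTmDomains
  reason[fail] <- "tm_domains"
  fail <- is.na(reason) & maxFc < cfg$minLog2fc
  reason[fail] <- "low_expression"
  keep <- is.na(reason)
  list(retained = features[keep, , drop = FALSE],
       rejected = data.frame(gene = features$gene[!keep],
                             reason = reason[!keep],
                             stringsAsFactors = FALSE))
}

#' Secretion call from a yeast signal-sequence trap growth assay
#'
#' Growth on sucrose-only medium indicates secretion of the invertase
#' fusion, i.e. a functional signal peptide. Each construct's growth
#' readings (OD) are compared to the no-signal-peptide control by a
#' two-tailed unpaired t-test; a construct is called secreted iff its mean
#' exceeds the control mean and p < `alpha`.
#'
#' @param odValues named list: construct -> numeric growth readings
#'   (>= 3 replicates recommended; < 2 is an error).
#' @param noSpControl numeric readings of the no-signal-peptide control.
#' @param alpha significance level (default 0.05).
#' @return data.frame `construct`, `meanOd`, `controlMean`, `p`,
#'   `secreted`.
#' @export
ysstCall <- function(odValues, noSpControl, alpha = 0.05) {
  if (length(noSpControl) < 2L) stop("need >= 2 control replicates")
  rows <- lapply(names(odValues), function(cn) {
    v <- odValues[[cn]]
    if (length(v) < 2L)
      stop("construct '", cn, "' has < 2 replicates")
    if (length(v) < 3L)
      warning("construct '", cn, "' has < 3 replicates")
    cmp <- groupCompare(v, noSpControl,
                        kind = "t_test_two_tailed_unpaired")
    data.frame(construct = cn, meanOd = mean(v),
               controlMean = mean(noSpControl), p = cmp$p,
               secreted = mean(v) > mean(noSpControl) & cmp$p < alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
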