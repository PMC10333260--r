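#' @include AllClasses.R
NULL

checkWellColumns <- function(wells) {
  need <- c("plate", "well", "construct", "reporter", "condition",
            "luc", "gus")
  miss <- setdiff(need, names(wells))
  if (length(miss))
    stop("well table missing column(s): ", paste(miss, collapse = ", "))
  if (any(wells$luc < 0, na.rm = TRUE) || any(wells$gus < 0, na.rm = TRUE))
    stop("negative luminescence/fluorescence readings")
  bad <- setdiff(unique(wells$reporter), SCREEN_HORMONES)
  if (length(bad))
    stop("unknown reporter hormone(s): ", paste(bad, collapse = ", "))
  invisible(wells)
}

#' Plate-level quality filter on transformation efficiency
#'
#' Removes wells whose glucuronidase (GUS) signal indicates failed
#' transformation. Per plate, the threshold is 50% of the "highest 10%"
#' GUS value, read as the mean of the top ceiling(0.1 * n) GUS readings on
#' that plate (a `"max"` variant uses the plate maximum instead). Wells
#' with GUS below the threshold are omitted. The retained set is invariant
#' under positive rescaling of a plate's GUS channel.
#'
#' @param wells data.frame with columns `plate`, `well`, `construct`,
#'   `reporter`, `condition`, `luc`, `gus` (extra columns pass through).
#' @param topStat `"top_decile_mean"` (default) or `"max"`.
#' @return list with `kept` and `omitted` well tables.
#' @export
qcFilterWells <- function(wells, topStat = c("top_decile_mean", "max")) {
  topStat <- match.arg(topStat)
  checkWellColumns(wells)
  keep <- logical(nrow(wells))
  for (p in unique(wells$plate)) {
    i <- which(wells$plate == p)
    g <- wells$gus[i]
    high <- if (topStat == "max") max(g)
            else mean(sort(g, decreasing = TRUE)[seq_len(ceiling(0.1 * length(g)))])
    keepP <- g >= 0.5 * high
    if (!any(keepP))
      stop("plate '", p, "' failed QC: all wells below threshold")
    keep[i] <- keepP
  }
  list(kept = wells[keep, , drop = FALSE],
       omitted = wells[!keep, , drop = FALSE])
}

#' GUS-normalise luciferase readings and aggregate replicates
#'
#' Normalises each well's luciferase signal by its GUS signal
#' (transformation-efficiency control) and averages replicate wells per
#' (construct, reporter, condition), pooling across plates after per-plate
#' QC.
#'
#' @param wells QC-passed well table (the `kept` element of
#'   [qcFilterWells()]). Wells with zero GUS are excluded with a warning.
#' @return data.frame `construct`, `reporter`, `condition`, `activity`
#'   (mean luc/gus), `nWells`.
#' @export
normalizeAndAggregate <- function(wells) {
  checkWellColumns(wells)
  zero <- wells$gus == 0
  if (any(zero)) {
    warning(sum(zero), " well(s) with zero GUS excluded")
    wells <- wells[!zero, , drop = FALSE]
  }
  wells$normalized <- wells$luc / wells$gus
  agg <- stats::aggregate(normalized ~ construct + reporter + condition,
                          data = wells, FUN = mean)
  names(agg)[names(agg) == "normalized"] <- "activity"
  cnt <- stats::aggregate(normalized ~ construct + reporter + condition,
                          data = wells, FUN = length)
  agg$nWells <- cnt$normalized
  agg[order(agg$construct, agg$reporter, agg$condition), , drop = FALSE]
}

lookupActivity <- function(agg, construct, reporter, condition) {
  i <- agg$construct == construct & agg$reporter == reporter &
    agg$condition == condition
  if (!any(i)) NA_real_ else agg$activity[which(i)[1L]]
}

#' Effector-to-empty-vector reporter ratios
#'
#' For one effector and one hormone reporter, forms the mock ratio
#' (effector mock activity / empty-vector mock activity) and the treatment
#' ratio (same under hormone treatment), their product — the overall
#' effect of the effector on the pathway — its log2, and the ranking
#' factor |log2 product|.
#'
#' @param agg aggregated activities from [normalizeAndAggregate()];
#'   must contain empty-vector (`emptyVector`) rows for both conditions.
#' @param effector construct id.
#' @param reporter hormone label.
#' @param emptyVector construct id of the empty-vector control
#'   (default `"EV"`).
#' @return one-row data.frame `effector`, `reporter`, `mockRatio`,
#'   `treatmentRatio`, `product`, `log2Product`, `rankFactor`.
#' @export
effectorRatios <- function(agg, effector, reporter, emptyVector = "EV") {
  evM <- lookupActivity(agg, emptyVector, reporter, "mock")
  evT <- lookupActivity(agg, emptyVector, reporter, "treated")
  if (is.na(evM) || is.na(evT))
    stop("missing empty-vector baseline for reporter ", reporter)
  if (evM == 0 || evT == 0)
    stop("zero empty-vector baseline for reporter ", reporter)
  efM <- lookupActivity(agg, effector, reporter, "mock")
  efT <- lookupActivity(agg, effector, reporter, "treated")
  if (is.na(efM) || is.na(efT))
    stop("missing measurements for ", effector, " / ", reporter)
  mockRatio <- efM / evM
  treatmentRatio <- efT / evT
  product <- mockRatio * treatmentRatio
  data.frame(effector = effector, reporter = reporter,
             mockRatio = mockRatio, treatmentRatio = treatmentRatio,
             product = product, log2Product = log2(product),
             rankFactor = abs(log2(product)), stringsAsFactors = FALSE)
}

#' Call significant reporter modulation
#'
#' A reporter change is significant when the effector alters it more than
#' `foldThreshold`-fold (strict) in either direction versus the
#' empty-vector control, evaluated on the product of the mock and
#' treatment ratios: `induced` when product > foldThreshold, `suppressed`
#' when product < 1/foldThreshold, `ns` otherwise (a product exactly at
#' the boundary is `ns`). With `on = "either_ratio"` a single ratio beyond
#' the threshold suffices (direction from the log2 product).
#'
#' @param records data.frame from [effectorRatios()] (any number of rows).
#' @param foldThreshold fold-change threshold (default 2).
#' @param on `"product"` (default) or `"either_ratio"`.
#' @return `records` with a `call` column.
#' @export
callModulation <- function(records, foldThreshold = 2,
                           on = c("product", "either_ratio")) {
  on <- match.arg(on)
  hit <- if (on == "product")
    records$product > foldThreshold | records$product < 1 / foldThreshold
  else
    pmax(records$mockRatio, 1 / records$mockRatio) > foldThreshold |
    pmax(records$treatmentRatio, 1 / records$treatmentRatio) > foldThreshold
  records$call <- "ns"
  records$call[hit & records$log2Product > 0] <- "induced"
  records$call[hit & records$log2Product < 0] <- "suppressed"
  records
}

#' Run the full reporter-screen analysis
#'
#' Pipeline driver: per-plate QC, GUS normalisation, replicate
#' aggregation, effector/empty-vector ratios for every effector x reporter
#' combination present, and modulation calls.
#'
#' @inheritParams qcFilterWells
#' @inheritParams callModulation
#' @param emptyVector empty-vector construct id.
#' @return data.frame of scored records (one row per effector x reporter)
#'   with a `call` column; the omitted wells are attached as attribute
#'   `"omittedWells"`.
#' @export
screenAnalysis <- function(wells, foldThreshold = 2, emptyVector = "EV",
                           topStat = "top_decile_mean") {
  qc <- qcFilterWells(wells, topStat = topStat)
  agg <- normalizeAndAggregate(qc$kept)
  combos <- unique(agg[agg$construct != emptyVector,
                       c("construct", "reporter")])
  ## a combination can lose all wells of one condition to QC; skip it
  ## (a missing empty-vector baseline remains an error)
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    full <- all(vapply(c("mock", "treated"), function(cond)
      !is.na(lookupActivity(agg, combos$construct[i],
                            combos$reporter[i], cond)), TRUE))
    if (!full) {
      warning("no QC-passed wells for ", combos$construct[i], " / ",
              combos$reporter[i], " in one condition; skipped")
      return(NULL)
    }
    effectorRatios(agg, combos$construct[i], combos$reporter[i],
                   emptyVector = emptyVector)
  })
  records <- callModulation(do.call(rbind, rows),
                            foldThreshold = foldThreshold)
  names(records)[names(records) == "effector"] <- "effector"
  attr(records, "omittedWells") <- qc$omitted
  records
}

#' Rank effectors by effect strength per hormone
#'
#' Sorts records within each hormone reporter by the ranking factor
#' |log2(mock ratio x treatment ratio)|, largest first, and returns the
#' top `n`. Ties are broken lexicographically by effector id so the
#' selection is deterministic.
#'
#' @param records data.frame from [screenAnalysis()] or
#'   [effectorRatios()].
#' @param n how many effectors per hormone (default 10).
#' @return data.frame of the top records with a `rank` column, grouped by
#'   reporter.
#' @export
rankEffectors <- function(records, n = 10L) {
  out <- lapply(split(records, records$reporter), function(d) {
    d <- d[order(-d$rankFactor, d$effector), , drop = FALSE]
    d <- utils::head(d, n)
    d$rank <- seq_len(nrow(d))
    d
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Summarise a reporter screen
#'
#' Reproduces the standard screen summary: per-hormone counts of inducing
#' and suppressing effectors, the number of effectors with at least one
#' significant call, the number significant in exactly one hormone
#' pathway, and direction totals.
#'
#' @param records called records from [screenAnalysis()].
#' @return list with `perHormone` (data.frame `reporter`, `induced`,
#'   `suppressed`, `changed`), `nCombinations`, `nSignificant`,
#'   `nInduced`, `nSuppressed`, `nModulatingEffectors`,
#'   `nSingleHormoneEffectors`.
#' @export
screenSummary <- function(records) {
  sig <- records[records$call != "ns", , drop = FALSE]
  perH <- lapply(split(records, records$reporter), function(d)
    data.frame(reporter = d$reporter[1L],
               induced = sum(d$call == "induced"),
               suppressed = sum(d$call == "suppressed"),
               changed = sum(d$call != "ns"),
               stringsAsFactors = FALSE))
  perH <- do.call(rbind, perH)
  rownames(perH) <- NULL
  nPathways <- table(sig$effector)
  list(perHormone = perH,
       nCombinations = nrow(records),
       nSignificant = nrow(sig),
       nInduced = sum(records$call == "induced"),
       nSuppressed = sum(records$call == "suppressed"),
       nModulatingEffectors = length(unique(sig$effector)),
       nSingleHormoneEffectors = sum(nPathways == 1L))
}

## Compact letter display from a logical "significantly different" matrix
## (insert-and-absorb): groups sharing a letter are not significantly
## different.
letterGroups <- function(diffMat) {
  groups <- rownames(diffMat)
  letters_ <- list()
  for (g in groups) {
    placed <- FALSE
    for (i in seq_along(letters_)) {
      if (!any(diffMat[g, letters_[[i]]])) {
        letters_[[i]] <- c(letters_[[i]], g)
        placed <- TRUE
      }
    }
    if (!placed) letters_[[length(letters_) + 1L]] <- g
  }
  out <- stats::setNames(rep("", length(groups)), groups)
  for (i in seq_along(letters_))
    out[letters_[[i]]] <- paste0(out[letters_[[i]]], letters[i])
  out
}

#' Reporter analysis in mutant protoplasts
#'
#' For reporter assays across genotypes (wild type plus mutants): within
#' each biological-replicate batch, GUS-normalised activities are divided
#' by the wild-type mock mean of that batch (reducing between-replicate
#' variation; the wild-type mock mean is exactly 1 by construction). The
#' normalised values are then analysed by two-way ANOVA
#' (genotype x treatment) with Tukey all-pairs comparisons of the
#' genotype:treatment cell means, summarised as compact letter groups.
#'
#' @param wells well table as in [qcFilterWells()] with `construct`
#'   holding genotype ids and an additional `batch` column (biological
#'   replicate); single-batch tables may omit it.
#' @param wildType wild-type genotype id (default `"Col-0"`).
#' @return list with `values` (per-well normalised data), `anova` (the
#'   two-way ANOVA table), `tukey` (pairwise adjusted p-values for
#'   genotype:treatment cells) and `letters` (compact letter display).
#' @export
mutantReporterAnalysis <- function(wells, wildType = "Col-0") {
  checkWellColumns(wells)
  if (!"batch" %in% names(wells)) wells$batch <- "batch1"
  wells$normalized <- wells$luc / wells$gus
  out <- lapply(split(wells, wells$batch), function(d) {
    wtMock <- d$normalized[d$construct == wildType &
                             d$condition == "mock"]
    if (length(wtMock) == 0L)
      stop("no wild-type ('", wildType, "') mock wells in batch ",
           d$batch[1L])
    d$relative <- d$normalized / mean(wtMock)
    d
  })
  values <- do.call(rbind, out)
  rownames(values) <- NULL
  values$construct <- factor(values$construct)
  values$condition <- factor(values$condition)
  fit <- stats::aov(relative ~ construct * condition, data = values)
  values$cell <- interaction(values$construct, values$condition, sep = ":")
  cellFit <- stats::aov(relative ~ cell, data = values)
  tk <- stats::TukeyHSD(cellFit)$cell
  cells <- levels(values$cell)
  diffMat <- matrix(FALSE, length(cells), length(cells),
                    dimnames = list(cells, cells))
  ## Tukey rownames are "lvl2-lvl1"; genotype ids may contain "-", so
  ## resolve the split against the known cell labels.
  for (r in rownames(tk)) {
    if (tk[r, "p adj"] >= 0.05 || is.na(tk[r, "p adj"])) next
    for (c1 in cells) {
      if (startsWith(r, paste0(c1, "-"))) {
        c2 <- substring(r, nchar(c1) + 2L)
        if (c2 %in% cells) {
          diffMat[c1, c2] <- TRUE
          diffMat[c2, c1] <- TRUE
          break
        }
      }
    }
  }
  list(values = values, anova = summary(fit), tukey = tk,
       letters = letterGroups(diffMat))
}
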