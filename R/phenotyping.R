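#' @include AllClasses.R
NULL

#' Hormone tolerance index of transgenic or mutant lines
#'
#' Quantifies how strongly a line's growth trait (primary root length,
#' lateral root number, hypocotyl length) responds to a hormone treatment
#' relative to control lines. Per line, the response is
#' `100 * treated mean / mock mean` (percent of mock). Each test line's
#' response is divided by the mean response of the control lines and
#' multiplied by 100 to give relative responsiveness; tolerance is that
#' value minus 100 (percentage points). Negative tolerance means the
#' line's trait is attenuated more strongly by the treatment than the
#' controls' (reduced tolerance); positive means increased tolerance. The
#' index is invariant to the trait's measurement units, and the mean
#' tolerance of the control lines themselves is 0 by construction.
#'
#' @param measurements data.frame with columns `line`, `genotype_class`
#'   (`effector_line` / `control_line` / `mutant` / `wild_type`),
#'   `treatment` (`"mock"` or a hormone label), `replicate`, `trait`,
#'   `value`.
#' @param trait which trait to analyse.
#' @param treatment the non-mock treatment to compare against mock.
#' @param controlClass genotype class of the control lines
#'   (default `"control_line"`).
#' @param responseAs `"percent_of_mock"` (default: treated/mock x 100) or
#'   `"percent_reduction"` (100 - treated/mock x 100).
#' @return data.frame, one row per non-control line and one per control
#'   line, with `line`, `trait`, `treatment`, `responsePercent`,
#'   `relativeResponsivenessPercent`, `tolerance`.
#' @export
hormoneTolerance <- function(measurements, trait, treatment,
                             controlClass = "control_line",
                             responseAs = c("percent_of_mock",
                                            "percent_reduction")) {
  responseAs <- match.arg(responseAs)
  d <- measurements[measurements$trait == trait &
                      measurements$treatment %in% c("mock", treatment), ,
                    drop = FALSE]
  if (nrow(d) == 0L) stop("no measurements for trait '", trait, "'")
  lines_ <- unique(d$line)
  resp <- vapply(lines_, function(l) {
    mock <- d$value[d$line == l & d$treatment == "mock"]
    trt <- d$value[d$line == l & d$treatment == treatment]
    if (length(mock) == 0L || length(trt) == 0L)
      stop("line '", l, "' lacks mock or treated measurements")
    if (mean(mock) == 0) stop("zero mock mean for line '", l, "'")
    r <- 100 * mean(trt) / mean(mock)
    if (responseAs == "percent_reduction") 100 - r else r
  }, 1)
  cls <- vapply(lines_, function(l)
    d$genotype_class[d$line == l][1L], "")
  ctrl <- resp[cls == controlClass]
  if (length(ctrl) == 0L)
    stop("no control lines of class '", controlClass, "'")
  rel <- 100 * resp / mean(ctrl)
  data.frame(line = lines_, trait = trait, treatment = treatment,
             genotype_class = cls,
             responsePercent = unname(resp),
             relativeResponsivenessPercent = unname(rel),
             tolerance = unname(rel - 100),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Relative anthocyanin content from a two-wavelength absorbance pair
#'
#' `content = (A530 - 0.25 * Afar) * 5`, where A530 is the absorbance at
#' 530 nm (anthocyanin peak) and Afar the far-red reading correcting for
#' chlorophyll/turbidity. Vectorised; linear in both absorbances. Negative
#' values (far-red reading dominating) are returned as-is with a warning.
#'
#' @param a530 absorbance at 530 nm (>= 0).
#' @param aFar far-red absorbance (>= 0).
#' @return numeric vector of relative contents.
#' @export
anthocyaninContent <- function(a530, aFar) {
  if (any(a530 < 0) || any(aFar < 0)) stop("absorbances must be >= 0")
  content <- (a530 - 0.25 * aFar) * 5
  if (any(content < 0))
    warning("negative anthocyanin content value(s) returned as-is")
  content
}

#' Germination rates per row and per plate
#'
#' @param germinated integer vector of germinated-seed counts per row.
#' @param total integer vector of sown-seed counts per row (> 0).
#' @return list with `rowRates` and `plateRate` (mean of row rates).
#' @export
germinationRate <- function(germinated, total) {
  if (any(total <= 0)) stop("total seed counts must be > 0")
  if (any(germinated > total))
    stop("more germinated than sown seeds in a row")
  if (any(germinated < 0)) stop("negative counts")
  rates <- germinated / total
  list(rowRates = rates, plateRate = mean(rates))
}

#' Relative expression by the delta-Ct methods
#'
#' `2^-dCt` with `dCt = Ct_target - Ct_reference` (absolute expression
#' relative to the reference gene); when a calibrator delta-Ct is given,
#' `2^-(dCt - dCt_calibrator)` (the delta-delta-Ct method).
#'
#' @param ctTarget Ct of the gene of interest.
#' @param ctReference Ct of the reference gene.
#' @param calibratorDelta optional delta-Ct of the calibrator sample.
#' @return expression value(s).
#' @export
relativeExpression <- function(ctTarget, ctReference,
                               calibratorDelta = NULL) {
  dCt <- ctTarget - ctReference
  if (!is.null(calibratorDelta)) dCt <- dCt - calibratorDelta
  2^(-dCt)
}

#' Two-group and multi-group comparisons for phenotyping data
#'
#' `t_test_two_tailed_unpaired`: Welch two-sample two-tailed t-test of
#' `a` vs `b`; degenerate inputs with identical constant groups return
#' p = 1 by convention. `anova_tukey`: one-way ANOVA across the groups of
#' a named list with Tukey all-pairs comparisons and compact letter
#' groups.
#'
#' @param a numeric vector (first group), or for `anova_tukey` a named
#'   list of numeric vectors.
#' @param b numeric vector (second group; ignored for `anova_tukey`).
#' @param kind `"t_test_two_tailed_unpaired"` or `"anova_tukey"`.
#' @return for the t-test, list with `statistic` and `p`; for ANOVA, list
#'   with `anova`, `tukey` and `letters`.
#' @export
groupCompare <- function(a, b = NULL,
                         kind = c("t_test_two_tailed_unpaired",
                                  "anova_tukey")) {
  kind <- match.arg(kind)
  if (kind == "t_test_two_tailed_unpaired") {
    if (length(a) < 2L || length(b) < 2L)
      stop("t-test needs >= 2 values per group")
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      if (mean(a) == mean(b))
        return(list(statistic = 0, p = 1))
      return(list(statistic = Inf * sign(mean(a) - mean(b)), p = 0))
    }
    tt <- stats::t.test(a, b, alternative = "two.sided", paired = FALSE)
    list(statistic = unname(tt$statistic), p = tt$p.value)
  } else {
    stopifnot(is.list(a), !is.null(names(a)))
    d <- data.frame(value = unlist(a, use.names = FALSE),
                    group = factor(rep(names(a), lengths(a))))
    fit <- stats::aov(value ~ group, data = d)
    tk <- stats::TukeyHSD(fit)$group
    groups <- levels(d$group)
    diffMat <- matrix(FALSE, length(groups), length(groups),
                      dimnames = list(groups, groups))
    for (r in rownames(tk)) {
      if (is.na(tk[r, "p adj"]) || tk[r, "p adj"] >= 0.05) next
      for (g1 in groups) {
        if (startsWith(r, paste0(g1, "-"))) {
          g2 <- substring(r, nchar(g1) + 2L)
          if (g2 %in% groups) {
            diffMat[g1, g2] <- TRUE; diffMat[g2, g1] <- TRUE; break
          }
        }
      }
    }
    list(anova = summary(fit), tukey = tk,
         letters = letterGroups(diffMat))
  }
}
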