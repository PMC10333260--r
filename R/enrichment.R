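#' @include AllClasses.R AllGenerics.R
NULL

#' Build an annotation map from a gene/term table
#'
#' @param table data.frame with columns `gene` and `term` (one row per
#'   annotation), or a file path. Files may be plain 2-column TSV
#'   (gene, term) or a minimal GAF-like dialect in which column 2 is the
#'   gene id and column 5 the term id (detected by column count >= 5 and
#'   absence of a header).
#' @param termLabels optional named character vector of term descriptions.
#' @return an [AnnotationMap-class].
#' @export
annotationMap <- function(table, termLabels = character()) {
  if (is.character(table) && length(table) == 1L) {
    d <- utils::read.table(table, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE, comment.char = "!")
    table <- if (ncol(d) >= 5L)
      data.frame(gene = d[[2L]], term = d[[5L]], stringsAsFactors = FALSE)
    else
      data.frame(gene = d[[1L]], term = d[[2L]], stringsAsFactors = FALSE)
    if (identical(tolower(unlist(table[1L, ])), c("gene", "term")))
      table <- table[-1L, , drop = FALSE]
  }
  stopifnot(all(c("gene", "term") %in% names(table)))
  table <- unique(table[, c("gene", "term")])
  g2t <- lapply(split(table$term, table$gene), function(x) sort(unique(x)))
  t2g <- lapply(split(table$gene, table$term), function(x) sort(unique(x)))
  new("AnnotationMap", gene2term = g2t, term2gene = t2g,
      termLabels = termLabels)
}

#' Per-term enrichment of a query gene set
#'
#' For every annotation term with at least one query gene, computes the
#' classic one-sided Fisher (hypergeometric upper tail) enrichment p-value
#' of the query against the reference: with N reference genes of which K
#' carry the term, and n query genes of which k carry it,
#' `fisher_p = P(X >= k)` for X hypergeometric(K, N-K, n). When per-gene
#' scores are supplied, a two-sample Kolmogorov-Smirnov p-value comparing
#' scores of term members vs non-members within the reference is added.
#' No term-graph decorrelation is performed; annotations are taken as
#' given, including any ancestor propagation already present in the map.
#'
#' @param query character vector of query genes; must be a subset of
#'   `reference`.
#' @param reference character vector, the gene universe.
#' @param ann an [AnnotationMap-class].
#' @param scores optional named numeric vector of per-gene scores.
#' @return data.frame with columns `term`, `k`, `K`, `n`, `N`, `fisher_p`,
#'   and `ks_p` when scores are given, ordered by `fisher_p`.
#' @export
termEnrichment <- function(query, reference, ann, scores = NULL) {
  query <- unique(query)
  reference <- unique(reference)
  offenders <- setdiff(query, reference)
  if (length(offenders))
    stop("query genes absent from reference: ",
         paste(utils::head(offenders, 5L), collapse = ", "),
         if (length(offenders) > 5L) ", ...")
  N <- length(reference)
  n <- length(query)
  t2g <- ann@term2gene
  rows <- lapply(names(t2g), function(term) {
    members <- intersect(t2g[[term]], reference)
    k <- sum(query %in% members)
    if (k == 0L) return(NULL)
    K <- length(members)
    fp <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    out <- data.frame(term = term, k = k, K = K, n = n, N = N,
                      fisher_p = fp, stringsAsFactors = FALSE)
    if (!is.null(scores)) {
      inS <- scores[intersect(members, names(scores))]
      outS <- scores[intersect(setdiff(reference, members), names(scores))]
      out$ks_p <- if (length(inS) && length(outS))
        suppressWarnings(stats::ks.test(inS, outS)$p.value) else NA_real_
    }
    out
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) {
    res <- data.frame(term = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), fisher_p = numeric(),
                      stringsAsFactors = FALSE)
    if (!is.null(scores)) res$ks_p <- numeric()
    return(res)
  }
  res <- res[order(res$fisher_p, res$term), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Coverage-based filtering of enrichment terms
#'
#' Specificity/redundancy filter used for comparative enrichment: a term is
#' kept only if it annotates at most `maxRefFrac` of the reference set
#' (removing broad, uninformative terms) and covers at least
#' `minQueryFrac` of the query set (removing terms supported by too few
#' query genes). With the reference defaults this removes terms annotating
#' more than 10% of the reference and terms representing less than 5% of
#' the query.
#'
#' @param rows data.frame from [termEnrichment()].
#' @param referenceSize N, the reference set size (defaults to the `N`
#'   column of `rows`).
#' @param querySize n, the query set size (defaults to the `n` column).
#' @param maxRefFrac maximum reference coverage K/N (default 0.10).
#' @param minQueryFrac minimum query coverage k/n (default 0.05).
#' @return the filtered subset of `rows` (order preserved).
#' @export
filterTerms <- function(rows, referenceSize = NULL, querySize = NULL,
                        maxRefFrac = 0.10, minQueryFrac = 0.05) {
  if (nrow(rows) == 0L) return(rows)
  N <- if (is.null(referenceSize)) rows$N else referenceSize
  n <- if (is.null(querySize)) rows$n else querySize
  keep <- rows$K <= maxRefFrac * N & rows$k >= minQueryFrac * n
  out <- rows[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; a thin wrapper over
#' [stats::p.adjust()] with input validation, returned in the original
#' order.
#'
#' @param pvalues numeric vector of raw p-values in \[0, 1\].
#' @return adjusted p-values, same length and order.
#' @export
bhAdjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Differential-expression threshold filter
#'
#' Applies the standard reporting filter to a precomputed per-gene
#' differential-expression statistics table: BH-adjusts the p-values and
#' keeps genes with `|log2fc| >= lfcCut` (inclusive) and adjusted
#' `p < alpha` (strict).
#'
#' @param stats data.frame with columns `gene`, `log2fc`, `pvalue`; one
#'   row per gene.
#' @param lfcCut absolute log2 fold-change cutoff (default 0.6).
#' @param alpha adjusted-p cutoff (default 0.05).
#' @return list with `genes` (character vector of retained genes) and
#'   `table` (the input with an `adjusted_p` and `significant` column).
#' @export
degFilter <- function(stats, lfcCut = 0.6, alpha = 0.05) {
  stopifnot(all(c("gene", "log2fc", "pvalue") %in% names(stats)))
  if (anyDuplicated(stats$gene))
    stop("duplicate genes in statistics table")
  stats$adjusted_p <- bhAdjust(stats$pvalue)
  stats$significant <- abs(stats$log2fc) >= lfcCut &
    stats$adjusted_p < alpha
  list(genes = stats$gene[stats$significant], table = stats)
}
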