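## Genomic alteration summaries: per-gene mutation and copy-number
## alteration frequencies within a cohort, and the association of
## alterations with expression (rank-sum test, CNV/methylation--expression
## Pearson correlation).

#' Per-gene somatic mutation frequency in a cohort
#'
#' A sample counts as mutated in a gene if it carries at least one
#' qualifying variant row; multiple variants in the same gene count once.
#'
#' @param muts data.frame with columns `sample`, `gene`, `variant_class`.
#' @param cohort_samples Character vector of samples defining the cohort.
#' @param genes Genes to report (frequency 0 for genes never mutated).
#' @param variant_classes Optional include-list of variant classes; by
#'   default every row counts (which classes "count" as mutations is a
#'   dataset convention, so it is exposed as a knob).
#' @return data.frame `(gene, mutation_freq, n_mutated, n_samples)`.
#' @export
mutation_frequency <- function(muts, cohort_samples, genes,
                               variant_classes = NULL) {
  if (length(cohort_samples) == 0L) .stopf("empty cohort")
  if (!all(c("sample", "gene") %in% names(muts))) {
    .stopf("'muts' needs columns 'sample' and 'gene'")
  }
  keep <- muts$sample %in% cohort_samples
  if (!is.null(variant_classes)) {
    keep <- keep & muts$variant_class %in% variant_classes
  }
  m <- muts[keep, , drop = FALSE]
  n <- length(cohort_samples)
  counts <- vapply(genes, function(g) {
    length(unique(m$sample[m$gene == g]))
  }, integer(1L))
  data.frame(gene = genes, mutation_freq = counts / n,
             n_mutated = counts, n_samples = n,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-gene CNV amplification and deletion frequency
#'
#' On GISTIC-like thresholded values a sample is called amplified when its
#' value is `>= amp_ge` and deleted when `<= del_le`; the thresholds make
#' the two calls mutually exclusive per sample.
#'
#' @param cnv Gene-by-sample numeric matrix of copy-number values.
#' @param cohort_samples Samples defining the cohort (must all be columns).
#' @param amp_ge,del_le Call thresholds; `del_le < amp_ge` required.
#' @return data.frame `(gene, amp_freq, del_freq, n_samples)`.
#' @export
cnv_frequency <- function(cnv, cohort_samples, amp_ge = 1, del_le = -1) {
  if (del_le >= amp_ge) .stopf("'del_le' must be < 'amp_ge'")
  if (length(cohort_samples) == 0L) .stopf("empty cohort")
  missing <- setdiff(cohort_samples, colnames(cnv))
  if (length(missing)) {
    .stopf("cohort sample '%s' missing from CNV matrix", missing[1L])
  }
  m <- cnv[, cohort_samples, drop = FALSE]
  n <- ncol(m)
  data.frame(gene = rownames(m),
             amp_freq = rowSums(m >= amp_ge) / n,
             del_freq = rowSums(m <= del_le) / n,
             n_samples = n,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Rank-sum test of expression between altered and unaltered samples
#'
#' Wilcoxon rank-sum, exact enumeration when both groups have at most 10
#' observations and the pooled values are tie-free, otherwise the normal
#' approximation with tie correction.
#'
#' @param expr Numeric expression values, one per sample.
#' @param status Logical (or 0/1) per-sample alteration flag.
#' @return list `(statistic, p_value, median_altered, median_unaltered)`.
#' @export
alteration_expression_test <- function(expr, status) {
  status <- as.logical(status)
  x <- expr[status]
  y <- expr[!status]
  if (length(x) == 0L || length(y) == 0L) {
    .stopf("both altered and unaltered groups must be non-empty")
  }
  ht <- rank_sum_test(x, y)
  list(statistic = ht$statistic, p_value = ht$p_value,
       median_altered = stats::median(x),
       median_unaltered = stats::median(y))
}

#' Wilcoxon rank-sum test (exact for small tie-free groups)
#'
#' @param x,y Numeric value vectors for the two groups.
#' @return list `(statistic, p_value, exact)`.
#' @export
rank_sum_test <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) .stopf("empty group")
  exact <- length(x) <= 10L && length(y) <= 10L &&
    !anyDuplicated(c(x, y))
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       exact = exact)
}

#' Pearson correlation between expression and another per-sample value
#'
#' Used for CNV--expression and methylation--expression association; the
#' p-value comes from the t distribution with `n - 2` degrees of freedom.
#'
#' @param expr,other Paired numeric vectors, at least 3 observations.
#' @return list `(r, p_value, n)`.
#' @export
omic_expression_correlation <- function(expr, other) {
  if (length(expr) != length(other)) .stopf("vectors differ in length")
  if (length(expr) < 3L) .stopf("need at least 3 paired observations")
  if (stats::sd(expr) == 0 || stats::sd(other) == 0) {
    .stopf("undefined correlation: constant vector")
  }
  ht <- stats::cor.test(expr, other, method = "pearson")
  list(r = unname(ht$estimate), p_value = ht$p.value, n = length(expr))
}
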