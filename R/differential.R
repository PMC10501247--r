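## Differential expression and promoter-methylation calling.
## Expression: per-gene Welch t-test on log2 values with Benjamini-
## Hochberg adjustment; a gene is called up/down only when |log2 fold
## change| exceeds 1 (strict) AND the adjusted p falls below alpha.
## Methylation: promoter-probe beta means per gene, Wilcoxon rank-sum,
## and delta-beta (difference of group mean betas).

#' Benjamini-Hochberg step-up adjustment
#'
#' Classic step-up procedure: with ordered p-values `p_(1) <= ... <= p_(n)`
#' the adjusted value is `min_{j >= i} min(1, n * p_(j) / j)`, reported in
#' the original input order.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order as the input.
#' @export
bh_adjust <- function(pvals) {
  if (length(pvals) == 0L) return(numeric(0))
  if (anyNA(pvals) || any(pvals < 0 | pvals > 1)) {
    .stopf("p-values must lie in [0, 1]")
  }
  n <- length(pvals)
  o <- order(pvals, decreasing = TRUE)
  q <- pmin(1, cummin(pvals[o] * n / seq.int(n, 1L)))
  q[order(o)]
}

#' Differential expression between cancer and normal cohorts
#'
#' Per gene: log2 fold change as the difference of group means of log2
#' values, a two-sided Welch t-test, BH adjustment over all tested genes,
#' and an up/down/ns call using strict thresholds `|log2fc| > lfc` and
#' `p_adjusted < alpha`.
#'
#' @param cancer,normal Gene-by-sample log2 expression matrices sharing a
#'   gene set (rows are matched by name).
#' @param lfc Log2 fold-change call threshold (strict inequality).
#' @param alpha Adjusted-p call threshold (strict inequality).
#' @return data.frame `(gene, log2fc, mean_cancer, mean_normal, p_raw,
#'   p_adjusted, call)` with `call` in `up`, `down`, `ns`.
#' @export
de_test <- function(cancer, normal, lfc = 1, alpha = 0.05) {
  if (ncol(cancer) < 2L || ncol(normal) < 2L) {
    .stopf("need at least 2 samples per group")
  }
  genes <- rownames(cancer)
  if (!setequal(genes, rownames(normal))) {
    .stopf("cancer and normal matrices must share the same gene set")
  }
  normal <- normal[genes, , drop = FALSE]
  n1 <- ncol(cancer); n2 <- ncol(normal)
  m1 <- rowMeans(cancer); m2 <- rowMeans(normal)
  v1 <- apply(cancer, 1L, stats::var)
  v2 <- apply(normal, 1L, stats::var)
  se2 <- v1 / n1 + v2 / n2
  lfc_hat <- m1 - m2
  tstat <- lfc_hat / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  ## degenerate rows: zero variance in both groups
  zero <- se2 == 0
  p[zero & lfc_hat == 0] <- 1
  p[zero & lfc_hat != 0] <- 0
  padj <- bh_adjust(p)
  call <- rep("ns", length(genes))
  call[lfc_hat > lfc & padj < alpha] <- "up"
  call[lfc_hat < -lfc & padj < alpha] <- "down"
  data.frame(gene = genes, log2fc = lfc_hat,
             mean_cancer = m1, mean_normal = m2,
             p_raw = p, p_adjusted = padj, call = call,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Aggregate promoter probes into gene-level beta means
#'
#' Keeps promoter probes only, drops probes that map to no gene, and
#' averages each gene's promoter probes per sample (a single probe passes
#' through unchanged). Genes whose probes are all non-promoter are
#' excluded with a message.
#'
#' @param betas Probe-by-sample beta matrix, values in `[0, 1]`.
#' @param map data.frame `(probe_id, gene_id, promoter)`.
#' @return Gene-by-sample beta matrix.
#' @export
aggregate_promoter_probes <- function(betas, map) {
  if (any(betas < 0 | betas > 1)) .stopf("beta value outside [0, 1]")
  map <- map[!is.na(map$gene_id) & nzchar(map$gene_id), , drop = FALSE]
  map <- map[map$probe_id %in% rownames(betas), , drop = FALSE]
  prom <- map[as.logical(map$promoter), , drop = FALSE]
  lost <- setdiff(unique(map$gene_id), unique(prom$gene_id))
  if (length(lost)) {
    message("excluding ", length(lost),
            " gene(s) with no promoter probe: ",
            paste(lost, collapse = ", "))
  }
  genes <- unique(prom$gene_id)
  out <- matrix(NA_real_, nrow = length(genes), ncol = ncol(betas),
                dimnames = list(genes, colnames(betas)))
  for (g in genes) {
    pr <- prom$probe_id[prom$gene_id == g]
    out[g, ] <- colMeans(betas[pr, , drop = FALSE])
  }
  out
}

#' Differential promoter methylation between cancer and normal cohorts
#'
#' Per gene: delta-beta (mean cancer beta minus mean normal beta) and a
#' Wilcoxon rank-sum p-value; hyper- and hypomethylation calls require
#' `p < alpha` (strict) and the corresponding delta-beta sign.
#'
#' @param cancer_betas,normal_betas Gene-by-sample beta matrices sharing a
#'   gene set.
#' @param alpha Call threshold on the raw Wilcoxon p (strict inequality).
#' @return data.frame `(gene, mean_beta_cancer, mean_beta_normal,
#'   delta_beta, p_value, call)` with `call` in `hyper`, `hypo`, `ns`.
#' @export
diff_methylation <- function(cancer_betas, normal_betas, alpha = 0.05) {
  if (ncol(cancer_betas) == 0L || ncol(normal_betas) == 0L) {
    .stopf("both cohorts must be non-empty")
  }
  if (any(cancer_betas < 0 | cancer_betas > 1) ||
      any(normal_betas < 0 | normal_betas > 1)) {
    .stopf("beta value outside [0, 1]")
  }
  genes <- rownames(cancer_betas)
  if (!setequal(genes, rownames(normal_betas))) {
    .stopf("cohorts must share the same gene set")
  }
  normal_betas <- normal_betas[genes, , drop = FALSE]
  mc <- rowMeans(cancer_betas)
  mn <- rowMeans(normal_betas)
  p <- vapply(genes, function(g) {
    rank_sum_test(cancer_betas[g, ], normal_betas[g, ])$p_value
  }, numeric(1L))
  delta <- mc - mn
  call <- rep("ns", length(genes))
  call[delta > 0 & p < alpha] <- "hyper"
  call[delta < 0 & p < alpha] <- "hypo"
  data.frame(gene = genes, mean_beta_cancer = mc, mean_beta_normal = mn,
             delta_beta = delta, p_value = p, call = call,
             stringsAsFactors = FALSE, row.names = NULL)
}
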