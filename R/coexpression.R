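## Family co-expression network against an empirical null.
## Family-gene pair correlations are ranked against the |r| distribution
## of randomly sampled background (protein-coding) gene pairs computed in
## the same condition; the empirical p is the fraction of null pairs with
## |r| at least as large. Networks keep pairs with p strictly below alpha
## (default 0.01), and the cancer-vs-normal edge-count shift is assessed
## with an exact binomial test on condition-exclusive edges.

#' Pearson correlation for a list of gene pairs
#'
#' @param expr Gene-by-sample expression matrix (at least 3 samples).
#' @param pairs Two-column data.frame or matrix of gene identifiers.
#' @return data.frame `(gene_a, gene_b, r)`; symmetric in pair order.
#' @export
pairwise_correlations <- function(expr, pairs) {
  if (ncol(expr) < 3L) .stopf("need at least 3 samples")
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  a <- as.character(pairs[[1L]]); b <- as.character(pairs[[2L]])
  miss <- setdiff(unique(c(a, b)), rownames(expr))
  if (length(miss)) .stopf("gene '%s' not in expression matrix", miss[1L])
  used <- unique(c(a, b))
  sds <- apply(expr[used, , drop = FALSE], 1L, stats::sd)
  if (any(sds == 0)) {
    .stopf("undefined correlation: constant gene '%s'",
           used[which(sds == 0)[1L]])
  }
  r <- .row_cor(expr[a, , drop = FALSE], expr[b, , drop = FALSE])
  r[a == b] <- 1
  data.frame(gene_a = a, gene_b = b, r = r,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Empirical null distribution of |r| over random background gene pairs
#'
#' Samples `n_pairs` distinct unordered pairs uniformly from the
#' background pool (with replacement only when the pool holds fewer than
#' `n_pairs` pairs) and stores their absolute Pearson correlations,
#' sorted ascending.
#'
#' @param expr Gene-by-sample expression matrix for one condition.
#' @param background_genes Pool of background gene identifiers (>= 2).
#' @param n_pairs Number of null pairs (default 10000).
#' @param seed Optional integer seed for the pair draw.
#' @param condition Label stored with the null.
#' @return An object of class `null_distribution` with fields
#'   `condition`, `abs_r` (sorted), `n_pairs`, `seed`.
#' @export
sample_null_distribution <- function(expr, background_genes,
                                     n_pairs = 10000L, seed = NULL,
                                     condition = "cancer") {
  background_genes <- intersect(background_genes, rownames(expr))
  k <- length(background_genes)
  if (k < 2L) .stopf("background pool must hold at least 2 genes")
  n_pairs <- .check_count(n_pairs, "n_pairs")
  if (!is.null(seed)) set.seed(seed)
  total <- k * (k - 1) / 2
  if (n_pairs <= total) {
    ## distinct unordered pairs, uniform without replacement
    if (total <= 5e6) {
      idx <- which(upper.tri(matrix(FALSE, k, k)))
      pick <- idx[sample.int(length(idx), n_pairs)]
      i <- ((pick - 1L) %/% k) + 1L   # column (since upper.tri is by column)
      j <- ((pick - 1L) %% k) + 1L    # row
      ii <- pmin(i, j); jj <- pmax(i, j)
    } else {
      seen <- character(0)
      ii <- jj <- integer(0)
      while (length(ii) < n_pairs) {
        m <- n_pairs - length(ii)
        a <- sample.int(k, 2 * m, replace = TRUE)
        b <- sample.int(k, 2 * m, replace = TRUE)
        ok <- a != b
        a <- a[ok]; b <- b[ok]
        lo <- pmin(a, b); hi <- pmax(a, b)
        key <- paste(lo, hi)
        new <- !(key %in% seen) & !duplicated(key)
        take <- which(new)[seq_len(min(m, sum(new)))]
        ii <- c(ii, lo[take]); jj <- c(jj, hi[take])
        seen <- c(seen, key[take])
      }
    }
  } else {
    a <- sample.int(k, n_pairs, replace = TRUE)
    b <- sample.int(k - 1L, n_pairs, replace = TRUE)
    b <- b + (b >= a)
    ii <- pmin(a, b); jj <- pmax(a, b)
  }
  ga <- background_genes[ii]; gb <- background_genes[jj]
  r <- .row_cor(expr[ga, , drop = FALSE], expr[gb, , drop = FALSE])
  structure(list(condition = condition, abs_r = sort(unname(abs(r))),
                 n_pairs = n_pairs,
                 seed = if (is.null(seed)) NA_integer_ else seed),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("null_distribution (%s): %d pairs, median |r| = %.4f\n",
              x$condition, x$n_pairs, stats::median(x$abs_r)))
  invisible(x)
}

#' Empirical p-value of a correlation against a null distribution
#'
#' `p = #(null |r| >= |r_obs|) / n_pairs`; ties at the boundary count
#' toward the numerator (conservative), and p can be exactly 0 - there is
#' no +1 correction, so record `n_pairs` if you wish to floor it.
#'
#' @param r_obs Observed correlation(s); vectorised.
#' @param null A [sample_null_distribution()] object.
#' @return Empirical p-value(s) in `[0, 1]`.
#' @export
empirical_pvalue <- function(r_obs, null) {
  if (!inherits(null, "null_distribution") || length(null$abs_r) == 0L) {
    .stopf("'null' must be a non-empty null_distribution")
  }
  v <- null$abs_r   # sorted ascending
  n <- length(v)
  below <- findInterval(abs(r_obs), v, left.open = TRUE)  # null < |r_obs|
  (n - below) / n
}

#' Build a co-expression network from scored edges
#'
#' Retains pairs whose empirical p for the chosen condition is strictly
#' below `alpha` and returns an undirected igraph whose vertices are all
#' genes appearing in the tested universe.
#'
#' @param edges data.frame with `gene_a`, `gene_b`, `p_cancer`,
#'   `p_normal` (and optionally `r_cancer` / `r_normal`).
#' @param alpha Significance level (strict `<`).
#' @param condition `"cancer"` or `"normal"`.
#' @return An `igraph` object.
#' @export
build_network <- function(edges, alpha = 0.01,
                          condition = c("cancer", "normal")) {
  condition <- match.arg(condition)
  pcol <- paste0("p_", condition)
  if (!pcol %in% names(edges)) .stopf("edges lack column '%s'", pcol)
  keep <- edges[edges[[pcol]] < alpha, , drop = FALSE]
  verts <- sort(unique(c(edges$gene_a, edges$gene_b)))
  d <- keep[, c("gene_a", "gene_b"), drop = FALSE]
  rcol <- paste0("r_", condition)
  if (rcol %in% names(keep)) d$r <- keep[[rcol]]
  igraph::graph_from_data_frame(d, directed = FALSE,
                                vertices = data.frame(name = verts))
}

.net_keys <- function(net) {
  el <- igraph::as_edgelist(net)
  if (nrow(el) == 0L) character(0) else .pair_key(el[, 1L], el[, 2L])
}

#' Classify tested pairs by network membership
#'
#' Partitions the tested-pair universe into `cancer_only`, `normal_only`,
#' `shared` and `insignificant` according to which condition's network
#' retained each edge.
#'
#' @param cancer_net,normal_net Networks from [build_network()], built
#'   over the same universe.
#' @param universe Two-column data.frame of all tested pairs.
#' @return `universe` with a `status` factor column; statuses always
#'   partition the universe.
#' @export
classify_edges <- function(cancer_net, normal_net, universe) {
  ukey <- .pair_key(universe[[1L]], universe[[2L]])
  ck <- .net_keys(cancer_net)
  nk <- .net_keys(normal_net)
  if (!all(ck %in% ukey) || !all(nk %in% ukey)) {
    .stopf("networks contain edges outside the tested universe")
  }
  inc <- ukey %in% ck
  inn <- ukey %in% nk
  status <- ifelse(inc & inn, "shared",
            ifelse(inc, "cancer_only",
            ifelse(inn, "normal_only", "insignificant")))
  out <- as.data.frame(universe, stringsAsFactors = FALSE)
  names(out)[1:2] <- c("gene_a", "gene_b")
  out$status <- factor(status, levels = c("cancer_only", "normal_only",
                                          "shared", "insignificant"))
  out
}

#' Exact binomial test for a cancer-vs-normal edge-count shift
#'
#' Tests whether condition-exclusive edges split evenly: `k` cancer-only
#' edges among `n = cancer_only + normal_only` trials against p0 = 0.5,
#' two-sided.
#'
#' @param n_cancer_only,n_normal_only Edge counts.
#' @param alpha Significance level for the direction call.
#' @return list `(p_value, direction)` with `direction` in `increase`,
#'   `decrease`, `none`; `p_value` is `NA` when both counts are zero.
#' @export
binomial_shift_test <- function(n_cancer_only, n_normal_only,
                                alpha = 0.05) {
  k <- .check_count(n_cancer_only, "n_cancer_only", min = 0L)
  m <- .check_count(n_normal_only, "n_normal_only", min = 0L)
  n <- k + m
  if (n == 0L) return(list(p_value = NA_real_, direction = "none"))
  p <- stats::binom.test(k, n, p = 0.5)$p.value
  direction <- "none"
  if (p < alpha) {
    if (k > n / 2) direction <- "increase"
    if (k < n / 2) direction <- "decrease"
  }
  list(p_value = p, direction = direction)
}

#' Full family co-expression rewiring analysis for one cohort
#'
#' Computes all family-gene pair correlations in cancer and normal,
#' assigns empirical p-values against condition-specific background
#' nulls, builds both networks at `alpha`, classifies every tested pair,
#' and runs the binomial shift test on condition-exclusive edges.
#'
#' @param cancer,normal Gene-by-sample log2 expression matrices.
#' @param family_genes Genes whose pairwise network is analysed.
#' @param background_genes Null pool (excluded family genes recommended).
#' @param n_pairs Null size per condition.
#' @param alpha Edge retention threshold (strict).
#' @param seed Integer seed for the null pair draws.
#' @return list with `edges` (per-pair table with correlations, empirical
#'   p-values and status), `cancer_net`, `normal_net`, `nulls`, and
#'   `comparison` (edge counts plus binomial shift test).
#' @export
coexpression_analysis <- function(cancer, normal, family_genes,
                                  background_genes, n_pairs = 10000L,
                                  alpha = 0.01, seed = 1L) {
  family_genes <- intersect(family_genes, rownames(cancer))
  if (length(family_genes) < 2L) .stopf("need at least 2 family genes")
  cmb <- utils::combn(sort(family_genes), 2L)
  universe <- data.frame(gene_a = cmb[1L, ], gene_b = cmb[2L, ],
                         stringsAsFactors = FALSE)
  rc <- pairwise_correlations(cancer, universe)$r
  rn <- pairwise_correlations(normal, universe)$r
  null_c <- sample_null_distribution(cancer, background_genes, n_pairs,
                                     seed = seed, condition = "cancer")
  null_n <- sample_null_distribution(normal, background_genes, n_pairs,
                                     seed = seed + 1L, condition = "normal")
  edges <- data.frame(universe,
                      r_cancer = rc, r_normal = rn,
                      p_cancer = empirical_pvalue(rc, null_c),
                      p_normal = empirical_pvalue(rn, null_n),
                      stringsAsFactors = FALSE)
  cancer_net <- build_network(edges, alpha, "cancer")
  normal_net <- build_network(edges, alpha, "normal")
  classified <- classify_edges(cancer_net, normal_net, universe)
  edges$status <- classified$status
  counts <- table(edges$status)
  shift <- binomial_shift_test(counts[["cancer_only"]],
                               counts[["normal_only"]])
  comparison <- data.frame(
    n_cancer_edges = counts[["cancer_only"]] + counts[["shared"]],
    n_normal_edges = counts[["normal_only"]] + counts[["shared"]],
    n_shared = counts[["shared"]],
    n_cancer_only = counts[["cancer_only"]],
    n_normal_only = counts[["normal_only"]],
    binomial_p = shift$p_value,
    direction = shift$direction,
    stringsAsFactors = FALSE)
  list(edges = edges, cancer_net = cancer_net, normal_net = normal_net,
       nulls = list(cancer = null_c, normal = null_n),
       comparison = comparison)
}
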