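## Gain/loss rewiring of TF-target co-regulation.
## For a regulator A and target B, delta-R = Cor_cancer(A,B) -
## Cor_normal(A,B). Significance comes from shuffling the cancer/normal
## labels of the pooled samples (group sizes preserved), recomputing
## delta-R each time, and reporting P = sum(S_i) / N where S_i = 1 when
## the permuted statistic is at least as extreme as the observed one.
## The default convention compares |delta-R| (two-sided); a signed
## one-sided variant is available. There is no +1 small-sample
## correction, so P can be exactly 0.

#' Filter a regulator-target table by binding significance score
#'
#' @param table data.frame with columns `tf`, `target`, `score`.
#' @param min_score Retention threshold; strictly greater scores are kept.
#' @return The retained rows.
#' @export
filter_targets <- function(table, min_score = 100) {
  if (nrow(table) == 0L) return(table)
  sc <- table$score
  if (!is.numeric(sc)) {
    sc <- suppressWarnings(as.numeric(sc))
    if (anyNA(sc)) .stopf("non-numeric significance score")
  }
  table[sc > min_score, , drop = FALSE]
}

#' Change in pair correlation between conditions (delta-R)
#'
#' `delta_r = PearsonR(A, B | cancer) - PearsonR(A, B | normal)`,
#' bounded in `[-2, 2]`.
#'
#' @param exprA_c,exprB_c Regulator and target values in cancer samples.
#' @param exprA_n,exprB_n Regulator and target values in normal samples.
#' @return A single number in `[-2, 2]`.
#' @export
delta_r <- function(exprA_c, exprB_c, exprA_n, exprB_n) {
  if (length(exprA_c) < 3L || length(exprA_n) < 3L) {
    .stopf("need at least 3 samples per condition")
  }
  .cor_strict(exprA_c, exprB_c, "cancer vector") -
    .cor_strict(exprA_n, exprB_n, "normal vector")
}

## Column-wise Pearson r of a[idx] vs b[idx] where idx is an index matrix
## (one permuted group per column). Returns NA for degenerate columns.
.col_cor_idx <- function(idx, a, b) {
  m <- nrow(idx)
  A <- matrix(a[idx], nrow = m)
  B <- matrix(b[idx], nrow = m)
  sa <- .colSums(A, m, ncol(A)); sb <- .colSums(B, m, ncol(B))
  saa <- .colSums(A * A, m, ncol(A)); sbb <- .colSums(B * B, m, ncol(B))
  sab <- .colSums(A * B, m, ncol(A))
  num <- sab - sa * sb / m
  den2 <- (saa - sa^2 / m) * (sbb - sb^2 / m)
  r <- ifelse(den2 > 0, num / sqrt(pmax(den2, 0)), NA_real_)
  r
}

## Count permuted statistics at least as extreme as the observed one.
## Exact ties are intended (the observed labelling itself recurs among
## permutations), so the comparison carries a small absolute tolerance
## against floating-point fuzz in the correlation sums.
.count_extreme <- function(d, obs, convention, eps = 1e-9) {
  if (convention == "absolute") {
    sum(abs(d) >= abs(obs) - eps)
  } else if (obs >= 0) {
    sum(d >= obs - eps)
  } else {
    sum(d <= obs + eps)
  }
}

.perm_stats <- function(a, b, nc, n, n_perm) {
  perm <- vapply(seq_len(n_perm), function(i) sample.int(n),
                 integer(n))
  rc <- .col_cor_idx(perm[seq_len(nc), , drop = FALSE], a, b)
  rn <- .col_cor_idx(perm[(nc + 1L):n, , drop = FALSE], a, b)
  rc - rn
}

#' Label-permutation p-value for an observed delta-R
#'
#' Shuffles the cancer/normal labels of the pooled samples `n_perm` times
#' (group sizes preserved), recomputes delta-R for each shuffle, and
#' returns `P = sum(S_i) / n_perm`. Under the default `"absolute"`
#' convention `S_i = 1` when `|delta-R_i| >= |delta-R_obs|`; under
#' `"signed"` the comparison is one-sided in the direction of the
#' observed statistic. Permutations yielding a degenerate (constant)
#' group are redrawn and counted.
#'
#' @param exprA,exprB Pooled regulator and target values (cancer samples
#'   followed by normal, in any order matching `labels`).
#' @param labels Condition per pooled sample: `"cancer"`/`"normal"` or a
#'   logical vector that is `TRUE` for cancer.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Optional integer seed.
#' @param convention `"absolute"` (two-sided, default) or `"signed"`.
#' @return list `(delta_r_obs, p_value, s_count, n_perm, n_degenerate)`.
#' @export
permutation_pvalue <- function(exprA, exprB, labels, n_perm = 1000L,
                               seed = NULL,
                               convention = c("absolute", "signed")) {
  convention <- match.arg(convention)
  n_perm <- .check_count(n_perm, "n_perm")
  is_c <- if (is.logical(labels)) labels else labels == "cancer"
  nc <- sum(is_c); nn <- sum(!is_c)
  if (nc < 3L || nn < 3L) .stopf("need at least 3 samples per condition")
  n <- nc + nn
  obs <- delta_r(exprA[is_c], exprB[is_c], exprA[!is_c], exprB[!is_c])
  ## pool so positions 1..nc of an identity permutation are cancer
  a <- c(exprA[is_c], exprA[!is_c])
  b <- c(exprB[is_c], exprB[!is_c])
  if (!is.null(seed)) set.seed(seed)
  d <- .perm_stats(a, b, nc, n, n_perm)
  n_deg <- 0L
  while (anyNA(d)) {            # redraw degenerate permutations
    bad <- which(is.na(d))
    n_deg <- n_deg + length(bad)
    d[bad] <- .perm_stats(a, b, nc, n, length(bad))
  }
  s <- .count_extreme(d, obs, convention)
  list(delta_r_obs = obs, p_value = s / n_perm, s_count = s,
       n_perm = n_perm, n_degenerate = n_deg)
}

#' Exact permutation p-value by exhaustive label enumeration
#'
#' Enumerates every distinct assignment of condition labels that
#' preserves the group sizes (at most 12 pooled samples) and returns the
#' fraction whose permuted delta-R is at least as extreme as the observed
#' one, under the same convention as [permutation_pvalue()]. Serves as
#' the independent oracle for the Monte-Carlo version.
#'
#' @inheritParams permutation_pvalue
#' @return list `(delta_r_obs, p_value, n_splits)`.
#' @export
exact_permutation_pvalue <- function(exprA, exprB, labels,
                                     convention = c("absolute", "signed")) {
  convention <- match.arg(convention)
  is_c <- if (is.logical(labels)) labels else labels == "cancer"
  nc <- sum(is_c); nn <- sum(!is_c)
  n <- nc + nn
  if (n > 12L) .stopf("exact enumeration limited to 12 samples")
  if (nc < 3L || nn < 3L) .stopf("need at least 3 samples per condition")
  obs <- delta_r(exprA[is_c], exprB[is_c], exprA[!is_c], exprB[!is_c])
  a <- c(exprA[is_c], exprA[!is_c])
  b <- c(exprB[is_c], exprB[!is_c])
  splits <- utils::combn(n, nc)
  d <- apply(splits, 2L, function(idx) {
    rc <- .cor_strict(a[idx], b[idx], "cancer split")
    rn <- .cor_strict(a[-idx], b[-idx], "normal split")
    rc - rn
  })
  s <- .count_extreme(d, obs, convention)
  list(delta_r_obs = obs, p_value = s / ncol(splits),
       n_splits = ncol(splits))
}

#' Classify a pair as gain, loss or neither
#'
#' Gain: significant with `delta_r > 0` (co-regulation acquired in
#' cancer); loss: significant with `delta_r < 0`; `delta_r = 0` is
#' `none` by convention regardless of p.
#'
#' @param delta_r Observed delta-R value(s).
#' @param p_perm Permutation p-value(s).
#' @param alpha Significance level (strict `<`).
#' @return Character vector in `gain`, `loss`, `none`.
#' @export
classify_pattern <- function(delta_r, p_perm, alpha = 0.05) {
  out <- rep("none", length(delta_r))
  out[delta_r > 0 & p_perm < alpha] <- "gain"
  out[delta_r < 0 & p_perm < alpha] <- "loss"
  out
}

#' Scan all regulator-target pairs for gain/loss rewiring
#'
#' Applies [permutation_pvalue()] to every retained regulator-target pair
#' present in both expression matrices, adjusts p-values by BH within
#' each regulator's family of pairs, and classifies patterns.
#'
#' @param targets Retained target table (`tf`, `target` columns), e.g.
#'   from [filter_targets()].
#' @param cancer,normal Gene-by-sample log2 expression matrices.
#' @param n_perm Permutations per pair.
#' @param alpha Significance level for the pattern call (on the raw
#'   permutation p, strict).
#' @param seed Integer seed; each pair gets a deterministic derived seed.
#' @param convention Passed to [permutation_pvalue()].
#' @return data.frame `(tf, target, r_cancer, r_normal, delta_r, p_perm,
#'   fdr, pattern)`; `fdr` is BH within tf.
#' @export
dysregulation_scan <- function(targets, cancer, normal, n_perm = 1000L,
                               alpha = 0.05, seed = 1L,
                               convention = "absolute") {
  keep <- targets$tf %in% rownames(cancer) &
    targets$target %in% rownames(cancer) &
    targets$tf %in% rownames(normal) &
    targets$target %in% rownames(normal)
  tb <- targets[keep, , drop = FALSE]
  n <- nrow(tb)
  rc <- rn <- dr <- pp <- numeric(n)
  nc <- ncol(cancer); nn <- ncol(normal)
  labels <- rep(c(TRUE, FALSE), c(nc, nn))
  for (i in seq_len(n)) {
    A <- c(cancer[tb$tf[i], ], normal[tb$tf[i], ])
    B <- c(cancer[tb$target[i], ], normal[tb$target[i], ])
    res <- permutation_pvalue(A, B, labels, n_perm = n_perm,
                              seed = (seed + i) %% .Machine$integer.max,
                              convention = convention)
    rc[i] <- .cor_strict(A[labels], B[labels])
    rn[i] <- .cor_strict(A[!labels], B[!labels])
    dr[i] <- res$delta_r_obs
    pp[i] <- res$p_value
  }
  fdr <- rep(NA_real_, n)
  for (tf in unique(tb$tf)) {
    sel <- tb$tf == tf
    fdr[sel] <- bh_adjust(pp[sel])
  }
  data.frame(tf = tb$tf, target = tb$target,
             r_cancer = rc, r_normal = rn, delta_r = dr,
             p_perm = pp, fdr = fdr,
             pattern = classify_pattern(dr, pp, alpha),
             stringsAsFactors = FALSE, row.names = NULL)
}
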