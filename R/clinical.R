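## Survival stratification by expression median split (Kaplan-Meier,
## log-rank, univariate Cox) and drug-sensitivity screening (expression
## vs IC50 Pearson correlation with magnitude and significance gates).
## KM and the log-rank test are implemented directly from the risk-set
## bookkeeping so they can be checked against hand calculations; Cox
## fitting is delegated to survival::coxph (Breslow ties by default).

#' Split samples into high/low groups at the expression median
#'
#' Values strictly above the median go to `high`; values at or below the
#' median (including ties at the median) go to `low`.
#'
#' @param expr Named numeric vector of per-sample expression (>= 4).
#' @return Factor with levels `low`, `high`, named by sample.
#' @export
median_split <- function(expr) {
  if (length(expr) < 4L) .stopf("need at least 4 samples")
  med <- stats::median(expr)
  g <- factor(ifelse(expr > med, "high", "low"), levels = c("low", "high"))
  if (any(table(g) == 0L)) {
    .stopf("degenerate split: a median-split group is empty")
  }
  names(g) <- names(expr)
  g
}

#' Kaplan-Meier product-limit estimate
#'
#' @param time Positive follow-up times.
#' @param event Event indicator (1 = observed, 0 = censored).
#' @return data.frame `(time, n_risk, n_event, n_censor, survival)` with
#'   one row per distinct event time; the curve starts at S = 1 and is a
#'   right-continuous step function.
#' @export
km_estimate <- function(time, event) {
  if (length(time) == 0L) .stopf("need at least 1 record")
  if (any(time <= 0)) .stopf("non-positive survival time")
  if (!all(event %in% c(0, 1))) .stopf("event flags must be 0/1")
  o <- order(time)
  time <- time[o]; event <- event[o]
  ev_times <- unique(time[event == 1])
  out <- data.frame(time = ev_times,
                    n_risk = rep(NA_real_, length(ev_times)),
                    n_event = rep(NA_real_, length(ev_times)),
                    n_censor = rep(NA_real_, length(ev_times)),
                    survival = rep(NA_real_, length(ev_times)))
  s <- 1
  for (i in seq_along(ev_times)) {
    t0 <- ev_times[i]
    at_risk <- sum(time >= t0)
    d <- sum(time == t0 & event == 1)
    cns <- sum(time == t0 & event == 0)
    s <- s * (1 - d / at_risk)
    out[i, ] <- c(t0, at_risk, d, cns, s)
  }
  out
}

#' Two-group log-rank test
#'
#' Observed-minus-expected events over the pooled event times with the
#' hypergeometric variance; p from the chi-square distribution with one
#' degree of freedom. Invariant to swapping the group labels.
#'
#' @param timeA,eventA Times and event flags for group A.
#' @param timeB,eventB Times and event flags for group B.
#' @return list `(chi_square, p_value, observed_A, expected_A, n_events)`;
#'   with zero events, `chi_square` and `p_value` are `NA`.
#' @export
logrank_test <- function(timeA, eventA, timeB, eventB) {
  if (length(timeA) == 0L || length(timeB) == 0L) {
    .stopf("both groups must be non-empty")
  }
  if (any(c(timeA, timeB) <= 0)) .stopf("non-positive survival time")
  time <- c(timeA, timeB)
  event <- c(eventA, eventB)
  grp <- rep(c(1L, 2L), c(length(timeA), length(timeB)))
  if (sum(event) == 0) {
    return(list(chi_square = NA_real_, p_value = NA_real_,
                observed_A = 0, expected_A = 0, n_events = 0L))
  }
  ev_times <- sort(unique(time[event == 1]))
  O1 <- E1 <- V <- 0
  for (t0 in ev_times) {
    n1 <- sum(time >= t0 & grp == 1L)
    n2 <- sum(time >= t0 & grp == 2L)
    nt <- n1 + n2
    d1 <- sum(time == t0 & event == 1 & grp == 1L)
    dt <- sum(time == t0 & event == 1)
    O1 <- O1 + d1
    E1 <- E1 + dt * n1 / nt
    if (nt > 1) {
      V <- V + dt * (n1 / nt) * (n2 / nt) * (nt - dt) / (nt - 1)
    }
  }
  chi <- if (V > 0) (O1 - E1)^2 / V else 0
  list(chi_square = chi,
       p_value = stats::pchisq(chi, df = 1L, lower.tail = FALSE),
       observed_A = O1, expected_A = E1, n_events = sum(event))
}

#' Univariate Cox proportional-hazards regression
#'
#' Fits a single covariate - the median-split group by default, or a
#' continuous expression vector - by partial likelihood (Breslow tie
#' handling) via [survival::coxph()]. Complete separation (monotone
#' likelihood) is flagged and leaves the confidence interval unbounded.
#'
#' @param covariate Factor with levels `low`/`high` (hazard ratio is
#'   high vs low) or a numeric vector.
#' @param time,event Survival times and 0/1 event flags.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @param alpha Significance level for the direction call.
#' @return list `(log_hr, hr, se, ci_lower, ci_upper, p_value, n_events,
#'   direction, separation)`.
#' @export
cox_univariate <- function(covariate, time, event, ties = "breslow",
                           alpha = 0.05) {
  if (any(time <= 0)) .stopf("non-positive survival time")
  if (sum(event) == 0) .stopf("no events observed")
  if (is.factor(covariate) || is.character(covariate)) {
    covariate <- factor(covariate, levels = c("low", "high"))
    if (any(table(covariate) == 0L)) {
      .stopf("both covariate levels must be present")
    }
    x <- as.numeric(covariate == "high")
  } else {
    x <- as.numeric(covariate)
    if (stats::sd(x) == 0) .stopf("constant covariate")
  }
  ## separation is detected below, so coxph's own warning is redundant
  fit <- suppressWarnings(
    survival::coxph(survival::Surv(time, event) ~ x, ties = ties))
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(fit$var[1L, 1L]))
  separation <- !is.finite(beta) || abs(beta) > 15 || se > 100
  z <- beta / se
  p <- 2 * stats::pnorm(-abs(z))
  ci <- beta + c(-1, 1) * stats::qnorm(0.975) * se
  direction <- "ns"
  if (!separation && is.finite(p) && p < alpha) {
    direction <- if (beta > 0) "risk" else "protective"
  }
  list(log_hr = beta, hr = exp(beta), se = se,
       ci_lower = exp(ci[1L]), ci_upper = exp(ci[2L]),
       p_value = p, n_events = sum(event),
       direction = direction, separation = separation)
}

#' Expression vs IC50 association for one gene-drug pair
#'
#' Pearson correlation across shared cell lines; the pair is retained
#' only when `|PCC| > pcc_threshold` AND `p < alpha` (both strict).
#'
#' @param expr Named expression values across cell lines.
#' @param ic50 Named IC50 (typically ln IC50) values across cell lines.
#' @param pcc_threshold Magnitude gate (strict `>`).
#' @param alpha Significance gate (strict `<`).
#' @return list `(pcc, p_value, n, retained)`.
#' @export
drug_correlation <- function(expr, ic50, pcc_threshold = 0.2,
                             alpha = 0.05) {
  if (!is.null(names(expr)) && !is.null(names(ic50))) {
    shared <- intersect(names(expr), names(ic50))
    expr <- expr[shared]; ic50 <- ic50[shared]
  }
  if (length(expr) < 3L) .stopf("need at least 3 shared cell lines")
  if (stats::sd(expr) == 0 || stats::sd(ic50) == 0) {
    .stopf("undefined correlation: constant vector")
  }
  ht <- stats::cor.test(expr, ic50, method = "pearson")
  pcc <- unname(ht$estimate)
  list(pcc = pcc, p_value = ht$p.value, n = length(expr),
       retained = abs(pcc) > pcc_threshold && ht$p.value < alpha)
}

#' Gene-drug-target-pathway axis table
#'
#' Joins retained gene-drug associations to retained gene-(drug target)
#' correlations through the drug annotation, producing one deduplicated
#' row per `(gene, drug, drug_target, pathway)` where BOTH correlations
#' passed their filters. Drugs without annotation are dropped with a
#' message.
#'
#' @param gene_drug data.frame of retained gene-drug rows
#'   (`gene`, `drug`, `pcc`, `p_value`).
#' @param gene_target_corr data.frame of retained gene-target rows
#'   (`gene`, `target`, `pcc`, `p_value`).
#' @param drug_annotation data.frame `(drug, target_gene, pathway)`.
#' @return data.frame `(pathway, drug, gene, drug_target)`.
#' @export
build_drug_axis <- function(gene_drug, gene_target_corr, drug_annotation) {
  empty <- data.frame(pathway = character(), drug = character(),
                      gene = character(), drug_target = character(),
                      stringsAsFactors = FALSE)
  if (nrow(gene_drug) == 0L) return(empty)
  unann <- setdiff(gene_drug$drug, drug_annotation$drug)
  if (length(unann)) {
    message("dropping ", length(unann), " drug(s) without annotation: ",
            paste(unann, collapse = ", "))
  }
  rows <- list()
  for (i in seq_len(nrow(gene_drug))) {
    ann <- drug_annotation[drug_annotation$drug == gene_drug$drug[i], ,
                           drop = FALSE]
    for (j in seq_len(nrow(ann))) {
      hit <- gene_target_corr$gene == gene_drug$gene[i] &
        gene_target_corr$target == ann$target_gene[j]
      if (any(hit)) {
        rows[[length(rows) + 1L]] <- data.frame(
          pathway = ann$pathway[j], drug = gene_drug$drug[i],
          gene = gene_drug$gene[i], drug_target = ann$target_gene[j],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) return(empty)
  unique(do.call(rbind, rows))
}
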