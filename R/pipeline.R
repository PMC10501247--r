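## End-to-end orchestration: load and validate the TSV inputs, run every
## stage per cohort (alteration frequencies, differential expression and
## methylation, co-expression rewiring, delta-R dysregulation, survival,
## drug screening), and write one TSV per stage plus a JSON summary and a
## run manifest. Deterministic given (inputs, config, seed).

#' Pipeline configuration
#'
#' Collects input paths, analysis thresholds (all overridable; defaults
#' are the field-standard values: DE |log2fc| > 1 at adjusted p < 0.05,
#' methylation p < 0.05, co-expression empirical p < 0.01 against a
#' 10000-pair null, 1000 label permutations, target score > 100, drug
#' |PCC| > 0.2 at p < 0.05, and a minimum of 10 normal samples for the
#' paired-cohort stages), the seed, and the output directory.
#'
#' @param input_dir Directory holding the standard input TSV set (as
#'   written by [write_cohort()]); individual paths can be overridden
#'   via `paths`.
#' @param out_dir Output directory.
#' @param seed Integer seed for the null draw and permutations.
#' @param paths Optional named list overriding individual input paths.
#' @param thresholds Optional named list overriding individual thresholds.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir, out_dir, seed = 1L,
                            paths = list(), thresholds = list()) {
  files <- c(expression = "expression.tsv", samples = "samples.tsv",
             mutations = "mutations.tsv", cnv = "cnv.tsv",
             methylation = "methylation.tsv", probe_map = "probe_map.tsv",
             targets = "targets.tsv", survival = "survival.tsv",
             cellline_expression = "cellline_expression.tsv",
             drug_ic50 = "drug_ic50.tsv",
             drug_annotation = "drug_annotation.tsv",
             family_genes = "family_genes.txt",
             background_genes = "background_genes.txt")
  p <- as.list(file.path(input_dir, files))
  names(p) <- names(files)
  p[names(paths)] <- paths
  th <- list(de_lfc = 1, de_alpha = 0.05, meth_alpha = 0.05,
             coexpr_alpha = 0.01, n_null_pairs = 10000L, n_perm = 1000L,
             target_min_score = 100, drug_pcc = 0.2, drug_alpha = 0.05,
             survival_alpha = 0.05, min_normal_samples = 10L,
             cnv_amp_ge = 1, cnv_del_le = -1)
  unknown <- setdiff(names(thresholds), names(th))
  if (length(unknown)) .stopf("unknown threshold '%s'", unknown[1L])
  th[names(thresholds)] <- thresholds
  for (nm in c("de_alpha", "meth_alpha", "coexpr_alpha", "drug_alpha",
               "survival_alpha")) {
    .check_number(th[[nm]], nm, lower = 1e-12, upper = 1 - 1e-12)
  }
  structure(list(paths = p, thresholds = th,
                 seed = .check_count(seed, "seed", min = 0L),
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Load and validate the pipeline inputs
#'
#' Reads every input table, applies schema checks (duplicate identifiers,
#' non-numeric matrix cells, betas outside `[0, 1]`, non-positive
#' survival times are rejected with their line number), and reports the
#' sample-identifier intersections across omics.
#'
#' @param config A [pipeline_config()] object.
#' @return list of validated tables plus an `intersections` report.
#' @export
load_inputs <- function(config) {
  p <- config$paths
  for (f in unlist(p)) if (!file.exists(f)) .stopf("missing input: %s", f)
  expr <- read_matrix_tsv(p$expression)
  samples <- read_table_tsv(p$samples)
  if (!all(c("sample", "cohort", "condition") %in% names(samples))) {
    .stopf("samples table needs columns sample, cohort, condition")
  }
  muts <- read_table_tsv(p$mutations)
  names(muts)[1:3] <- c("sample", "gene", "variant_class")
  cnv <- read_matrix_tsv(p$cnv)
  meth <- read_matrix_tsv(p$methylation)
  if (any(meth < 0 | meth > 1)) {
    .stopf("beta value outside [0, 1] in %s", p$methylation)
  }
  probe_map <- read_table_tsv(p$probe_map)
  targets <- read_table_tsv(p$targets)
  surv <- read_table_tsv(p$survival)
  bad <- which(surv$time <= 0 | !(surv$event %in% c(0, 1)))
  if (length(bad)) {
    .stopf("invalid survival row at line %d of %s (time <= 0 or bad event flag)",
           bad[1L] + 1L, p$survival)
  }
  cl_expr <- read_matrix_tsv(p$cellline_expression)
  ic50 <- read_table_tsv(p$drug_ic50)
  drug_ann <- read_table_tsv(p$drug_annotation)
  fam <- readLines(p$family_genes)
  bg <- readLines(p$background_genes)

  inter <- list(
    expression_vs_samples = intersect(colnames(expr), samples$sample),
    expression_only = setdiff(colnames(expr), samples$sample),
    cnv_vs_expression = intersect(colnames(cnv), colnames(expr)),
    methylation_vs_expression = intersect(colnames(meth), colnames(expr)),
    survival_vs_expression = intersect(surv$sample, colnames(expr)))

  list(expression = expr, samples = samples, mutations = muts, cnv = cnv,
       methylation = meth, probe_map = probe_map, targets = targets,
       survival = surv, cellline_expression = cl_expr, drug_ic50 = ic50,
       drug_annotation = drug_ann, family_genes = fam,
       background_genes = bg, intersections = inter)
}

.report_row <- function(stage, cohort, n_in, n_out, reason = "") {
  data.frame(stage = stage, cohort = cohort, n_in = n_in, n_out = n_out,
             n_dropped = n_in - n_out, reason = reason,
             stringsAsFactors = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes every stage for every cohort in the sample table. Cohorts
#' with fewer than `min_normal_samples` normal samples are excluded from
#' the paired stages (differential expression/methylation, co-expression,
#' delta-R) but still contribute to the alteration-frequency and survival
#' stages. All randomness derives from `config$seed`; re-running with an
#' identical config reproduces the output tree byte for byte.
#'
#' @param config A [pipeline_config()] object.
#' @param inputs Optional pre-loaded [load_inputs()] result.
#' @return Invisibly, a list with every stage's tables, the stage
#'   reports, and the output directory. Side effect: result TSVs,
#'   `summary.json`, `manifest.json` and `stage_reports.tsv` in
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config, inputs = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(inputs)) inputs <- load_inputs(config)
  th <- config$thresholds
  seed0 <- config$seed %% 100000000L
  fam <- intersect(inputs$family_genes, rownames(inputs$expression))
  cohorts <- sort(unique(inputs$samples$cohort))
  reports <- list()
  out <- list(alteration = list(), cnv_corr = list(), de = list(),
              meth = list(), edges = list(), comparison = list(),
              dysreg = list(), cox = list(), km = list())

  for (ci in seq_along(cohorts)) {
    ch <- cohorts[ci]
    smp <- inputs$samples[inputs$samples$cohort == ch, ]
    tumor <- intersect(smp$sample[smp$condition == "cancer"],
                       colnames(inputs$expression))
    normal <- intersect(smp$sample[smp$condition == "normal"],
                        colnames(inputs$expression))
    Ec <- inputs$expression[, tumor, drop = FALSE]
    En <- inputs$expression[, normal, drop = FALSE]

    ## -- genomics: alteration frequencies -------------------------------
    mf <- mutation_frequency(inputs$mutations, tumor, fam)
    cnv_samp <- intersect(tumor, colnames(inputs$cnv))
    cf <- cnv_frequency(inputs$cnv[fam, , drop = FALSE], cnv_samp,
                        amp_ge = th$cnv_amp_ge, del_le = th$cnv_del_le)
    alt <- merge(mf, cf[, c("gene", "amp_freq", "del_freq")], by = "gene")
    alt <- data.frame(cohort = ch, alt, stringsAsFactors = FALSE)
    out$alteration[[ch]] <- alt
    reports[[length(reports) + 1L]] <-
      .report_row("alteration_frequency", ch, length(fam), nrow(alt))

    ## CNV-expression correlation per family gene (cancer samples)
    cc <- lapply(fam, function(g) {
      v <- inputs$cnv[g, cnv_samp]
      e <- Ec[g, cnv_samp]
      if (stats::sd(v) == 0 || stats::sd(e) == 0 || length(v) < 3L) {
        return(NULL)
      }
      r <- omic_expression_correlation(e, v)
      data.frame(cohort = ch, gene = g, r = r$r, p_value = r$p_value,
                 n = r$n, stringsAsFactors = FALSE)
    })
    cc <- do.call(rbind, cc)
    out$cnv_corr[[ch]] <- cc
    reports[[length(reports) + 1L]] <-
      .report_row("cnv_expression_correlation", ch, length(fam),
                  NROW(cc), "constant CNV or expression")

    paired <- length(normal) >= th$min_normal_samples
    if (!paired) {
      reports[[length(reports) + 1L]] <-
        .report_row("paired_stages", ch, length(fam), 0L,
                    sprintf("skipped: %d normal samples < %d",
                            length(normal), th$min_normal_samples))
    } else {
      ## -- differential expression -------------------------------------
      de <- de_test(Ec[fam, , drop = FALSE], En[fam, , drop = FALSE],
                    lfc = th$de_lfc, alpha = th$de_alpha)
      out$de[[ch]] <- data.frame(cohort = ch, de, stringsAsFactors = FALSE)
      reports[[length(reports) + 1L]] <-
        .report_row("differential_expression", ch, length(fam), nrow(de))

      ## -- differential methylation ------------------------------------
      mt <- intersect(tumor, colnames(inputs$methylation))
      mn <- intersect(normal, colnames(inputs$methylation))
      gb <- suppressMessages(
        aggregate_promoter_probes(inputs$methylation, inputs$probe_map))
      dm <- diff_methylation(gb[, mt, drop = FALSE],
                             gb[, mn, drop = FALSE],
                             alpha = th$meth_alpha)
      out$meth[[ch]] <- data.frame(cohort = ch, dm,
                                   stringsAsFactors = FALSE)
      reports[[length(reports) + 1L]] <-
        .report_row("differential_methylation", ch, nrow(gb), nrow(dm))

      ## -- co-expression rewiring --------------------------------------
      cx <- coexpression_analysis(Ec, En, fam, inputs$background_genes,
                                  n_pairs = th$n_null_pairs,
                                  alpha = th$coexpr_alpha,
                                  seed = seed0 + 13L * ci)
      out$edges[[ch]] <- data.frame(cohort = ch, cx$edges,
                                    stringsAsFactors = FALSE)
      out$comparison[[ch]] <- data.frame(cohort = ch, cx$comparison,
                                         stringsAsFactors = FALSE)
      reports[[length(reports) + 1L]] <-
        .report_row("coexpression", ch, nrow(cx$edges), nrow(cx$edges))

      ## -- delta-R dysregulation ---------------------------------------
      kept <- filter_targets(inputs$targets,
                             min_score = th$target_min_score)
      ds <- dysregulation_scan(kept, Ec, En, n_perm = th$n_perm,
                               alpha = 0.05, seed = seed0 + 1000L * ci)
      out$dysreg[[ch]] <- data.frame(cohort = ch, ds,
                                     stringsAsFactors = FALSE)
      reports[[length(reports) + 1L]] <-
        .report_row("dysregulation", ch, nrow(inputs$targets), nrow(ds),
                    "score <= min or gene absent from expression")
    }

    ## -- survival -------------------------------------------------------
    sv <- inputs$survival[inputs$survival$sample %in% tumor, ]
    cox_rows <- list(); km_rows <- list()
    n_fit <- 0L
    if (nrow(sv) >= 4L && sum(sv$event) > 0L) {
      for (g in fam) {
        v <- Ec[g, sv$sample]
        grp <- tryCatch(median_split(v), error = function(e) NULL)
        if (is.null(grp)) next
        fit <- tryCatch(
          cox_univariate(grp, sv$time, sv$event,
                         alpha = th$survival_alpha),
          error = function(e) NULL)
        if (is.null(fit)) next
        lr <- logrank_test(sv$time[grp == "high"], sv$event[grp == "high"],
                           sv$time[grp == "low"], sv$event[grp == "low"])
        n_fit <- n_fit + 1L
        cox_rows[[g]] <- data.frame(
          cohort = ch, gene = g, log_hr = fit$log_hr, hr = fit$hr,
          ci_lower = fit$ci_lower, ci_upper = fit$ci_upper,
          p_value = fit$p_value, logrank_chi_square = lr$chi_square,
          logrank_p = lr$p_value, direction = fit$direction,
          stringsAsFactors = FALSE)
        for (lv in c("high", "low")) {
          kmv <- km_estimate(sv$time[grp == lv], sv$event[grp == lv])
          if (nrow(kmv)) {
            km_rows[[paste(g, lv)]] <- data.frame(
              cohort = ch, gene = g, group = lv, kmv,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
    out$cox[[ch]] <- if (length(cox_rows)) do.call(rbind, cox_rows)
    out$km[[ch]] <- if (length(km_rows)) do.call(rbind, km_rows)
    reports[[length(reports) + 1L]] <-
      .report_row("survival", ch, length(fam), n_fit,
                  "degenerate split or no events")
  }

  ## -- drug screening (cohort-independent, cell-line based) -------------
  cl <- inputs$cellline_expression
  ic <- inputs$drug_ic50
  drugs <- sort(unique(ic$drug))
  genes_cl <- intersect(fam, rownames(cl))
  drug_rows <- list()
  n_combo <- length(genes_cl) * length(drugs)
  for (d in drugs) {
    sub <- ic[ic$drug == d, ]
    v <- stats::setNames(sub$ic50, sub$cell_line)
    for (g in genes_cl) {
      res <- tryCatch(
        drug_correlation(cl[g, ], v, pcc_threshold = th$drug_pcc,
                         alpha = th$drug_alpha),
        error = function(e) NULL)
      if (is.null(res)) next
      drug_rows[[paste(g, d)]] <- data.frame(
        gene = g, drug = d, pcc = res$pcc, p_value = res$p_value,
        n = res$n, retained = res$retained, stringsAsFactors = FALSE)
    }
  }
  drug_tab <- if (length(drug_rows)) do.call(rbind, drug_rows) else
    data.frame(gene = character(), drug = character(), pcc = numeric(),
               p_value = numeric(), n = integer(), retained = logical())
  rownames(drug_tab) <- NULL
  reports[[length(reports) + 1L]] <-
    .report_row("drug_screen", "all", n_combo, nrow(drug_tab),
                "constant vectors or < 3 shared lines")

  ## gene vs drug-target correlations (for the axis table)
  ann <- inputs$drug_annotation
  gt_rows <- list()
  for (g in genes_cl) {
    for (tgt in unique(ann$target_gene)) {
      if (!tgt %in% rownames(cl) || tgt == g) next
      res <- tryCatch(
        drug_correlation(cl[g, ], cl[tgt, ], pcc_threshold = th$drug_pcc,
                         alpha = th$drug_alpha),
        error = function(e) NULL)
      if (is.null(res) || !res$retained) next
      gt_rows[[paste(g, tgt)]] <- data.frame(
        gene = g, target = tgt, pcc = res$pcc, p_value = res$p_value,
        stringsAsFactors = FALSE)
    }
  }
  gt_tab <- if (length(gt_rows)) do.call(rbind, gt_rows) else
    data.frame(gene = character(), target = character(), pcc = numeric(),
               p_value = numeric())
  axis <- suppressMessages(
    build_drug_axis(drug_tab[drug_tab$retained, , drop = FALSE],
                    gt_tab, ann))

  results <- list(
    alteration_frequency = do.call(rbind, out$alteration),
    cnv_expression_correlation = do.call(rbind, out$cnv_corr),
    de_results = do.call(rbind, out$de),
    methylation_results = do.call(rbind, out$meth),
    coexpression_edges = do.call(rbind, out$edges),
    network_comparison = do.call(rbind, out$comparison),
    dysregulation = do.call(rbind, out$dysreg),
    cox_results = do.call(rbind, out$cox),
    km_curves = do.call(rbind, out$km),
    drug_associations = drug_tab,
    drug_axis = axis)
  reports <- do.call(rbind, reports)

  write_reports(results, reports, config)
  invisible(list(results = results, reports = reports,
                 out_dir = config$out_dir))
}

#' Write pipeline result tables, JSON summary and run manifest
#'
#' One TSV per stage, a `summary.json` with reconciled counts, a
#' `stage_reports.tsv` (inputs = outputs + dropped for every stage), and
#' a `manifest.json` recording the seed, thresholds, an MD5 digest of
#' the serialized configuration and the file inventory. Nothing written
#' here contains a timestamp, so identical runs are byte-identical.
#'
#' @param results Named list of stage tables.
#' @param reports Stage-report data.frame.
#' @param config The [pipeline_config()] used.
#' @return The output directory, invisibly.
#' @export
write_reports <- function(results, reports, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(config$out_dir, f)
  empty_schemas <- list(
    de_results = c("cohort", "gene", "log2fc", "p_raw", "p_adjusted",
                   "call"),
    methylation_results = c("cohort", "gene", "delta_beta", "p_value",
                            "call"),
    coexpression_edges = c("cohort", "gene_a", "gene_b", "r_cancer",
                           "r_normal", "p_cancer", "p_normal", "status"),
    dysregulation = c("cohort", "tf", "target", "delta_r", "p_perm",
                      "fdr", "pattern"))
  for (nm in names(results)) {
    tb <- results[[nm]]
    if (is.null(tb)) {
      cols <- empty_schemas[[nm]]
      if (is.null(cols)) cols <- "empty"
      tb <- as.data.frame(stats::setNames(
        replicate(length(cols), character(0), simplify = FALSE), cols))
    }
    num <- vapply(tb, is.numeric, logical(1L))
    tb[num] <- lapply(tb[num], function(x) round(x, 8))
    write_table_tsv(tb, p(paste0(nm, ".tsv")))
  }
  write_table_tsv(reports, p("stage_reports.tsv"))

  cnt <- function(tb, expr) if (is.null(tb)) 0L else sum(expr(tb))
  summary <- list(
    n_de_up = cnt(results$de_results, function(t) t$call == "up"),
    n_de_down = cnt(results$de_results, function(t) t$call == "down"),
    n_hyper = cnt(results$methylation_results,
                  function(t) t$call == "hyper"),
    n_hypo = cnt(results$methylation_results,
                 function(t) t$call == "hypo"),
    edges_by_status = if (is.null(results$coexpression_edges)) list() else
      as.list(table(results$coexpression_edges$status)),
    n_gain = cnt(results$dysregulation, function(t) t$pattern == "gain"),
    n_loss = cnt(results$dysregulation, function(t) t$pattern == "loss"),
    n_cox_significant = cnt(results$cox_results,
                            function(t) t$direction != "ns"),
    n_drug_retained = cnt(results$drug_associations,
                          function(t) t$retained),
    n_axis_rows = if (is.null(results$drug_axis)) 0L else
      nrow(results$drug_axis))
  jsonlite::write_json(summary, p("summary.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  cfg_json <- p("config.json")
  jsonlite::write_json(
    list(seed = config$seed, thresholds = config$thresholds,
         paths = lapply(config$paths, basename)),
    cfg_json, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  manifest <- list(
    package = "corewire",
    version = as.character(utils::packageVersion("corewire")),
    seed = config$seed,
    config_md5 = unname(tools::md5sum(cfg_json)),
    files = sort(setdiff(list.files(config$out_dir), "manifest.json")))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(config$out_dir)
}
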