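## Synthetic cohort generator. Emulates the structure of a paired
## cancer/normal multi-omic cohort (expression, mutations, CNV, promoter
## methylation, TF->target scores, survival, cell-line drug response) with
## every planted effect recorded in a ground-truth ledger, so each
## downstream stage can be tested without any external dataset.

#' Draw a pair of vectors with a planted Pearson correlation
#'
#' Samples `n` observations from a bivariate Gaussian with population
#' correlation `rho` (a Gaussian copula on the log2-expression scale:
#' values are already log-scale so no further transform is applied).
#' For `rho = +/-1` the second vector is an exact affine image of the
#' first, so the sample correlation is exactly `+/-1`.
#'
#' Uses R's global RNG stream; seed with [set.seed()] for reproducibility.
#'
#' @param rho Population correlation in `[-1, 1]`.
#' @param n Number of observations, at least 2.
#' @return A list with numeric vectors `x` and `y` of length `n`.
#' @examples
#' set.seed(1)
#' z <- sample_correlated_pair(0.9, 200)
#' cor(z$x, z$y)
#' @export
sample_correlated_pair <- function(rho, n) {
  .check_number(rho, "rho", -1, 1)
  .check_count(n, "n", min = 2L)
  x <- stats::rnorm(n)
  if (abs(rho) == 1) {
    return(list(x = x, y = rho * x))
  }
  y <- rho * x + sqrt(1 - rho^2) * stats::rnorm(n)
  list(x = x, y = y)
}

.empty_pairs <- function() {
  data.frame(gene_a = character(), gene_b = character(),
             rho_cancer = numeric(), rho_normal = numeric(),
             stringsAsFactors = FALSE)
}

#' Configuration of a synthetic paired cancer/normal cohort
#'
#' The defaults describe one fixed "stated world": a 49-gene family over a
#' 300-gene background with 50 cancer and 50 normal samples, four planted
#' co-expression pairs whose correlation differs between conditions, three
#' differentially expressed genes, two differentially methylated genes, a
#' survival gene with a log hazard ratio of `log(2)` between median-split
#' groups, and two expression--IC50 drug couplings. See the methods
#' vignette for the rationale behind each default.
#'
#' @param cohort_id Cohort label used in sample identifiers.
#' @param n_family_genes,n_background_genes Number of family (analysed) and
#'   background (null-pool) genes.
#' @param n_cancer,n_normal,n_cell_lines Sample counts.
#' @param planted_pairs data.frame `(gene_a, gene_b, rho_cancer, rho_normal)`;
#'   each gene may appear in at most one pair.
#' @param mutation_rate Per-gene Bernoulli probability that a cancer sample
#'   carries a somatic mutation.
#' @param mutation_effect Additive log2-expression shift in mutated samples.
#' @param cnv_dosage_slope log2-expression units per copy-number unit.
#' @param methylation_slope log2-expression units per beta unit (negative:
#'   promoter methylation represses).
#' @param de_genes data.frame `(gene, log2fc)` of planted expression shifts.
#' @param dm_genes data.frame `(gene, logit_shift)` of planted methylation
#'   shifts on the logit-beta scale (positive = hypermethylated in cancer).
#' @param survival_gene Gene whose median split drives the planted hazard;
#'   `NA` disables the survival effect.
#' @param survival_log_hr Log hazard ratio of the high-expression group.
#' @param drug_couplings data.frame `(gene, drug, slope, noise_sd)`:
#'   IC50 = slope * expression + Gaussian noise across cell lines.
#' @param drug_annotation data.frame `(drug, target_gene, pathway)`.
#' @param cell_line_pairs data.frame `(gene_a, gene_b, rho)` of planted
#'   cell-line co-expression (links drugs to their annotated targets).
#' @param noise_sd Residual standard deviation of log2 expression.
#' @param seed Integer seed; identical config + seed reproduces the cohort
#'   byte-for-byte.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(cohort_id = "SYN",
                          n_family_genes = 49L,
                          n_background_genes = 300L,
                          n_cancer = 50L,
                          n_normal = 50L,
                          n_cell_lines = 60L,
                          planted_pairs = data.frame(
                            gene_a = c("FAM01", "FAM03", "FAM05", "FAM07"),
                            gene_b = c("FAM02", "FAM04", "FAM06", "FAM08"),
                            rho_cancer = c(0.9, 0.0, 0.8, 0.5),
                            rho_normal = c(0.0, 0.9, 0.8, -0.5),
                            stringsAsFactors = FALSE),
                          mutation_rate = 0.05,
                          mutation_effect = 1.0,
                          cnv_dosage_slope = 0.5,
                          methylation_slope = -2.0,
                          de_genes = data.frame(
                            gene = c("FAM09", "FAM10", "FAM11"),
                            log2fc = c(3.0, -2.0, 1.5),
                            stringsAsFactors = FALSE),
                          dm_genes = data.frame(
                            gene = c("FAM12", "FAM13"),
                            logit_shift = c(2.0, -2.0),
                            stringsAsFactors = FALSE),
                          survival_gene = "FAM01",
                          survival_log_hr = log(2),
                          drug_couplings = data.frame(
                            gene = c("FAM01", "FAM02"),
                            drug = c("drug_A", "drug_B"),
                            slope = c(0.8, -0.6),
                            noise_sd = c(0.5, 0.5),
                            stringsAsFactors = FALSE),
                          drug_annotation = data.frame(
                            drug = c("drug_A", "drug_B", "drug_null"),
                            target_gene = c("FAM03", "FAM05", "FAM20"),
                            pathway = c("PI3K/MTOR signaling", "Cell cycle",
                                        "Unknown"),
                            stringsAsFactors = FALSE),
                          cell_line_pairs = data.frame(
                            gene_a = c("FAM01", "FAM02"),
                            gene_b = c("FAM03", "FAM05"),
                            rho = c(0.6, 0.6),
                            stringsAsFactors = FALSE),
                          noise_sd = 1.0,
                          seed = 1L) {
  cfg <- list(cohort_id = as.character(cohort_id),
              n_family_genes = .check_count(n_family_genes, "n_family_genes"),
              n_background_genes = .check_count(n_background_genes,
                                                "n_background_genes"),
              n_cancer = .check_count(n_cancer, "n_cancer"),
              n_normal = .check_count(n_normal, "n_normal"),
              n_cell_lines = .check_count(n_cell_lines, "n_cell_lines"),
              planted_pairs = if (is.null(planted_pairs)) .empty_pairs()
                              else planted_pairs,
              mutation_rate = .check_number(mutation_rate, "mutation_rate",
                                            0, 1),
              mutation_effect = .check_number(mutation_effect,
                                              "mutation_effect"),
              cnv_dosage_slope = .check_number(cnv_dosage_slope,
                                               "cnv_dosage_slope"),
              methylation_slope = .check_number(methylation_slope,
                                                "methylation_slope"),
              de_genes = de_genes,
              dm_genes = dm_genes,
              survival_gene = if (is.null(survival_gene)) NA_character_
                              else as.character(survival_gene),
              survival_log_hr = .check_number(survival_log_hr,
                                              "survival_log_hr"),
              drug_couplings = drug_couplings,
              drug_annotation = drug_annotation,
              cell_line_pairs = cell_line_pairs,
              noise_sd = .check_number(noise_sd, "noise_sd"),
              seed = .check_count(seed, "seed", min = 0L))
  if (cfg$noise_sd <= 0) .stopf("'noise_sd' must be > 0")
  class(cfg) <- "cohort_config"
  .validate_config(cfg)
  cfg
}

.validate_config <- function(cfg) {
  fam <- .family_gene_names(cfg$n_family_genes)
  pp <- cfg$planted_pairs
  if (nrow(pp)) {
    if (any(abs(pp$rho_cancer) > 1) || any(abs(pp$rho_normal) > 1)) {
      .stopf("planted pair rho values must lie in [-1, 1]")
    }
    used <- c(pp$gene_a, pp$gene_b)
    if (anyDuplicated(used)) {
      .stopf("gene '%s' appears in more than one planted pair",
             used[duplicated(used)][1L])
    }
    if (!all(used %in% fam)) {
      .stopf("planted pair gene '%s' is not a family gene",
             setdiff(used, fam)[1L])
    }
  }
  for (nm in c("de_genes", "dm_genes")) {
    tb <- cfg[[nm]]
    if (!is.null(tb) && nrow(tb) && !all(tb$gene %in% fam)) {
      .stopf("%s entry '%s' is not a family gene", nm,
             setdiff(tb$gene, fam)[1L])
    }
  }
  if (nrow(pp) && NROW(cfg$de_genes)) {
    clash <- intersect(cfg$de_genes$gene, c(pp$gene_a, pp$gene_b))
    if (length(clash)) {
      .stopf("gene '%s' cannot be both a DE gene and a planted-pair gene",
             clash[1L])
    }
  }
  if (!is.na(cfg$survival_gene) && !(cfg$survival_gene %in% fam)) {
    .stopf("survival_gene '%s' is not a family gene", cfg$survival_gene)
  }
  invisible(cfg)
}

.family_gene_names <- function(n) sprintf("FAM%02d", seq_len(n))
.background_gene_names <- function(n) sprintf("BG%04d", seq_len(n))

.clip01 <- function(x) pmin(1, pmax(0, x))

#' Generate a synthetic target-score table for a set of regulators
#'
#' Mimics a ChIP-derived TF-to-target table: each regulator receives the
#' requested number of targets drawn without replacement from `candidates`
#' (never itself), each with a binding significance score drawn uniformly
#' from `score_range`.
#'
#' @param tfs Character vector of regulator gene ids.
#' @param candidates Character vector of candidate target gene ids.
#' @param score_range Numeric length-2 vector, inclusive score bounds.
#' @param sizes Targets per regulator: a single count or one per regulator.
#' @return data.frame `(tf, target, score)`.
#' @export
generate_target_sets <- function(tfs, candidates, score_range = c(10, 500),
                                 sizes = 15L) {
  if (length(candidates) == 0L) .stopf("'candidates' must be non-empty")
  if (any(sizes < 0)) .stopf("'sizes' must be >= 0")
  sizes <- rep_len(as.integer(sizes), length(tfs))
  out <- vector("list", length(tfs))
  for (i in seq_along(tfs)) {
    pool <- setdiff(candidates, tfs[i])
    if (sizes[i] > length(pool)) {
      .stopf("requested %d targets for '%s' but only %d candidates",
             sizes[i], tfs[i], length(pool))
    }
    if (sizes[i] == 0L) {
      out[[i]] <- data.frame(tf = character(), target = character(),
                             score = numeric(), stringsAsFactors = FALSE)
      next
    }
    tg <- sample(pool, sizes[i])
    out[[i]] <- data.frame(tf = tfs[i], target = tg,
                           score = stats::runif(sizes[i], score_range[1L],
                                                score_range[2L]),
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Generate a complete synthetic cohort from a configuration
#'
#' Produces paired cancer/normal log2 expression with planted pair
#' correlations and fold changes, sample-level Bernoulli mutations that
#' shift expression, GISTIC-like copy-number calls with a dosage effect,
#' promoter methylation betas coupled to expression on the logit scale,
#' a TF-target score table, exponential proportional-hazards survival
#' split on the survival gene's median, and cell-line expression with
#' linear expression--IC50 couplings. Every planted effect is listed
#' exactly once in the `truth` ledger.
#'
#' @param config A [cohort_config()] object.
#' @return An object of class `synthetic_cohort`: a list of matrices and
#'   tables (see the methods vignette for the full inventory).
#' @examples
#' co <- generate_cohort(cohort_config(n_cancer = 20, n_normal = 20))
#' dim(co$expression_cancer)
#' head(co$truth)
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) {
    .stopf("'config' must be a cohort_config object")
  }
  .validate_config(config)
  set.seed(config$seed)

  fam <- .family_gene_names(config$n_family_genes)
  bg <- .background_gene_names(config$n_background_genes)
  genes <- c(fam, bg)
  nc <- config$n_cancer
  nn <- config$n_normal
  tumor_ids <- sprintf("%s_T%03d", config$cohort_id, seq_len(nc))
  normal_ids <- sprintf("%s_N%03d", config$cohort_id, seq_len(nn))

  ## baseline log2 abundance per gene, shared across conditions
  mu <- stats::runif(length(genes), 4, 10)
  names(mu) <- genes
  sd0 <- config$noise_sd

  Ec <- mu + matrix(stats::rnorm(length(genes) * nc, 0, sd0),
                    nrow = length(genes),
                    dimnames = list(genes, tumor_ids))
  En <- mu + matrix(stats::rnorm(length(genes) * nn, 0, sd0),
                    nrow = length(genes),
                    dimnames = list(genes, normal_ids))

  truth <- list()
  note <- function(effect, gene, partner, value) {
    truth[[length(truth) + 1L]] <<- data.frame(
      effect = effect, gene = gene, partner = partner, value = value,
      stringsAsFactors = FALSE)
  }

  ## planted differential expression
  de <- config$de_genes
  for (i in seq_len(NROW(de))) {
    Ec[de$gene[i], ] <- Ec[de$gene[i], ] + de$log2fc[i]
    note("de_log2fc", de$gene[i], NA_character_, de$log2fc[i])
  }

  ## somatic mutations: Bernoulli per family gene per cancer sample;
  ## mutated samples get an additive expression shift. A sprinkle of
  ## duplicate variant rows exercises distinct-sample counting downstream.
  classes <- c("Missense_Mutation", "Nonsense_Mutation",
               "Frame_Shift_Del", "Splice_Site")
  mut_rows <- list()
  for (g in fam) {
    hit <- which(stats::rbinom(nc, 1L, config$mutation_rate) == 1L)
    if (!length(hit)) next
    Ec[g, hit] <- Ec[g, hit] + config$mutation_effect
    mut_rows[[g]] <- data.frame(
      sample = tumor_ids[hit], gene = g,
      variant_class = sample(classes, length(hit), replace = TRUE),
      stringsAsFactors = FALSE)
    dup <- hit[stats::runif(length(hit)) < 0.1]
    if (length(dup)) {
      mut_rows[[paste0(g, ".dup")]] <- data.frame(
        sample = tumor_ids[dup], gene = g,
        variant_class = sample(classes, length(dup), replace = TRUE),
        stringsAsFactors = FALSE)
    }
  }
  mutations <- if (length(mut_rows)) do.call(rbind, mut_rows) else
    data.frame(sample = character(), gene = character(),
               variant_class = character(), stringsAsFactors = FALSE)
  rownames(mutations) <- NULL

  ## copy number: thresholded GISTIC-like calls in {-2,...,2}, family genes
  cnv <- matrix(sample(c(-2L, -1L, 0L, 1L, 2L), length(fam) * nc,
                       replace = TRUE, prob = c(0.03, 0.12, 0.70, 0.12, 0.03)),
                nrow = length(fam), dimnames = list(fam, tumor_ids))
  Ec[fam, ] <- Ec[fam, ] + config$cnv_dosage_slope * cnv

  ## promoter methylation: gene-level betas generated on the logit scale,
  ## probes jitter around the gene value; coupling to expression is linear
  ## in beta with slope methylation_slope (applied to both conditions).
  base_beta <- stats::rbeta(length(fam), 2, 5)
  names(base_beta) <- fam
  lo <- stats::qlogis(pmin(0.98, pmax(0.02, base_beta)))
  beta_c <- stats::plogis(lo + matrix(stats::rnorm(length(fam) * nc, 0, 0.5),
                                      nrow = length(fam)))
  beta_n <- stats::plogis(lo + matrix(stats::rnorm(length(fam) * nn, 0, 0.5),
                                      nrow = length(fam)))
  dimnames(beta_c) <- list(fam, tumor_ids)
  dimnames(beta_n) <- list(fam, normal_ids)
  dm <- config$dm_genes
  for (i in seq_len(NROW(dm))) {
    g <- dm$gene[i]
    beta_c[g, ] <- stats::plogis(stats::qlogis(beta_c[g, ]) + dm$logit_shift[i])
    note("dm_logit_shift", g, NA_character_, dm$logit_shift[i])
  }
  Ec[fam, ] <- Ec[fam, ] + config$methylation_slope * (beta_c - base_beta)
  En[fam, ] <- En[fam, ] + config$methylation_slope * (beta_n - base_beta)

  ## probe-level betas: 1-3 promoter probes per gene, ~10% of genes get an
  ## extra gene-body probe that promoter aggregation must ignore.
  n_probes <- sample(1:3, length(fam), replace = TRUE)
  probe_rows <- list()
  probe_betas <- list()
  pid <- 0L
  for (i in seq_along(fam)) {
    for (k in seq_len(n_probes[i])) {
      pid <- pid + 1L
      id <- sprintf("cg%06d", pid)
      probe_rows[[id]] <- data.frame(probe_id = id, gene_id = fam[i],
                                     promoter = TRUE,
                                     stringsAsFactors = FALSE)
      probe_betas[[id]] <- .clip01(
        c(beta_c[i, ], beta_n[i, ]) +
          stats::rnorm(nc + nn, 0, 0.02))
    }
    if (stats::runif(1) < 0.1) {
      pid <- pid + 1L
      id <- sprintf("cg%06d", pid)
      probe_rows[[id]] <- data.frame(probe_id = id, gene_id = fam[i],
                                     promoter = FALSE,
                                     stringsAsFactors = FALSE)
      probe_betas[[id]] <- .clip01(stats::runif(nc + nn))
    }
  }
  probe_map <- do.call(rbind, probe_rows)
  rownames(probe_map) <- NULL
  methylation <- do.call(rbind, probe_betas)
  colnames(methylation) <- c(tumor_ids, normal_ids)

  ## planted co-expression pairs, applied last so the population
  ## correlation is exact: coupling noise from CNV/methylation/mutations
  ## would otherwise attenuate the planted rho. Pair genes keep their
  ## rows in the mutation/CNV/methylation tables but carry no expression
  ## coupling from them.
  pp <- config$planted_pairs
  for (i in seq_len(nrow(pp))) {
    zc <- sample_correlated_pair(pp$rho_cancer[i], nc)
    zn <- sample_correlated_pair(pp$rho_normal[i], nn)
    Ec[pp$gene_a[i], ] <- mu[pp$gene_a[i]] + sd0 * zc$x
    Ec[pp$gene_b[i], ] <- mu[pp$gene_b[i]] + sd0 * zc$y
    En[pp$gene_a[i], ] <- mu[pp$gene_a[i]] + sd0 * zn$x
    En[pp$gene_b[i], ] <- mu[pp$gene_b[i]] + sd0 * zn$y
    note("pair_rho_cancer", pp$gene_a[i], pp$gene_b[i], pp$rho_cancer[i])
    note("pair_rho_normal", pp$gene_a[i], pp$gene_b[i], pp$rho_normal[i])
  }

  ## TF -> target score table (regulators = family, targets = background)
  targets <- generate_target_sets(fam, bg, score_range = c(10, 500),
                                  sizes = min(15L, length(bg) - 1L))

  ## survival: exponential proportional hazards on the survival-gene
  ## median split; uniform censoring.
  surv <- data.frame(sample = tumor_ids, time = numeric(nc),
                     event = integer(nc), stringsAsFactors = FALSE)
  base_hazard <- log(2) / 24   # median survival 24 time units at baseline
  censor_max <- 100
  if (!is.na(config$survival_gene)) {
    v <- Ec[config$survival_gene, ]
    high <- v > stats::median(v)
    rate <- base_hazard * exp(config$survival_log_hr * high)
    note("survival_log_hr", config$survival_gene, NA_character_,
         config$survival_log_hr)
  } else {
    rate <- rep(base_hazard, nc)
  }
  tt <- stats::rexp(nc, rate)
  cc <- stats::runif(nc, 0, censor_max)
  surv$time <- pmin(tt, cc)
  surv$event <- as.integer(tt <= cc)

  ## cell lines: family-gene expression with planted cell-line pairs and
  ## linear IC50 couplings; one uncoupled drug provides a negative control.
  cl_ids <- sprintf("CL%03d", seq_len(config$n_cell_lines))
  Ecl <- mu[fam] + matrix(stats::rnorm(length(fam) * config$n_cell_lines,
                                       0, sd0),
                          nrow = length(fam), dimnames = list(fam, cl_ids))
  clp <- config$cell_line_pairs
  for (i in seq_len(NROW(clp))) {
    z <- sample_correlated_pair(clp$rho[i], config$n_cell_lines)
    Ecl[clp$gene_a[i], ] <- mu[clp$gene_a[i]] + sd0 * z$x
    Ecl[clp$gene_b[i], ] <- mu[clp$gene_b[i]] + sd0 * z$y
    note("cell_line_pair_rho", clp$gene_a[i], clp$gene_b[i], clp$rho[i])
  }
  dc <- config$drug_couplings
  drug_names <- unique(c(dc$drug, config$drug_annotation$drug))
  ic_rows <- list()
  for (d in drug_names) {
    j <- match(d, dc$drug)
    ic <- if (!is.na(j)) {
      dc$slope[j] * Ecl[dc$gene[j], ] +
        stats::rnorm(config$n_cell_lines, 0, dc$noise_sd[j])
    } else {
      stats::rnorm(config$n_cell_lines, 0, 1)
    }
    if (!is.na(j)) note("drug_slope", dc$gene[j], d, dc$slope[j])
    ic_rows[[d]] <- data.frame(cell_line = cl_ids, drug = d, ic50 = ic,
                               stringsAsFactors = FALSE)
  }
  drug_ic50 <- do.call(rbind, ic_rows)
  rownames(drug_ic50) <- NULL

  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(effect = character(), gene = character(),
               partner = character(), value = numeric(),
               stringsAsFactors = FALSE)

  samples <- data.frame(
    sample = c(tumor_ids, normal_ids),
    cohort = config$cohort_id,
    condition = rep(c("cancer", "normal"), c(nc, nn)),
    stringsAsFactors = FALSE)

  structure(list(
    expression_cancer = Ec,
    expression_normal = En,
    samples = samples,
    mutations = mutations,
    cnv = cnv,
    methylation = methylation,
    probe_map = probe_map,
    targets = targets,
    survival = surv,
    cellline_expression = Ecl,
    drug_ic50 = drug_ic50,
    drug_annotation = config$drug_annotation,
    truth = truth,
    family_genes = fam,
    background_genes = bg,
    config = config), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "synthetic_cohort '%s': %d family + %d background genes, %d cancer / %d normal samples\n",
    x$config$cohort_id, length(x$family_genes), length(x$background_genes),
    x$config$n_cancer, x$config$n_normal))
  cat(sprintf("  %d mutation rows, %d probes, %d target rows, %d planted effects\n",
              nrow(x$mutations), nrow(x$methylation), nrow(x$targets),
              nrow(x$truth)))
  invisible(x)
}

#' Write a synthetic cohort as the pipeline's TSV input set
#'
#' Emits every table in the dialect the pipeline reads, so the generator
#' doubles as a fixture factory: `expression.tsv`, `samples.tsv`,
#' `mutations.tsv`, `cnv.tsv`, `methylation.tsv`, `probe_map.tsv`,
#' `targets.tsv`, `survival.tsv`, `cellline_expression.tsv`,
#' `drug_ic50.tsv`, `drug_annotation.tsv`, `family_genes.txt`,
#' `background_genes.txt` and `truth.tsv`.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if absent).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  expr <- cbind(cohort$expression_cancer, cohort$expression_normal)
  write_matrix_tsv(round(expr, 6), p("expression.tsv"))
  write_table_tsv(cohort$samples, p("samples.tsv"))
  write_table_tsv(cohort$mutations, p("mutations.tsv"))
  write_matrix_tsv(cohort$cnv, p("cnv.tsv"))
  write_matrix_tsv(round(cohort$methylation, 6), p("methylation.tsv"),
                   id_name = "probe")
  write_table_tsv(cohort$probe_map, p("probe_map.tsv"))
  write_table_tsv(cohort$targets, p("targets.tsv"))
  write_table_tsv(cohort$survival, p("survival.tsv"))
  write_matrix_tsv(round(cohort$cellline_expression, 6),
                   p("cellline_expression.tsv"))
  write_table_tsv(cohort$drug_ic50, p("drug_ic50.tsv"))
  write_table_tsv(cohort$drug_annotation, p("drug_annotation.tsv"))
  writeLines(cohort$family_genes, p("family_genes.txt"))
  writeLines(cohort$background_genes, p("background_genes.txt"))
  write_table_tsv(cohort$truth, p("truth.tsv"))
  invisible(dir)
}
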