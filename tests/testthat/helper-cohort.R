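## Shared fixtures: a scaled-down cohort configuration for fast tests
## (fewer genes/samples than the default stated world; planted structure
## unchanged) and a brute-force BH reference used as an oracle.

small_config <- function(seed = 1L, ...) {
  cohort_config(
    n_family_genes = 15L, n_background_genes = 60L,
    n_cancer = 30L, n_normal = 30L, n_cell_lines = 40L,
    planted_pairs = data.frame(
      gene_a = c("FAM01", "FAM03"), gene_b = c("FAM02", "FAM04"),
      rho_cancer = c(0.9, 0.0), rho_normal = c(0.0, 0.9),
      stringsAsFactors = FALSE),
    de_genes = data.frame(gene = "FAM09", log2fc = 3.0,
                          stringsAsFactors = FALSE),
    dm_genes = data.frame(gene = "FAM12", logit_shift = 2.0,
                          stringsAsFactors = FALSE),
    drug_annotation = data.frame(
      drug = c("drug_A", "drug_B", "drug_null"),
      target_gene = c("FAM03", "FAM05", "FAM14"),
      pathway = c("PI3K/MTOR signaling", "Cell cycle", "Unknown"),
      stringsAsFactors = FALSE),
    seed = seed, ...)
}

## Independent step-up BH: explicit double loop over ranks.
bh_bruteforce <- function(p) {
  n <- length(p)
  r <- rank(p, ties.method = "first")
  out <- numeric(n)
  for (i in seq_len(n)) {
    cand <- vapply(which(r >= r[i]), function(j) p[j] * n / r[j],
                   numeric(1L))
    out[i] <- min(1, min(cand))
  }
  out
}

## Independent exhaustive label-permutation oracle (coded separately
## from exact_permutation_pvalue: plain cor() over combn splits).
perm_oracle <- function(a, b, nc) {
  n <- length(a)
  obs <- cor(a[1:nc], b[1:nc]) - cor(a[(nc + 1):n], b[(nc + 1):n])
  splits <- combn(n, nc)
  d <- apply(splits, 2, function(ix) {
    cor(a[ix], b[ix]) - cor(a[-ix], b[-ix])
  })
  mean(abs(d) >= abs(obs) - 1e-9)   # ties count; tolerance for FP fuzz
}
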