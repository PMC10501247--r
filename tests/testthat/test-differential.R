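test_that("bh_adjust implements step-up BH exactly", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(c(0.2, 0.2, 0.2)), rep(0.2, 3))
  expect_equal(bh_adjust(numeric(0)), numeric(0))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  ## oracle battery: brute-force reference and stats::p.adjust
  set.seed(101)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    a <- bh_adjust(p)
    expect_equal(a, bh_bruteforce(p))
    expect_equal(a, p.adjust(p, method = "BH"))
  }
})

test_that("de_test computes log2fc, Welch p and strict-threshold calls", {
  set.seed(5)
  genes <- paste0("g", 1:4)
  samples_c <- paste0("t", 1:20); samples_n <- paste0("n", 1:20)
  base <- matrix(rnorm(80, 5, 0.1), 4, 20,
                 dimnames = list(genes, samples_c))
  normal <- matrix(rnorm(80, 5, 0.1), 4, 20,
                   dimnames = list(genes, samples_n))
  cancer <- base
  cancer["g1", ] <- cancer["g1", ] + 3      # clear up call
  cancer["g2", ] <- cancer["g2", ] - 3      # clear down call
  cancer["g3", ] <- cancer["g3", ] + 0.9    # significant but below lfc gate
  res <- de_test(cancer, normal)
  expect_equal(res$log2fc,
               rowMeans(cancer) - rowMeans(normal)[genes],
               ignore_attr = TRUE)
  expect_equal(res$call[res$gene == "g1"], "up")
  expect_equal(res$call[res$gene == "g2"], "down")
  ## |log2fc| <= 1 is ns regardless of p (strict > 1 threshold)
  expect_lt(res$p_adjusted[res$gene == "g3"], 0.05)
  expect_equal(res$call[res$gene == "g3"], "ns")

  ## identical matrices: all fold changes zero, everything ns
  same <- de_test(normal, normal)
  expect_true(all(same$log2fc == 0))
  expect_true(all(same$call == "ns"))

  expect_error(de_test(cancer[, 1, drop = FALSE], normal), "2 samples")
})

test_that("de_test recovers planted DE genes without excess false calls", {
  cfg <- cohort_config(n_family_genes = 12, n_background_genes = 100,
                       n_cancer = 50, n_normal = 50,
                       planted_pairs = NULL,
                       de_genes = data.frame(gene = c("FAM01", "FAM02"),
                                             log2fc = c(2.5, -2.0)),
                       dm_genes = NULL, survival_gene = NA,
                       mutation_rate = 0, cnv_dosage_slope = 0,
                       methylation_slope = 0, noise_sd = 0.5, seed = 31)
  co <- generate_cohort(cfg)
  res <- de_test(co$expression_cancer, co$expression_normal)
  expect_equal(res$call[res$gene == "FAM01"], "up")
  expect_equal(res$call[res$gene == "FAM02"], "down")
  false_calls <- sum(res$call != "ns" &
                       !res$gene %in% c("FAM01", "FAM02"))
  expect_lte(false_calls, 2L)   # ~alpha * 110 null genes in expectation
})

test_that("aggregate_promoter_probes averages promoter probes per gene", {
  betas <- matrix(c(0.7, 0.7,
                    0.2, 0.4,
                    0.9, 0.1,
                    0.5, 0.5),
                  nrow = 4, byrow = TRUE,
                  dimnames = list(c("p1", "p2", "p3", "p4"),
                                  c("s1", "s2")))
  map <- data.frame(
    probe_id = c("p1", "p2", "p3", "p4"),
    gene_id = c("G1", "G2", "G2", "G3"),
    promoter = c(TRUE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE)
  expect_message(out <- aggregate_promoter_probes(betas, map), "G3")
  expect_equal(out["G1", ], c(s1 = 0.7, s2 = 0.7))   # single probe passthrough
  expect_equal(unname(out["G2", "s1"]), mean(c(0.2, 0.9)))
  expect_false("G3" %in% rownames(out))              # no promoter probe

  bad <- betas; bad[1, 1] <- 1.2
  expect_error(aggregate_promoter_probes(bad, map), "\\[0, 1\\]")
})

test_that("diff_methylation calls hyper/hypo with rank-sum p", {
  nc <- 15; nn <- 15
  cancer <- rbind(G1 = rep(0.8, nc), G2 = seq(0.1, 0.4, length.out = nc))
  normal <- rbind(G1 = rep(0.3, nn), G2 = seq(0.1, 0.4, length.out = nn))
  colnames(cancer) <- paste0("t", 1:nc)
  colnames(normal) <- paste0("n", 1:nn)
  res <- diff_methylation(cancer, normal)
  expect_equal(res$delta_beta[res$gene == "G1"], 0.5)
  expect_equal(res$call[res$gene == "G1"], "hyper")
  expect_equal(res$delta_beta[res$gene == "G2"], 0)
  expect_equal(res$call[res$gene == "G2"], "ns")
  expect_true(all(abs(res$delta_beta) <= 1))

  ## n = 1 per group: the exact rank-sum p floor is 1, never callable
  one <- diff_methylation(matrix(0.9, 1, 1, dimnames = list("G", "a")),
                          matrix(0.1, 1, 1, dimnames = list("G", "b")))
  expect_equal(one$call, "ns")

  expect_error(diff_methylation(cancer * 2, normal), "\\[0, 1\\]")
})

test_that("diff_methylation sign matches the planted direction", {
  co <- generate_cohort(small_config(seed = 17))
  gb <- suppressMessages(
    aggregate_promoter_probes(co$methylation, co$probe_map))
  tumor <- co$samples$sample[co$samples$condition == "cancer"]
  norm <- co$samples$sample[co$samples$condition == "normal"]
  res <- diff_methylation(gb[, tumor], gb[, norm])
  ## FAM12 planted with positive logit shift in cancer
  expect_gt(res$delta_beta[res$gene == "FAM12"], 0)
  expect_equal(res$call[res$gene == "FAM12"], "hyper")
})
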