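mk_expr <- function(genes, n, seed = 1, sd = 1) {
  set.seed(seed)
  matrix(rnorm(length(genes) * n, 6, sd), nrow = length(genes),
         dimnames = list(genes, paste0("s", seq_len(n))))
}

test_that("pairwise_correlations is symmetric and exact on self pairs", {
  e <- mk_expr(paste0("g", 1:5), 50, seed = 2)
  pr <- data.frame(a = c("g1", "g2", "g3"), b = c("g1", "g3", "g2"))
  res <- pairwise_correlations(e, pr)
  expect_equal(res$r[1], 1.0)
  expect_equal(res$r[2], res$r[3])   # symmetry in pair order

  e["g4", ] <- 5
  expect_error(pairwise_correlations(e, data.frame(a = "g4", b = "g1")),
               "constant")
  expect_error(pairwise_correlations(e[, 1:2], pr), "3 samples")
})

test_that("pairwise_correlations recovers a planted rho within Fisher-z bounds", {
  set.seed(7)
  z <- sample_correlated_pair(0.9, 200)
  e <- rbind(A = z$x, B = z$y)
  colnames(e) <- paste0("s", 1:200)
  r <- pairwise_correlations(e, data.frame(a = "A", b = "B"))$r
  expect_gt(r, 0.8); expect_lt(r, 0.96)
})

test_that("sample_null_distribution is deterministic, sized and calibrated", {
  e <- mk_expr(paste0("bg", 1:50), 100, seed = 3)
  n1 <- sample_null_distribution(e, rownames(e), n_pairs = 2000, seed = 5)
  n2 <- sample_null_distribution(e, rownames(e), n_pairs = 2000, seed = 5)
  expect_identical(n1$abs_r, n2$abs_r)
  expect_length(n1$abs_r, 2000)
  expect_true(all(n1$abs_r >= 0 & n1$abs_r <= 1))
  expect_false(is.unsorted(n1$abs_r))

  ## i.i.d. noise at n = 100 samples: median |r| ~ 0.6745 / sqrt(n - 1)
  expect_lt(abs(median(n1$abs_r) - 0.6745 / sqrt(99)), 0.01)

  ## forced single pair from a 2-gene pool
  tiny <- sample_null_distribution(e[1:2, ], rownames(e)[1:2], n_pairs = 1,
                                   seed = 1)
  expect_equal(tiny$abs_r, abs(cor(e[1, ], e[2, ])))

  ## pool smaller than n_pairs falls back to replacement sampling
  many <- sample_null_distribution(e[1:3, ], rownames(e)[1:3],
                                   n_pairs = 10, seed = 1)
  expect_length(many$abs_r, 10)

  expect_error(sample_null_distribution(e[1, , drop = FALSE],
                                        "bg1", 10), "2 genes")
})

test_that("empirical_pvalue counts ties toward the numerator", {
  null <- structure(list(condition = "cancer",
                         abs_r = seq(0.1, 1.0, by = 0.1),
                         n_pairs = 10L, seed = 1L),
                    class = "null_distribution")
  expect_equal(empirical_pvalue(0.55, null), 0.5)
  expect_equal(empirical_pvalue(0.5, null), 0.6)  # tie at 0.5 counts
  expect_equal(empirical_pvalue(0, null), 1.0)
  expect_equal(empirical_pvalue(1.5, null), 0.0)
  expect_equal(empirical_pvalue(-0.55, null), 0.5) # absolute value
})

test_that("build_network retains strictly sub-alpha edges as an igraph", {
  edges <- data.frame(gene_a = c("A", "B", "C"),
                      gene_b = c("B", "C", "A"),
                      p_cancer = c(0.001, 0.01, 0.5),
                      p_normal = c(0.5, 0.5, 0.5))
  net <- build_network(edges, alpha = 0.01, condition = "cancer")
  expect_s3_class(net, "igraph")
  expect_equal(igraph::ecount(net), 1L)  # p = 0.01 excluded (strict <)
  expect_equal(sum(igraph::degree(net)), 2L)

  empty <- build_network(transform(edges, p_cancer = 0.5), 0.01, "cancer")
  expect_equal(igraph::ecount(empty), 0L)

  full <- build_network(transform(edges, p_cancer = 0), 0.01, "cancer")
  expect_equal(sum(igraph::degree(full)), 6L)  # handshake lemma

  ## edge set invariant to input pair order
  net2 <- build_network(edges[c(3, 1, 2), ], 0.01, "cancer")
  expect_setequal(apply(igraph::as_edgelist(net), 1, function(x)
    paste(sort(x), collapse = "-")),
    apply(igraph::as_edgelist(net2), 1, function(x)
      paste(sort(x), collapse = "-")))
})

test_that("classify_edges partitions the tested universe", {
  genes <- paste0("g", 1:5)
  cmb <- combn(genes, 2)
  universe <- data.frame(gene_a = cmb[1, ], gene_b = cmb[2, ])
  edges <- data.frame(universe,
                      p_cancer = rep(1, 10), p_normal = rep(1, 10))
  edges$p_cancer[1:4] <- 0   # 1:3 cancer-only + 1 shared
  edges$p_normal[4:6] <- 0   # 1 shared + 2 normal-only
  cn <- build_network(edges, 0.01, "cancer")
  nn <- build_network(edges, 0.01, "normal")
  cl <- classify_edges(cn, nn, universe)
  counts <- table(cl$status)
  expect_equal(unname(counts[["cancer_only"]]), 3L)
  expect_equal(unname(counts[["normal_only"]]), 2L)
  expect_equal(unname(counts[["shared"]]), 1L)
  expect_equal(unname(counts[["insignificant"]]), 4L)
  expect_equal(sum(counts), nrow(universe))

  expect_error(classify_edges(cn, nn, universe[1:3, ]), "universe")
})

test_that("binomial_shift_test matches exact binomial tails", {
  r <- binomial_shift_test(8, 2)
  expect_equal(r$p_value, 112 / 1024)   # 2 * P(X >= 8 | n=10, 0.5)
  expect_equal(r$direction, "none")

  expect_equal(binomial_shift_test(5, 5)$p_value, 1.0)

  r20 <- binomial_shift_test(20, 0)
  expect_equal(r20$p_value, 2 * (1 / 2^20))
  expect_equal(r20$direction, "increase")

  r0 <- binomial_shift_test(0, 0)
  expect_true(is.na(r0$p_value))
  expect_equal(r0$direction, "none")
})

test_that("coexpression_analysis classifies planted pairs and conserves counts", {
  co <- generate_cohort(small_config(seed = 23))
  tumor <- co$samples$sample[co$samples$condition == "cancer"]
  norm <- co$samples$sample[co$samples$condition == "normal"]
  expr <- cbind(co$expression_cancer, co$expression_normal)
  cx <- coexpression_analysis(expr[, tumor], expr[, norm],
                              co$family_genes, co$background_genes,
                              n_pairs = 2000, seed = 4)
  ## count conservation
  expect_equal(sum(table(cx$edges$status)), nrow(cx$edges))
  expect_lte(cx$comparison$n_shared,
             min(cx$comparison$n_cancer_edges,
                 cx$comparison$n_normal_edges))
  ## planted rho = 0.9 cancer-only pair found
  st <- cx$edges$status[cx$edges$gene_a == "FAM01" &
                          cx$edges$gene_b == "FAM02"]
  expect_equal(as.character(st), "cancer_only")
  st2 <- cx$edges$status[cx$edges$gene_a == "FAM03" &
                           cx$edges$gene_b == "FAM04"]
  expect_equal(as.character(st2), "normal_only")
})
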