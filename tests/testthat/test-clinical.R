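test_that("median_split assigns ties to low and rejects degenerate input", {
  g <- median_split(c(a = 1, b = 2, c = 3, d = 4))
  expect_equal(as.character(g), c("low", "low", "high", "high"))
  g2 <- median_split(c(1, 2, 2, 3))
  expect_equal(as.character(g2), c("low", "low", "low", "high"))
  expect_error(median_split(c(1, 1, 1, 1)), "degenerate")
  expect_error(median_split(c(1, 2)), "4 samples")
})

test_that("km_estimate reproduces hand-computed product limits", {
  ## three events, no censoring
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0))

  ## risk-set bookkeeping with interleaved censoring
  km2 <- km_estimate(c(1, 1.5, 2, 3), c(1, 0, 1, 0))
  expect_equal(km2$survival, c(3 / 4, 3 / 4 * 1 / 2))
  expect_equal(km2$n_risk, c(4, 2))

  ## all censored: flat at 1 (no event rows)
  km3 <- km_estimate(c(1, 2, 3), c(0, 0, 0))
  expect_equal(nrow(km3), 0L)

  ## equals the empirical survival function without censoring
  set.seed(2)
  tt <- rexp(40) + 0.01
  km4 <- km_estimate(tt, rep(1, 40))
  emp <- sapply(km4$time, function(t0) mean(tt > t0))
  expect_equal(km4$survival, emp)

  expect_error(km_estimate(c(0, 1), c(1, 1)), "non-positive")
})

test_that("logrank_test matches the 4-event hand calculation", {
  ## A events at {1,2}, B events at {3,4}: O1=2, E1=5/6, V=17/36
  lr <- logrank_test(c(1, 2), c(1, 1), c(3, 4), c(1, 1))
  expect_equal(lr$chi_square, 49 / 17, tolerance = 1e-12)
  expect_equal(lr$p_value, pchisq(49 / 17, 1, lower.tail = FALSE))

  ## identical groups: chi-square 0, p 1
  lr0 <- logrank_test(c(1, 2, 3), c(1, 1, 0), c(1, 2, 3), c(1, 1, 0))
  expect_equal(lr0$chi_square, 0)
  expect_equal(lr0$p_value, 1)

  ## label swap invariance
  set.seed(4)
  tA <- rexp(20); tB <- rexp(20) * 2
  eA <- rbinom(20, 1, 0.8); eB <- rbinom(20, 1, 0.8)
  l1 <- logrank_test(tA, eA, tB, eB)
  l2 <- logrank_test(tB, eB, tA, eA)
  expect_equal(l1$chi_square, l2$chi_square)

  ## maximal separation is significant at n = 10/10
  lr2 <- logrank_test(rep(1:10, 1), rep(1, 10),
                      seq(20, 29), rep(0, 10))
  expect_lt(lr2$p_value, 0.05)

  ## zero events: no-test result
  lrna <- logrank_test(1:3, c(0, 0, 0), 1:3, c(0, 0, 0))
  expect_true(is.na(lrna$p_value))
})

test_that("logrank equals the Cox score test at beta = 0 on untied data", {
  set.seed(9)
  for (i in 1:10) {
    n <- 30
    time <- rexp(2 * n) + runif(2 * n, 0, 1e-4)  # untied
    event <- rbinom(2 * n, 1, 0.8)
    if (sum(event) == 0) next
    grp <- rep(c("low", "high"), each = n)
    lr <- logrank_test(time[grp == "high"], event[grp == "high"],
                       time[grp == "low"], event[grp == "low"])
    sc <- survival::coxph(
      survival::Surv(time, event) ~ I(grp == "high"))
    expect_equal(lr$chi_square, unname(sc$score), tolerance = 1e-6)
  }
})

test_that("cox_univariate reports direction and handles edge cases", {
  set.seed(12)
  n <- 200
  grp <- factor(rep(c("low", "high"), each = n), levels = c("low", "high"))
  rate <- ifelse(grp == "high", 2, 1)
  time <- rexp(2 * n, rate)
  event <- rep(1L, 2 * n)
  fit <- cox_univariate(grp, time, event)
  expect_gt(fit$hr, 1)
  expect_equal(fit$direction, "risk")
  expect_lt(abs(fit$log_hr - log(2)), 3 * fit$se)
  expect_true(fit$ci_lower < fit$hr && fit$hr < fit$ci_upper)

  ## identical survival in both groups: hr ~ 1, ns
  t0 <- rexp(2 * n)
  fit0 <- cox_univariate(grp, c(t0[1:n], t0[1:n]), event)
  expect_lt(abs(fit0$log_hr), 0.2)
  expect_equal(fit0$direction, "ns")

  expect_error(cox_univariate(grp, time, rep(0L, 2 * n)), "no events")
})

test_that("cox_univariate recovers the generator's planted log hazard ratio", {
  cfg <- cohort_config(n_family_genes = 5, n_background_genes = 5,
                       n_cancer = 300, n_normal = 10,
                       planted_pairs = NULL, de_genes = NULL,
                       dm_genes = NULL, survival_gene = "FAM01",
                       survival_log_hr = log(2), mutation_rate = 0,
                       seed = 77)
  co <- generate_cohort(cfg)
  grp <- median_split(co$expression_cancer["FAM01", co$survival$sample])
  fit <- cox_univariate(grp, co$survival$time, co$survival$event)
  expect_lt(abs(fit$log_hr - log(2)), 3 * fit$se)
})

test_that("drug_correlation applies both strict gates", {
  set.seed(6)
  n <- 100
  e <- rnorm(n); names(e) <- paste0("c", 1:n)
  strong <- 0.8 * e + rnorm(n, 0, 0.5); names(strong) <- names(e)
  res <- drug_correlation(e, strong)
  expect_true(res$retained)

  ## tiny |PCC| with minuscule p is still dropped (magnitude gate)
  set.seed(8)
  n2 <- 20000
  e2 <- rnorm(n2); weak <- 0.1 * e2 + rnorm(n2)
  names(e2) <- names(weak) <- paste0("c", 1:n2)
  res2 <- drug_correlation(e2, weak)
  expect_lt(res2$p_value, 1e-8)
  expect_lt(abs(res2$pcc), 0.2)
  expect_false(res2$retained)

  expect_error(drug_correlation(e[1:2], strong[1:2]), "3 shared")
  ## filter conserves counts
  expect_equal(res$retained + !res$retained, 1L)
})

test_that("build_drug_axis joins retained pairs through the annotation", {
  gd <- data.frame(gene = "G1", drug = "d1", pcc = 0.5, p_value = 0.001)
  gt <- data.frame(gene = "G1", target = c("T1", "T2"),
                   pcc = c(0.4, 0.3), p_value = c(0.01, 0.01))
  ann <- data.frame(drug = c("d1", "d1"), target_gene = c("T1", "T2"),
                    pathway = c("P1", "P2"))
  axis <- build_drug_axis(gd, gt, ann)
  expect_equal(nrow(axis), 2L)   # one drug via two annotated targets
  expect_setequal(axis$drug_target, c("T1", "T2"))

  ## no retained pairs -> empty table
  expect_equal(nrow(build_drug_axis(gd[0, ], gt, ann)), 0L)

  ## unannotated drug dropped with a message
  gd2 <- data.frame(gene = "G1", drug = "mystery", pcc = 0.5,
                    p_value = 0.001)
  expect_message(out <- build_drug_axis(gd2, gt, ann), "mystery")
  expect_equal(nrow(out), 0L)
})
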