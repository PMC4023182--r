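test_that("paired t-test matches the textbook closed form", {
  d <- c(0.1, 0.2, 0.3, 0.4)
  m18 <- c(1, 1, 1, 1)
  res <- paired_methylation_test(m18 + d, m18, alpha = 0.05)
  ora <- paired_t_closed(d)
  expect_equal(res$t, ora$t, tolerance = 1e-10)
  expect_equal(res$t, 3.872983, tolerance = 1e-6)
  expect_equal(res$df, 3)
  expect_equal(res$p, ora$p, tolerance = 1e-10)
  expect_equal(res$p, 0.03047, tolerance = 1e-3)
  expect_identical(res$classification, "dynamic")
  expect_equal(res$mean_diff, 0.25)
  # property: closed form equality on random vectors
  set.seed(40)
  for (rep in 1:10) {
    a <- rnorm(15); b <- rnorm(15)
    r <- paired_methylation_test(a, b)
    o <- paired_t_closed(a - b)
    expect_equal(r$t, o$t, tolerance = 1e-10)
    expect_equal(r$p, o$p, tolerance = 1e-10)
  }
})

test_that("degenerate and undersized pairings are handled explicitly", {
  x <- c(0.5, 0.7, 0.9)
  same <- paired_methylation_test(x, x)
  expect_true(same$degenerate)
  expect_identical(same$classification, "stable")
  expect_equal(same$mean_diff, 0)
  shift <- paired_methylation_test(x + 0.2, x)
  expect_true(shift$degenerate)
  expect_equal(shift$p, 0)   # zero-variance nonzero difference
  expect_identical(shift$classification, "dynamic")
  tiny <- paired_methylation_test(c(1, NA), c(0.5, 0.2))
  expect_identical(tiny$classification, "undetermined")
})

test_that("null temporal change is classified dynamic at ~ the alpha rate", {
  set.seed(41)
  hits <- vapply(1:1000, function(i) {
    m10 <- rnorm(34); m18 <- rnorm(34)
    paired_methylation_test(m10, m18)$classification == "dynamic"
  }, logical(1))
  se <- sqrt(0.05 * 0.95 / 1000)
  expect_lt(abs(mean(hits) - 0.05), 3 * se)
})

test_that("transition labels partition subjects as a pure function of status", {
  ph <- phenotype_panel(data.frame(
    sample_id = paste0("S", 1:6),
    asthma10 = c(0, 0, 1, 1, NA, 0),
    asthma18 = c(0, 1, 0, 1, 0, NA)))
  lab <- classify_transitions(ph)
  expect_equal(as.character(lab$label),
               c("none", "positive", "negative", "persistent",
                 "undetermined", "undetermined"))
  expect_equal(sum(table(lab$label)), nrow(ph))  # labels partition the cohort
})

test_that("stable vs dynamic classification switches the design matrix", {
  p <- tiny_panel(1, 1)
  cfg <- cohort_config(panel = p, n = 400, maf = flat_mafs(p),
                       moments = flat_moments(p, 0.3, 0.05), rho = 0.5,
                       outcome10 = outcome_model(b0 = qlogis(0.2)),
                       outcome18 = outcome_model(b0 = qlogis(0.2)),
                       missing = list(beta = 0, genotype = 0, phenotype = 0),
                       subsample = NULL)
  co <- simulate_cohort(cfg, seed = 42)
  cpg <- p$cpgs$probe[1]; snp <- p$snps$snp[1]
  dyn_stable <- data.frame(cpg = cpg, n_pairs = 400, mean_diff = 0, t = 0,
                           df = 399, p = 0.9, classification = "stable",
                           degenerate = FALSE)
  dyn_dynamic <- dyn_stable; dyn_dynamic$classification <- "dynamic"
  f_st <- transition_regression(co, cpg, snp, dyn_stable, "positive")
  f_dy <- transition_regression(co, cpg, snp, dyn_dynamic, "positive")
  expect_identical(f_st$predictor, "m_age18")
  expect_identical(f_dy$predictor, "delta_m")
  # different predictors give different fits on the same cohort
  expect_false(isTRUE(all.equal(coef(f_st)["meth"], coef(f_dy)["meth"])))
  # persistent subjects never enter; positive and negative sets share only "none"
  labs <- classify_transitions(co$phenotypes)
  n_pos <- sum(labs$label %in% c("positive", "none"))
  expect_equal(f_st$n_used, n_pos)
})

test_that("a true methylation-change effect on transition is recovered", {
  p <- tiny_panel(1, 1)
  cpg <- p$cpgs$probe[1]; snp <- p$snps$snp[1]
  cfg <- cohort_config(
    panel = p, n = 2000, maf = flat_mafs(p),
    moments = data.frame(probe = cpg, mean10 = 0.076, sd10 = 0.022,
                         mean18 = 0.062, sd18 = 0.013),
    rho = 0.7,
    outcome10 = outcome_model(b0 = -30),  # nobody asthmatic at age 10
    outcome18 = outcome_model(b0 = -1.2, b_delta = -3, cpg = cpg),
    missing = list(beta = 0, genotype = 0, phenotype = 0),
    subsample = NULL)
  co <- simulate_cohort(cfg, seed = 43)
  dyn <- methylation_dynamics(co, cpg)
  expect_identical(dyn$classification, "dynamic")
  fit <- transition_regression(co, cpg, snp, dyn, "positive")
  est <- fit$terms[fit$terms$term == "meth", ]
  expect_lt(est$estimate, 0)
  expect_lt(abs(est$estimate - (-3)), 3 * est$se)
  # null predictor: coefficient within 3 SE of zero
  cfg0 <- cfg
  cfg0$outcome18 <- outcome_model(b0 = -1.2)
  co0 <- simulate_cohort(cfg0, seed = 44)
  fit0 <- transition_regression(co0, cpg, snp, dyn, "positive")
  est0 <- fit0$terms[fit0$terms$term == "meth", ]
  expect_lt(abs(est0$estimate), 3 * est0$se)
})
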