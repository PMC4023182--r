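test_that("Hardy-Weinberg genotype simulation hits expected proportions", {
  al <- list(rsX = c("A", "G"))
  g0 <- simulate_genotypes(c(rsX = 0), 50, al, seed = 1)
  expect_true(all(unclass(g0)[, "rsX"] == "GG"))  # maf 0: all major homozygote

  g <- simulate_genotypes(c(rsX = 0.5), 1e5, al, seed = 2)
  frac <- table(unclass(g)[, "rsX"]) / 1e5
  expect_true(all(abs(frac[c("AA", "AG", "GG")] - c(0.25, 0.5, 0.25)) < 0.01))

  # allele-count calibration: rs3024685-like maf gives ~16.6% minor homozygotes
  maf <- (104 + 2 * 42) / 462
  g2 <- simulate_genotypes(c(rsX = maf), 1e5, al, seed = 3)
  expect_lt(abs(mean(unclass(g2)[, "rsX"] == "AA") - maf^2), 0.01)
  expect_error(simulate_genotypes(c(rsX = 0.6), 10, al), "\\[0, 0.5\\]")
})

test_that("method-of-moments beta shapes match the closed form", {
  sh <- beta_shape_params(0.076, 0.022)
  expect_equal(unname(sh), c(10.95091, 133.13996), tolerance = 1e-5)
  expect_error(beta_shape_params(0.5, 0.6), "infeasible")
})

test_that("simulated methylation recovers target moments", {
  mom <- data.frame(probe = "cgA", mean10 = 0.88, sd10 = 0.016,
                    mean18 = 0.86, sd18 = 0.019)
  sim <- simulate_methylation(5e4, mom, rho = 0.7, seed = 4)
  b10 <- unclass(sim$beta10)[, "cgA"]
  expect_lt(abs(mean(b10) - 0.88), 0.002)
  expect_lt(abs(sd(b10) - 0.016), 0.002)
  b18 <- unclass(sim$beta18)[, "cgA"]
  expect_lt(abs(mean(b18) - 0.86), 0.002)
})

test_that("copula links the two ages as configured", {
  mom <- data.frame(probe = "cgA", mean10 = 0.3, sd10 = 0.05,
                    mean18 = 0.3, sd18 = 0.05)
  # comonotone coupling with identical marginals: ages identical per sample
  sim <- simulate_methylation(500, mom, rho = 0, copula = "comonotone", seed = 5)
  expect_equal(unclass(sim$beta10)[, 1], unclass(sim$beta18)[, 1],
               tolerance = 1e-12)
  sim1 <- simulate_methylation(500, mom, rho = 1, seed = 5)
  expect_equal(unclass(sim1$beta10)[, 1], unclass(sim1$beta18)[, 1],
               tolerance = 1e-12)
  # empirical logit-scale correlation near the configured rho
  sim2 <- simulate_methylation(1e4, mom, rho = 0.7, seed = 6)
  r <- cor(beta_to_mvalue(unclass(sim2$beta10)[, 1]),
           beta_to_mvalue(unclass(sim2$beta18)[, 1]))
  expect_lt(abs(r - 0.7), 0.05)
})

test_that("null outcome model reproduces the target prevalence", {
  y <- simulate_outcomes(outcome_model(b0 = qlogis(0.143)), n = 1e5, seed = 7)
  expect_lt(abs(mean(y) - 0.143), 0.005)
  # saturating methylation effect splits outcomes by the sign of M
  m <- c(a = -2, b = -0.5, c = 0.5, d = 2)
  y2 <- simulate_outcomes(outcome_model(b0 = 0, b_m = 50, cpg = "cgA"),
                          mvalues = m, seed = 8)
  expect_equal(unname(y2), c(0L, 0L, 1L, 1L))
})

test_that("cohort simulation honours the nested age-10 subsample design", {
  co <- simulate_cohort(cohort_config(n = 245), seed = 42)
  b10 <- unclass(co$beta10)
  measured <- rownames(b10)[rowSums(!is.na(b10)) > 0]
  expect_length(measured, 34L)
  ph <- co$phenotypes[match(measured, co$phenotypes$sample_id), ]
  expect_equal(sum(ph$asthma10 == 1), 16L)
  expect_equal(sum(ph$asthma10 == 0), 18L)
  # age-10 complete-case set (status + methylation) is exactly the subsample
  cc <- stats::complete.cases(b10)
  expect_equal(sum(cc), 34L)
})

test_that("cohort simulation is bit-reproducible and masks at configured rates", {
  p <- tiny_panel(2, 2)
  cfg <- cohort_config(panel = p, n = 200, maf = flat_mafs(p),
                       moments = flat_moments(p),
                       missing = list(beta = 0, genotype = 0, phenotype = 0),
                       subsample = NULL)
  a <- simulate_cohort(cfg, seed = 9)
  b <- simulate_cohort(cfg, seed = 9)
  expect_identical(unclass(a$beta18), unclass(b$beta18))
  expect_identical(unclass(a$beta10), unclass(b$beta10))
  expect_identical(unclass(a$genotypes), unclass(b$genotypes))
  expect_identical(a$phenotypes, b$phenotypes)
  # no missingness configured, no subsample: fully observed
  expect_false(anyNA(unclass(a$beta10)))
  expect_false(anyNA(unclass(a$genotypes)))
  # infeasible subsample request errors
  cfg_bad <- cohort_config(panel = p, n = 30, maf = flat_mafs(p),
                           moments = flat_moments(p),
                           outcome10 = outcome_model(b0 = qlogis(0.01)),
                           subsample = list(cases = 16, controls = 10))
  expect_error(simulate_cohort(cfg_bad, seed = 10), "subsample")
})

test_that("truth record round-trips through serialization", {
  p <- tiny_panel(1, 1)
  cfg <- cohort_config(panel = p, n = 50, maf = flat_mafs(p),
                       moments = flat_moments(p), subsample = NULL)
  co <- simulate_cohort(cfg, seed = 11)
  d <- tempfile()
  write_cohort(co, d)
  co2 <- read_cohort(d, p)
  expect_equal(co2$truth$seed, 11)
  expect_equal(co2$truth$rho, co$truth$rho)
  expect_equal(unlist(co2$truth$maf), unlist(co$truth$maf))
  expect_equal(as.data.frame(co2$truth$moments), co$truth$moments,
               ignore_attr = TRUE)
  expect_identical(unclass(co2$beta18), unclass(co$beta18))
  unlink(d, recursive = TRUE)
})

test_that("HWE goodness of fit holds across replicate simulations", {
  al <- list(rsX = c("A", "G"))
  pvals <- vapply(1:40, function(i) {
    g <- unclass(simulate_genotypes(c(rsX = 0.3), 2000, al, seed = 100 + i))[, 1]
    obs <- table(factor(g, levels = c("AA", "AG", "GG")))
    expe <- 2000 * c(0.09, 0.42, 0.49)
    stats::chisq.test(obs, p = expe / 2000)$p.value
  }, numeric(1))
  expect_gte(mean(pvals > 0.01), 0.95)
})
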