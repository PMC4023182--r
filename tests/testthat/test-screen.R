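make_saturated_data <- function() {
  # binary "methylation" proxy x genotype strata with known cell counts:
  # G=0: exposed/unexposed cases 10/20, controls 20/10
  # G=1: exposed/unexposed cases 20/10, controls 10/20
  block <- function(g, ce, cu, ke, ku) {
    data.frame(
      y = c(rep(1, ce + cu), rep(0, ke + ku)),
      m = c(rep(1, ce), rep(0, cu), rep(1, ke), rep(0, ku)),
      g = g)
  }
  rbind(block("AA", 10, 20, 20, 10), block("AG", 20, 10, 10, 20))
}

test_that("saturated binary design matches closed-form log cross-product ratios", {
  d <- make_saturated_data()
  fit <- fit_interaction_model(d$y, d$m, d$g, reference = "AA")
  co <- coef(fit)
  or0 <- (10 * 10) / (20 * 20)   # exposure OR in the reference stratum
  or1 <- (20 * 20) / (10 * 10)
  expect_equal(unname(co["meth:geno=AG"]), log(or1 / or0), tolerance = 1e-6)
  expect_equal(unname(co["meth:geno=AG"]), 2.772589, tolerance = 1e-6)
  expect_equal(unname(co["meth"]), log(or0), tolerance = 1e-6)
  # intercept = log-odds of outcome in the (m=0, reference) cell
  expect_equal(unname(co["intercept"]), log(20 / 10), tolerance = 1e-6)
  expect_equal(unname(co["geno=AG"]), log(10 / 20) - log(20 / 10),
               tolerance = 1e-6)
})

test_that("coefficients and SEs match an independent IRLS oracle", {
  set.seed(21)
  for (rep in 1:5) {
    n <- 300
    m <- rnorm(n)
    g <- sample(c("AA", "AG", "GG"), n, replace = TRUE, prob = c(0.2, 0.5, 0.3))
    eta <- -0.5 + 0.6 * m + 0.4 * (g == "AA") + 0.8 * (g == "GG") * m
    y <- rbinom(n, 1, plogis(eta))
    fit <- fit_interaction_model(y, m, g, reference = "AG")
    gf <- relevel(factor(g), ref = "AG")
    X <- model.matrix(~ m * gf)
    ora <- irls_logistic(X, y)
    expect_equal(unname(coef(fit)), unname(ora$coef), tolerance = 1e-6)
    # glm stops on a deviance criterion, the oracle on coefficients, so the
    # observed-information SEs agree a little less tightly
    expect_equal(fit$terms$se, unname(ora$se), tolerance = 1e-4)
  }
})

test_that("a 3-level SNP against its reference yields the 2k-coefficient term set", {
  set.seed(22)
  n <- 200
  g <- sample(c("AA", "AG", "GG"), n, replace = TRUE)
  m <- rnorm(n)
  y <- rbinom(n, 1, 0.3)
  fit <- fit_interaction_model(y, m, g, reference = "AG")
  expect_setequal(fit$terms$term,
                  c("intercept", "meth", "geno=AA", "geno=GG",
                    "meth:geno=AA", "meth:geno=GG"))
  expect_identical(fit$reference, "AG")
  expect_equal(nrow(fit$terms), 6L)  # 2k with k = 3
})

test_that("default reference is the most frequent genotype; empty levels drop", {
  set.seed(23)
  n <- 150
  g <- sample(c("AA", "AG", "GG"), n, replace = TRUE, prob = c(0.1, 0.3, 0.6))
  m <- rnorm(n)
  y <- rbinom(n, 1, 0.4)
  fit <- fit_interaction_model(y, m, g)
  expect_identical(fit$reference, "GG")
  # a level present only in rows lost to missingness is dropped and recorded
  m2 <- m; m2[g == "AA"] <- NA
  fit2 <- fit_interaction_model(y, m2, g)
  expect_identical(fit2$dropped_levels, "AA")
  expect_false(any(grepl("AA", fit2$terms$term)))
})

test_that("separation is flagged but reported, and degenerate inputs error", {
  # quasi-complete separation: outcome determined by genotype stratum
  y <- c(rep(1, 20), rep(0, 20), rep(1, 10), rep(0, 30))
  g <- c(rep("AA", 40), rep("AG", 40))
  m <- c(rep(c(1, 0), c(20, 20)), rnorm(40))  # meth separates within AA
  fit <- fit_interaction_model(y, m, g, reference = "AG")
  expect_true(any(fit$terms$separation))
  expect_true(all(is.finite(fit$terms$estimate)))
  expect_error(fit_interaction_model(rep(1, 50), rnorm(50),
                                     rep(c("AA", "AG"), 25)),
               "degenerate outcome")
  expect_error(fit_interaction_model(c(0, 1, 0, 1), rnorm(4),
                                     c("AA", "AG", "GG", "AA")),
               "under-determined")
})

test_that("null data give estimates within 3 SE of zero", {
  set.seed(24)
  n <- 10000
  m <- rnorm(n)
  g <- sample(c("AA", "AG", "GG"), n, replace = TRUE)
  y <- rbinom(n, 1, 0.3)
  fit <- fit_interaction_model(y, m, g)
  tt <- fit$terms[fit$terms$term != "intercept", ]
  expect_true(all(abs(tt$estimate) < 3 * tt$se))
})

test_that("selection rule triggers on methylation main or interaction p < alpha", {
  mkfit <- function(p_meth, p_int, sep_int = FALSE) {
    structure(list(
      terms = data.frame(
        term = c("intercept", "meth", "geno=AA", "meth:geno=AA"),
        estimate = c(0, 1, 1, 1), se = 1,
        p = c(0.5, p_meth, 0.5, p_int),
        separation = c(FALSE, FALSE, FALSE, sep_int)),
      n_used = 100L, converged = TRUE, reference = "AG",
      dropped_levels = character(),
      spec = list(gene = "G", cpg = "cg", snp = "rs"), age = "age18"),
      class = "th2_fit")
  }
  # borderline main effect: selected at 0.05 only
  s <- select_models(list(mkfit(0.049, 0.8)), alpha = 0.05)
  expect_true(s$selected); expect_identical(s$trigger, "methylation_main")
  expect_false(select_models(list(mkfit(0.049, 0.8)), alpha = 0.01)$selected)
  # interaction-driven selection
  s2 <- select_models(list(mkfit(0.2, 0.003)), alpha = 0.01)
  expect_true(s2$selected); expect_identical(s2$trigger, "interaction")
  s3 <- select_models(list(mkfit(0.001, 0.003)), alpha = 0.01)
  expect_identical(s3$trigger, "both")
  expect_false(select_models(list(mkfit(1, 1)), alpha = 0.05)$selected)
  # separation-flagged interaction cannot trigger unless allowed
  expect_false(select_models(list(mkfit(0.2, 0.003, sep_int = TRUE)),
                             alpha = 0.01)$selected)
  expect_true(select_models(list(mkfit(0.2, 0.003, sep_int = TRUE)),
                            alpha = 0.01, allow_separated = TRUE)$selected)
  expect_error(select_models(list(mkfit(0.5, 0.5)), alpha = 1.5), "alpha")
})

test_that("screen visits the full within-gene model space minus exclusions", {
  co <- simulate_cohort(cohort_config(n = 245), seed = 1)
  p <- th2_panel()
  scr <- run_screen(co, p, age = "age18", alpha = 0.01)
  expect_equal(scr$n_models, 1361L)
  expect_equal(length(scr$fits), 1361L)
  gata3 <- panel_definition(p$cpgs[p$cpgs$gene == "GATA3", ],
                            p$snps[p$snps$gene == "GATA3", ])
  expect_equal(run_screen(co, gata3, age = "age18")$n_models, 1139L)
  excl <- p$cpgs$probe[p$cpgs$gene == "GATA3"]
  scr2 <- run_screen(co, p, age = "age18", exclude_probes = excl)
  expect_equal(scr2$n_models, 1361L - 1139L)
  # failures are captured per model, never raised
  expect_s3_class(scr$failures, "data.frame")
  # deterministic ordering matches enumerate_models
  expect_identical(names(scr$fits),
                   with(enumerate_models(p), paste(gene, cpg, snp, sep = "|")))
})
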