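test_that("report blocks carry Ref. markers and NA cells for absent strata", {
  p <- tiny_panel(1, 1)
  cpg <- p$cpgs$probe[1]; snp <- p$snps$snp[1]
  cfg <- cohort_config(panel = p, n = 300, maf = flat_mafs(p, 0.08),
                       moments = flat_moments(p), subsample = NULL,
                       missing = list(beta = 0, genotype = 0, phenotype = 0),
                       outcome18 = outcome_model(b0 = qlogis(0.3)))
  co <- simulate_cohort(cfg, seed = 50)
  # blank out the rare minor homozygote so its stratum drops from the fit
  g <- unclass(co$genotypes)
  g[g[, snp] == "AA", snp] <- NA_character_
  co$genotypes <- genotype_table(g)
  scr <- run_screen(co, p, age = "age18", alpha = 0.05)
  rep <- render_report(scr, p, models = data.frame(gene = "G1", cpg = cpg,
                                                   snp = snp))
  expect_true(any(rep$flag == "Ref."))
  aa_rows <- rep[rep$level == "AA" & rep$flag != "Ref.", ]
  expect_true(nrow(aa_rows) >= 1 && all(is.na(aa_rows$estimate)))
  expect_true(all(c("parameter", "level", "estimate", "p") %in% names(rep)))
  # empty selection renders an empty report, not an error
  rep0 <- render_report(scr, p, models = data.frame(gene = character(),
                                                    cpg = character(),
                                                    snp = character()))
  expect_equal(nrow(rep0), 0L)
})

test_that("transition table mirrors the two-direction layout", {
  p <- tiny_panel(1, 1)
  cpg <- p$cpgs$probe[1]; snp <- p$snps$snp[1]
  cfg <- cohort_config(panel = p, n = 600, maf = flat_mafs(p),
                       moments = flat_moments(p, 0.3, 0.05), rho = 0.5,
                       outcome10 = outcome_model(b0 = qlogis(0.25)),
                       outcome18 = outcome_model(b0 = qlogis(0.25)),
                       missing = list(beta = 0, genotype = 0, phenotype = 0),
                       subsample = NULL)
  co <- simulate_cohort(cfg, seed = 51)
  dyn <- methylation_dynamics(co, cpg)
  fits <- lapply(c("positive", "negative"), function(d)
    transition_regression(co, cpg, snp, dyn, d))
  tab <- render_transition_table(fits)
  expect_equal(nrow(tab), 1L)
  expect_true(all(c("logOR_positive", "p_positive", "logOR_negative",
                    "p_negative") %in% names(tab)))
  expect_true(all(is.finite(c(tab$logOR_positive, tab$logOR_negative))))
})

test_that("CLI subcommands write stage artifacts and a manifest", {
  d <- file.path(tempdir(), "cli-test")
  unlink(d, recursive = TRUE)
  p <- tiny_panel(2, 1)
  pf <- file.path(tempdir(), "tiny-panel.json")
  write_panel(p, pf)
  # simulate with an explicit small n (tiny panel lacks the nested design)
  cfgf <- file.path(tempdir(), "cfg.yaml")
  yaml::write_yaml(list(mode = "simulate", panel = pf, n = 150, seed = 3,
                        ages = list("age18"), alpha = list(age18 = 0.05),
                        B = 4, subsample = "none",
                        outdir = file.path(d, "all")), cfgf)
  # run_config validation
  cfg <- read_run_config(cfgf)
  expect_equal(cfg$B, 4L)
  expect_error(read_run_config(tempfile(fileext = ".yaml")), "not found")

  res <- run_pipeline(cfg)
  expect_true(file.exists(file.path(d, "all", "screen_age18.tsv")))
  expect_true(file.exists(file.path(d, "all", "bootstrap_age18.tsv")))
  expect_true(file.exists(file.path(d, "all", "manifest.json")))
  expect_true(file.exists(file.path(d, "all", "pipeline.log")))
  man <- jsonlite::fromJSON(file.path(d, "all", "manifest.json"))
  expect_equal(man$seed, 3)
  expect_equal(man$package, "th2screen")

  # repeated bootstrap subcommand runs are byte-identical
  simdir <- file.path(d, "cohort")
  th2_cli(c("simulate", "--panel", pf, "--n", "150", "--seed", "3",
            "--subsample", "none", "--out", simdir))
  expect_true(file.exists(file.path(simdir, "beta_age18.tsv")))
  b1 <- file.path(d, "b1"); b2 <- file.path(d, "b2")
  for (out in c(b1, b2))
    th2_cli(c("bootstrap", "--panel", pf, "--cohort", simdir, "--age", "age18",
              "--alpha", "0.05", "--B", "4", "--seed", "9", "--out", out))
  expect_identical(readLines(file.path(b1, "bootstrap_age18.tsv")),
                   readLines(file.path(b2, "bootstrap_age18.tsv")))
  expect_error(th2_cli(c("nonsense")), "unknown subcommand")
  expect_error(th2_cli(character()), "usage")
  unlink(c(d, pf, cfgf), recursive = TRUE)
})
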