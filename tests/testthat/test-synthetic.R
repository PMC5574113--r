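# Small configurations keep these checks fast; the cohort-scale behaviour
# is exercised in the acceptance suite.

test_that("simulated counts honor the configured structure", {
  cfg <- sim_config(n_genes = 300, n_tumor = 50, n_healthy = 80,
                    n_drivers = 10, beta = 4)
  sim <- simulate_counts(cfg, seed = 2)
  expect_equal(dim(sim$tumor$missense), c(50, 300))
  expect_equal(dim(sim$healthy$silent), c(80, 300))
  expect_equal(sum(sim$truth$driver), 10)
  expect_true(all(subset_counts(sim$tumor, "nonsilent") ==
                  sim$tumor$missense + sim$tumor$nonsense))
  # identical config + seed reproduces the draws exactly
  sim2 <- simulate_counts(cfg, seed = 2)
  expect_identical(sim$tumor, sim2$tumor)
  expect_identical(sim$healthy, sim2$healthy)
  expect_identical(sim$truth, sim2$truth)
})

test_that("a beta = 10 driver has ~10x the somatic rate of its germline rate", {
  cfg <- sim_config(n_genes = 300, n_tumor = 500, n_healthy = 500,
                    n_drivers = 20, beta = 10)
  sim <- simulate_counts(cfg, seed = 4)
  drivers <- sim$truth$gene[sim$truth$driver]
  mid <- drivers[sim$lambda[drivers] > 0.3]  # mid-range propensity
  tum <- subset_counts(sim$tumor, "nonsilent")[, mid, drop = FALSE]
  hea <- subset_counts(sim$healthy, "nonsilent")[, mid, drop = FALSE]
  pooled_ratio <- mean(colMeans(tum)) / mean(colMeans(hea))
  expect_gt(pooled_ratio, 8)
  expect_lt(pooled_ratio, 12)
})

test_that("without drivers tumor and healthy counts are exchangeable per gene", {
  cfg <- sim_config(n_genes = 200, n_tumor = 200, n_healthy = 200,
                    n_drivers = 0, exposure_sdlog = 0)
  sim <- simulate_counts(cfg, seed = 6)
  tum <- subset_counts(sim$tumor, "nonsilent")
  hea <- subset_counts(sim$healthy, "nonsilent")
  p <- vapply(seq_len(ncol(tum)), function(g)
    suppressWarnings(stats::ks.test(tum[, g], hea[, g]))$p.value,
    numeric(1))
  expect_gte(mean(p > 0.01), 0.95)
})

test_that("an empty tumor cohort yields a valid header-only MAF", {
  cfg <- sim_config(n_genes = 40, n_tumor = 0, n_healthy = 10,
                    n_drivers = 0)
  out <- simulate_cohorts(cfg, seed = 1, dir = tempfile())
  rec <- read_maf(out$maf)
  expect_equal(nrow(rec), 0)
})

test_that("truth evaluation scores a ranking against planted drivers", {
  truth <- data.frame(gene = paste0("g", 1:20),
                      driver = rep(c(TRUE, FALSE), c(4, 16)))
  res <- data.frame(gene = truth$gene,
                    uemd = c(10:7, runif(16)))  # drivers on top
  expect_equal(truth_eval(res, truth)$auprc, 1)
  expect_equal(unname(truth_eval(res, truth, ks = 4)$top_fraction), 1)
  # random scores give AUPRC near prevalence on average
  set.seed(10)
  reps <- replicate(50, {
    res$uemd <- runif(20)
    truth_eval(res, truth)$auprc
  })
  prev <- 4 / 20
  expect_lt(abs(mean(reps) - prev), 3 * stats::sd(reps))
})

test_that("multiple driver sets are disjoint and class-specific", {
  cfg <- sim_config(n_genes = 200, n_tumor = 100, n_healthy = 100,
                    driver_sets = list(
                      list(n = 8, beta = 6, classes = "missense"),
                      list(n = 8, beta = 6, classes = "nonsense")))
  sim <- simulate_counts(cfg, seed = 9)
  expect_equal(sum(sim$truth$driver), 16)
  expect_equal(sum(sim$truth$driver_set == 1, na.rm = TRUE), 8)
  set1 <- sim$truth$gene[!is.na(sim$truth$driver_set) & sim$truth$driver_set == 1]
  set2 <- sim$truth$gene[!is.na(sim$truth$driver_set) & sim$truth$driver_set == 2]
  expect_length(intersect(set1, set2), 0)
  # the boost lands only in the configured class: normalizing each gene's
  # tumor class mean by its lambda * mix exposes beta in the boosted class
  # and ~1 elsewhere
  mix <- cfg$mix
  norm_rate <- function(cl, genes)
    mean(colMeans(sim$tumor[[cl]][, genes, drop = FALSE]) /
           (sim$lambda[genes] * mix[[cl]]))
  expect_gt(norm_rate("missense", set1), 4)
  expect_lt(norm_rate("nonsense", set1), 2)
  expect_gt(norm_rate("nonsense", set2), 4)
  expect_lt(norm_rate("missense", set2), 2)
})
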