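test_that("simulated manifests are deterministic with forced compositions", {
  cfg <- simulation_config(n_samples = 10, n_probes = 10,
                           frac_sex_chrom = 0.2, seed = 9)
  m1 <- simulate_manifest(cfg)
  m2 <- simulate_manifest(cfg)
  expect_identical(m1$manifest, m2$manifest)
  expect_equal(sum(m1$manifest$sex_chromosome), 2)
  # positions sorted within chromosome
  bychr <- split(m1$manifest$position, m1$manifest$chromosome)
  expect_true(all(vapply(bychr, function(x) all(diff(x) >= 0),
                         logical(1))))
})

test_that("manifest categories round-trip through the annotation engine", {
  cfg <- simulation_config(n_samples = 10, n_probes = 1000, seed = 1)
  m <- simulate_manifest(cfg)
  rederived <- assign_functional_category(m$manifest$chromosome,
                                          m$manifest$position, m$models)
  expect_identical(m$manifest$category, rederived$category)
  expect_identical(m$manifest$gene, rederived$gene)
  # every probe gets exactly one category and counts sum to n_probes
  expect_true(all(m$manifest$category %in% functional_categories()))
  expect_equal(sum(table(m$manifest$category)), 1000)
})

test_that("methylation generation is seed-deterministic and zero-effect equivalent", {
  cfg <- simulation_config(n_samples = 30, n_probes = 150, seed = 5)
  man <- simulate_manifest(cfg)
  a <- simulate_methylation(cfg, man)
  b <- simulate_methylation(cfg, man)
  expect_identical(a$dataset$values, b$dataset$values)
  # effect_sd = 0 with causal probes reproduces the pure-null dataset
  cfg0 <- simulation_config(n_samples = 30, n_probes = 150, seed = 5,
                            frac_causal = 0)
  cfgz <- simulation_config(n_samples = 30, n_probes = 150, seed = 5,
                            effect_sd = 0)
  d0 <- simulate_methylation(cfg0, man)
  dz <- simulate_methylation(cfgz, man)
  expect_equal(d0$dataset$values, dz$dataset$values)
  expect_true(all(dz$truth$causal_slopes == 0))
})

test_that("GA respects truncation and the truth object is consistent", {
  cfg <- simulation_config(n_samples = 300, n_probes = 50, seed = 7)
  co <- simulate_cohort(cfg)
  ga <- co$dataset$samples$ga
  expect_true(all(ga >= 210 & ga <= 300))
  expect_equal(mean(ga), 274, tolerance = 0.02)
  expect_true(all(co$truth$causal_probe_ids %in%
                    co$dataset$manifest$probe_id))
  noncausal <- setdiff(co$dataset$manifest$probe_id,
                       co$truth$causal_probe_ids)
  expect_true(all(co$truth$causal_slopes[noncausal] == 0))
})

test_that("null cohort EWAS p-values are uniform", {
  cfg <- simulation_config(n_samples = 100, n_probes = 2000,
                           frac_causal = 0, n_latent = 0, seed = 21)
  co <- simulate_cohort(cfg)
  ew <- run_ewas(co$dataset)
  ks <- suppressWarnings(ks.test(ew$p[ew$ok], "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("strong-signal EWAS recovers causal slopes with correct signs", {
  cfg <- simulation_config(n_samples = 500, n_probes = 5000,
                           frac_causal = 0.05, effect_sd = 0.02, seed = 7)
  co <- simulate_cohort(cfg)
  ew <- run_ewas(co$dataset)
  hits <- ew$probe_id[ew$q < 0.05 & ew$ok]
  true_hits <- intersect(hits, co$truth$causal_probe_ids)
  sign_agree <- mean(sign(ew$estimate[match(true_hits, ew$probe_id)]) ==
                       sign(co$truth$causal_slopes[true_hits]))
  expect_gt(sign_agree, 0.9)
  expect_gt(length(true_hits) / length(co$truth$causal_probe_ids), 0.8)
})

test_that("exposure tables are deterministic and planted effects recoverable", {
  cfg <- simulation_config(n_samples = 500, n_probes = 10, seed = 3,
                           exposure_effects = c(
                             delivery_planned_csection = -4.4))
  man <- simulate_manifest(cfg)
  sim <- simulate_methylation(cfg, man)
  e1 <- simulate_exposures(cfg, sim$truth$ga, sim$truth)
  e2 <- simulate_exposures(cfg, sim$truth$ga, sim$truth)
  expect_identical(e1, e2)
  fit <- fit_exposure_model(sim$truth$ga, e1$delivery,
                            exposure_name = "delivery",
                            reference = "vaginal")
  row <- fit[fit$level == "planned_csection", ]
  se <- (row$ci_high - row$ci_low) / (2 * qt(0.975, row$n - 3))
  expect_lt(abs(row$coefficient - (-4.4)), 2 * se)
})

test_that("null exposures are unassociated with GA over replicates", {
  ps <- vapply(1:20, function(s) {
    cfg <- simulation_config(n_samples = 150, n_probes = 10, seed = s)
    man <- simulate_manifest(cfg)
    sim <- simulate_methylation(cfg, man)
    e <- simulate_exposures(cfg, sim$truth$ga, sim$truth)
    fit_exposure_model(sim$truth$ga, e$married, "married")$f_p
  }, numeric(1))
  # p-values should look uniform: no pile-up near 0
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})
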