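test_that("Stouffer-Liptak combination matches closed forms", {
  expect_equal(stouffer_liptak(0.37), 0.37)
  expect_equal(as.numeric(stouffer_liptak(c(0.5, 0.5), diag(2))), 0.5)
  expect_equal(as.numeric(stouffer_liptak(c(0.05, 0.05), diag(2))),
               1 - pnorm(2 * qnorm(0.95) / sqrt(2)), tolerance = 1e-12)
  expect_equal(as.numeric(stouffer_liptak(c(0.05, 0.05),
                                          matrix(1, 2, 2))), 0.05,
               tolerance = 1e-12)
  expect_error(stouffer_liptak(numeric(0)), "no p-values")
  # non-PD sigma is repaired and flagged
  sig <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3)
  out <- stouffer_liptak(c(0.1, 0.2, 0.3), sig)
  expect_true(attr(out, "repaired"))
  expect_true(out >= 0 && out <= 1)
})

test_that("Stouffer-Liptak is monotone in each input p", {
  set.seed(8)
  for (i in 1:50) {
    k <- sample(2:6, 1)
    A <- matrix(rnorm(k * k), k)
    sig <- cov2cor(crossprod(A) + diag(k))
    p <- runif(k)
    j <- sample(k, 1)
    p2 <- p
    p2[j] <- p[j] * runif(1)
    expect_lte(as.numeric(stouffer_liptak(p2, sig)),
               as.numeric(stouffer_liptak(p, sig)) + 1e-12)
  }
})

test_that("distance-binned ACF is near zero for iid p and one for duplicated probes", {
  set.seed(31)
  # dense uniform layout: ~1000 pairs per 50 bp bin, so each bin's
  # Monte-Carlo error is ~0.03
  pos <- sort(round(runif(2000, 1, 2e5)))
  p <- runif(2000)
  acf <- estimate_acf(p, rep("chr1", 2000), pos)
  est <- acf$correlation[-1][acf$n_pairs[-1] >= 10]
  expect_true(all(abs(est) < 0.1))
  expect_equal(acf$correlation[1], 1)
  # duplicated probes at +1 bp with identical p force first-bin r = 1
  # (originals spaced 5 kb apart so only duplicate pairs land in the bin)
  chrom2 <- rep("chr1", 400)
  pos2 <- seq(1, by = 5000, length.out = 200)
  pos2 <- as.vector(rbind(pos2, pos2 + 1))
  p2 <- rep(runif(200), each = 2)
  acf2 <- estimate_acf(p2, chrom2, pos2)
  expect_equal(acf2$correlation[2], 1, tolerance = 0.02)
  expect_error(estimate_acf(p2, chrom2, pos2, max_dist = 0), "positive")
})

test_that("neighborhood correction strengthens concordant evidence and matches a brute-force oracle", {
  acf0 <- estimate_acf(runif(2), c("chr1", "chr1"), c(1, 5000))  # ~null acf
  # isolated probe: p unchanged
  adj <- adjust_site_pvalues(c(0.42), "chr1", 100, acf0)
  expect_equal(adj, 0.42)
  # three clustered concordant probes: middle p drops below 0.01
  adj3 <- adjust_site_pvalues(rep(0.01, 3), rep("chr1", 3),
                              c(100, 200, 300), acf0)
  expect_lt(adj3[2], 0.01)
  # six-probe toy vs direct per-site combination
  set.seed(5)
  pos <- c(100, 300, 900, 5000, 5400, 9000)
  p <- c(0.001, 0.2, 0.03, 0.5, 0.04, 0.9)
  chrom <- rep("chr1", 6)
  acf <- estimate_acf(runif(50), rep("chr1", 50),
                      sort(round(runif(50, 1, 2e4))))
  adj6 <- adjust_site_pvalues(p, chrom, pos, acf, window = 1000)
  for (i in 1:6) {
    nb <- which(abs(pos - pos[i]) <= 1000)
    dd <- abs(outer(pos[nb], pos[nb], `-`))
    sig <- matrix(gaclock:::acf_correlation(acf, as.vector(dd)),
                  length(nb))
    diag(sig) <- 1
    expect_equal(adj6[i], as.numeric(stouffer_liptak(p[nb], sig)),
                 tolerance = 1e-12)
  }
})

test_that("region finding honours seeds, gaps and the two-probe minimum", {
  # no probe below the threshold -> empty
  expect_equal(nrow(find_regions(rep(0.5, 4), rep("chr1", 4),
                                 c(1, 50, 100, 150))), 0)
  r <- find_regions(c(0.001, 0.001, 0.001), rep("chr1", 3),
                    c(100, 200, 300), seed_p = 0.05, max_gap = 500)
  expect_equal(nrow(r), 1)
  expect_equal(r$n_probes, 3)
  expect_equal(c(r$start, r$end), c(100, 300))
  # a broken middle probe leaves two singletons, which are dropped
  r2 <- find_regions(c(0.001, 0.9, 0.001), rep("chr1", 3),
                     c(100, 200, 300), seed_p = 0.05, max_gap = 500)
  expect_equal(nrow(r2), 0)
  # gap rule splits runs
  r3 <- find_regions(rep(0.001, 4), rep("chr1", 4),
                     c(100, 200, 5000, 5100), seed_p = 0.05,
                     max_gap = 1000)
  expect_equal(nrow(r3), 2)
})

test_that("Sidak correction matches its closed form", {
  expect_equal(region_pvalue_sidak(0.3, 1000, 1000), 0.3)
  expect_equal(region_pvalue_sidak(0, 500, 1e6), 0)
  expect_equal(region_pvalue_sidak(0.001, 500, 1e6),
               1 - 0.999^2000, tolerance = 1e-12)
  expect_equal(region_pvalue_sidak(0.5, 100, 1e9), 1)
})

test_that("total searched span merges overlapping probe windows", {
  # two isolated probes and one overlapping pair
  span <- total_probe_span(rep("chr1", 3), c(5000, 5500, 20000),
                           window = 1000)
  expect_equal(span, (6500 - 4000 + 1) + 2001)
})

test_that("planted clusters are recovered and null data yields no regions", {
  rec <- logical(3); nullreg <- integer(3)
  for (s in 1:3) {
    cfg <- simulation_config(n_samples = 300, n_probes = 2000,
                             n_latent = 0, frac_causal = 0, seed = s)
    co <- simulate_cohort(cfg)
    ewn <- run_ewas(co$dataset)
    regn <- call_dmrs(ewn, co$dataset$manifest)
    nullreg[s] <- sum(regn$q < 0.05)
    pl <- plant_cluster(co$dataset)
    ew <- run_ewas(pl$dataset)
    reg <- call_dmrs(ew, pl$dataset$manifest)
    rec[s] <- region_hits_planted(reg, pl$planted_ids)
  }
  expect_true(all(rec))
  expect_true(all(nullreg == 0))
})
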