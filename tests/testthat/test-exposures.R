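test_that("binary exposure models reduce to group-mean differences with F = t^2", {
  set.seed(21)
  x <- rep(c("no", "yes"), c(40, 35))
  y <- 270 + 4 * (x == "yes") + rnorm(75, sd = 6)
  fit <- fit_exposure_model(y, x, "expo", reference = "no")
  expect_equal(fit$coefficient,
               mean(y[x == "yes"]) - mean(y[x == "no"]),
               tolerance = 1e-10)
  tt <- t.test(y[x == "yes"], y[x == "no"], var.equal = TRUE)
  expect_equal(fit$f_p, tt$p.value, tolerance = 1e-10)
  expect_equal(unname((fit$coefficient /
                         ((fit$ci_high - fit$ci_low) /
                            (2 * qt(0.975, 73))))^2),
               unname(tt$statistic^2), tolerance = 1e-8)
})

test_that("a small categorical fixture matches the matrix-algebra oracle", {
  y <- c(270, 272, 268, 281, 283, 262, 261, 265)
  x <- c("a", "a", "a", "b", "b", "c", "c", "c")
  fit <- fit_exposure_model(y, x, "grp", reference = "a")
  X <- cbind(1, b = as.numeric(x == "b"), c = as.numeric(x == "c"))
  beta <- solve(crossprod(X), crossprod(X, y))
  resid <- y - X %*% beta
  s2 <- sum(resid^2) / 5
  se <- sqrt(s2 * diag(solve(crossprod(X))))
  expect_equal(fit$coefficient, beta[2:3, 1], tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(fit$ci_low, beta[2:3, 1] - qt(0.975, 5) * se[2:3],
               tolerance = 1e-10, ignore_attr = TRUE)
  # F against intercept-only from RSS
  rss0 <- sum((y - mean(y))^2)
  fstat <- ((rss0 - sum(resid^2)) / 2) / s2
  expect_equal(fit$f_p[1], pf(fstat, 2, 5, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_error(fit_exposure_model(y, rep("a", 8)), "constant")
})

test_that("null exposures keep the F-test calibrated", {
  set.seed(31)
  ps <- replicate(400, {
    fit_exposure_model(rnorm(60), rnorm(60))$f_p
  })
  expect_lt(abs(mean(ps < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / 400))
})

test_that("the exposure scan computes per-outcome FDR and rejects degenerate outcomes", {
  cfg <- simulation_config(n_samples = 300, n_probes = 10, seed = 17,
                           exposure_effects = c(
                             delivery_planned_csection = -4.4))
  man <- simulate_manifest(cfg)
  sim <- simulate_methylation(cfg, man)
  expo <- simulate_exposures(cfg, sim$truth$ga, sim$truth)
  out <- run_all_exposures(data.frame(ga = sim$truth$ga), expo,
                           references = list(delivery = "vaginal"))
  expect_true(all(out$q >= out$f_p - 1e-12))
  expect_equal(sort(unique(out$outcome)), "ga")
  # q is shared across levels of the same exposure
  dd <- out[out$exposure == "delivery", ]
  expect_equal(length(unique(dd$q)), 1)
  expect_error(run_all_exposures(data.frame(egaa = rep(0, 300)), expo),
               "zero variance")
})

test_that("backward AIC selection retains strong predictors and matches the RSS oracle", {
  set.seed(41)
  n <- 300
  expos <- data.frame(strong = rnorm(n),
                      matrix(rnorm(n * 10), n,
                             dimnames = list(NULL, paste0("noise", 1:10))))
  y <- 274 + 5 * expos$strong + rnorm(n, sd = 1)
  sel <- backward_select_aic(y, expos)
  expect_true("strong" %in% sel$retained_exposures)
  # AIC trace non-increasing and every step matches n*log(RSS/n) + 2k
  expect_true(all(diff(sel$aic_trace$aic) <= 1e-12))
  for (i in seq_len(nrow(sel$aic_trace))) {
    dropped_so_far <- sel$aic_trace$dropped[seq_len(i)]
    keep <- setdiff(names(expos), dropped_so_far)
    f <- if (length(keep)) reformulate(keep, "y") else y ~ 1
    fit <- lm(f, data = cbind(y = y, expos))
    aic_oracle <- n * log(sum(residuals(fit)^2) / n) + 2 * fit$rank
    expect_equal(sel$aic_trace$aic[i], aic_oracle, tolerance = 1e-8)
  }
  # final model AIC never exceeds the full model's
  expect_lte(sel$aic_trace$aic[nrow(sel$aic_trace)],
             sel$aic_trace$aic[1])
})

test_that("selection agrees with stats::step on a mixed-type fixture", {
  set.seed(43)
  n <- 200
  dat <- data.frame(contin = rnorm(n),
                    cat3 = sample(c("x", "y", "z"), n, replace = TRUE),
                    junk1 = rnorm(n), junk2 = rnorm(n))
  y <- 274 + 2 * dat$contin + 3 * (dat$cat3 == "z") + rnorm(n)
  sel <- backward_select_aic(y, dat)
  ref <- step(lm(y ~ contin + cat3 + junk1 + junk2,
                 data = cbind(y = y, dat)), trace = 0,
              direction = "backward")
  ref_terms <- attr(terms(ref), "term.labels")
  expect_setequal(sel$retained_exposures, ref_terms)
  expect_equal(sel$r2, summary(ref)$r.squared, tolerance = 1e-10)
})

test_that("single- and multi-exposure estimates agree for independent exposures", {
  set.seed(47)
  n <- 400
  expos <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  y <- 274 + 2 * expos$a + rnorm(n, sd = 3)
  single <- fit_exposure_model(y, expos$a, "a")
  full <- lm(y ~ a + b + c, data = cbind(y = y, expos))
  se <- (single$ci_high - single$ci_low) / (2 * qt(0.975, n - 2))
  expect_lt(abs(single$coefficient - coef(full)["a"]), 2 * se)
})
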