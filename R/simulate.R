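#' Simulation configuration for synthetic methylation cohorts
#'
#' Describes a cord-blood-like array cohort: gestational age (GA) drawn from
#' a truncated normal, a sparse set of GA-associated CpGs with slopes on the
#' M scale, latent factors optionally correlated with GA (confounding), and
#' array nuisance structure (sex-chromosome probes, SNP flags, detection
#' failures). Defaults follow the cohort shape the pipeline is designed for:
#' n = 391 newborns, GA ~ Normal(274.02, 11.02) days truncated to
#' (210, 300), and an array-scale probe count scaled to desk size.
#'
#' @param n_samples Number of samples (>= 10).
#' @param n_probes Number of probes.
#' @param frac_causal Fraction of probes with a nonzero GA slope.
#' @param effect_sd SD of causal slopes, M-units per day.
#' @param n_latent Number of latent factors.
#' @param confounding_strength Correlation between each latent factor and GA.
#' @param latent_loading_sd SD of per-probe latent loadings (M-units).
#' @param ga_mean,ga_sd GA distribution, days.
#' @param ga_range Truncation bounds (min, max) in days; must contain
#'   `ga_mean`.
#' @param noise_sd_range Per-probe residual SD bounds (M-units); probe SDs
#'   are drawn uniformly in this range.
#' @param frac_sex_chrom Fraction of probes placed on sex chromosomes.
#' @param frac_snp_flagged Fraction of probes carrying a 3'/5' SNP flag.
#' @param detection_fail_rate Fraction of (probe, sample) pairs with
#'   detection p > 0.05.
#' @param n_genes Number of synthetic gene models.
#' @param exposure_effects Named numeric vector of GA shifts in days for
#'   exposures generated by [simulate_exposures()] (e.g.
#'   `c(delivery_planned_csection = -4.4)`); empty = all exposures null.
#' @param seed Integer seed; fully determines all outputs.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_samples = 391, n_probes = 5000,
                              frac_causal = 0.05, effect_sd = 0.02,
                              n_latent = 2, confounding_strength = 0,
                              latent_loading_sd = 0.1,
                              ga_mean = 274.02, ga_sd = 11.02,
                              ga_range = c(210, 300),
                              noise_sd_range = c(0.15, 0.45),
                              frac_sex_chrom = 0.05,
                              frac_snp_flagged = 0.02,
                              detection_fail_rate = 5e-5,
                              n_genes = 500,
                              exposure_effects = numeric(0),
                              seed = 1L) {
  fracs <- c(frac_causal, frac_sex_chrom, frac_snp_flagged,
             detection_fail_rate)
  stopifnot(all(fracs >= 0 & fracs <= 1),
            n_samples >= 10, n_probes >= 1,
            abs(confounding_strength) <= 1,
            ga_range[1] <= ga_mean, ga_mean <= ga_range[2],
            noise_sd_range[1] > 0, noise_sd_range[1] <= noise_sd_range[2],
            effect_sd >= 0, n_latent >= 0, n_genes >= 1)
  structure(as.list(environment()), class = "simulation_config")
}

# deterministic sub-stream seed so optional components never shift the RNG
# state of later ones (e.g. effect_sd = 0 must reproduce frac_causal = 0)
.sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + 104729 * k) %% 2147483647)
}

.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Simulate gene models
#'
#' Generates `n_genes` multi-exon gene models spread over the autosomes (and
#' chrX), with 2-6 exons, short UTRs at each end, and random strand.
#'
#' @param n_genes Number of genes.
#' @param chromosomes Chromosome names to place genes on.
#' @param chrom_len Chromosome length in bp.
#' @param seed Integer seed.
#' @return A [gene_models()] table.
#' @export
simulate_gene_models <- function(n_genes, chromosomes =
                                   c(paste0("chr", 1:22), "chrX"),
                                 chrom_len = 1e7, seed = 1L) {
  .with_seed(seed, {
    chr <- sort(sample(chromosomes, n_genes, replace = TRUE))
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    start <- round(stats::runif(n_genes, 1e4, chrom_len - 1e5))
    rows <- vector("list", n_genes)
    for (i in seq_len(n_genes)) {
      k <- sample(2:6, 1)
      exon_len <- round(stats::runif(k, 100, 400))
      intron_len <- round(stats::runif(k - 1, 800, 5000))
      s <- start[i] + c(0, cumsum(exon_len[-k] + intron_len))
      e <- s + exon_len - 1
      # s/e are left->right; orient 5'->3' by strand
      if (strand[i] == "+") {
        tss <- s[1]; tes <- e[k]; es <- s; ee <- e
      } else {
        tss <- e[k]; tes <- s[1]; es <- rev(s); ee <- rev(e)
      }
      u5 <- round(stats::runif(1, 40, 120))
      u3 <- round(stats::runif(1, 40, 120))
      if (strand[i] == "+") {
        utr5 <- c(es[1], min(es[1] + u5, ee[1]))
        utr3 <- c(max(ee[k] - u3, es[k]), ee[k])
      } else {
        utr5 <- c(max(ee[1] - u5, es[1]), ee[1])
        utr3 <- c(es[k], min(es[k] + u3, ee[k]))
      }
      rows[[i]] <- data.frame(
        gene = sprintf("GENE%04d", i), chromosome = chr[i],
        strand = strand[i], tss = tss, tes = tes,
        exon_starts = I(list(es)), exon_ends = I(list(ee)),
        utr5_start = utr5[1], utr5_end = utr5[2],
        utr3_start = utr3[1], utr3_end = utr3[2])
    }
    gene_models(do.call(rbind, rows))
  })
}

#' Simulate a probe manifest
#'
#' Places probes in small clusters (so nearby-probe structure exists for
#' regional analyses), 70% of clusters anchored near gene TSSs, with the
#' configured fractions on sex chromosomes and SNP-flagged. Gene and
#' functional-category columns are filled with [annotate_probes()] against
#' the simulated gene models, so manifest annotation is by construction
#' consistent with [assign_functional_category()].
#'
#' @param config A [simulation_config()].
#' @return A list with `manifest` (data.frame: `probe_id`, `chromosome`,
#'   `position`, `snp_3p_flag`, `snp_5p_flag`, `sex_chromosome`,
#'   `off_target`, `detection_fail_fraction`, `gene`, `category`,
#'   `tss_distance`) and `models` (the [gene_models()] used).
#' @export
simulate_manifest <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  models <- simulate_gene_models(config$n_genes,
                                 seed = .sub_seed(config$seed, 1))
  .with_seed(.sub_seed(config$seed, 2), {
    np <- config$n_probes
    n_sex <- round(config$frac_sex_chrom * np)
    n_auto <- np - n_sex
    chrom_len <- 1e7
    cluster_size <- 5
    place <- function(n, chroms, mods) {
      if (n == 0)
        return(data.frame(chromosome = character(), position = numeric()))
      n_clusters <- max(1, ceiling(n / cluster_size))
      anchored <- stats::runif(n_clusters) < 0.7 & nrow(mods) > 0
      gi <- if (nrow(mods) > 0) sample(nrow(mods), n_clusters,
                                       replace = TRUE)
            else rep(NA_integer_, n_clusters)
      centers_chr <- ifelse(anchored, mods$chromosome[gi],
                            sample(chroms, n_clusters, replace = TRUE))
      centers_pos <- ifelse(anchored,
                            mods$tss[gi] + round(stats::runif(n_clusters,
                                                              -3000, 3000)),
                            round(stats::runif(n_clusters, 1e4, chrom_len)))
      ci <- sample(rep(seq_len(n_clusters), length.out = n))
      pos <- pmax(1, centers_pos[ci] + round(stats::runif(n, 0, 2000)))
      data.frame(chromosome = centers_chr[ci], position = pos)
    }
    autos <- paste0("chr", 1:22)
    auto_models <- models[models$chromosome %in% autos, , drop = FALSE]
    sex_models <- models[models$chromosome == "chrX", , drop = FALSE]
    pa <- place(n_auto, autos, auto_models)
    pa$sex_chromosome <- rep(FALSE, nrow(pa))
    px <- place(n_sex, c("chrX", "chrY"), sex_models)
    px$sex_chromosome <- rep(TRUE, nrow(px))
    df <- rbind(pa, px)
    df <- df[order(match(df$chromosome, c(autos, "chrX", "chrY")),
                   df$position), ]
    rownames(df) <- NULL
    df$probe_id <- sprintf("cg%06d", seq_len(np))
    n_snp <- round(config$frac_snp_flagged * np)
    snp_idx <- sample(np, n_snp)
    df$snp_3p_flag <- FALSE
    df$snp_5p_flag <- FALSE
    if (n_snp > 0) {
      side <- stats::runif(n_snp) < 0.5
      df$snp_3p_flag[snp_idx[side]] <- TRUE
      df$snp_5p_flag[snp_idx[!side]] <- TRUE
    }
    df$off_target <- FALSE
    df$detection_fail_fraction <- 0
    df <- df[, c("probe_id", "chromosome", "position", "snp_3p_flag",
                 "snp_5p_flag", "sex_chromosome", "off_target",
                 "detection_fail_fraction")]
    df <- annotate_probes(df, models)
    list(manifest = df, models = models)
  })
}

# truncated normal draw via inverse-CDF (deterministic in the uniform draws)
.rtruncnorm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Simulate a methylation dataset with known truth
#'
#' Generative model per probe j, sample i (on the M scale):
#' `M_ij = baseline_j + slope_j * (GA_i - ga_mean) + loadings_j . latent_i +
#' sex/race terms (designated probe subsets) + Normal(0, sd_j)`.
#' GA is truncated-normal; each latent factor is drawn jointly Gaussian with
#' standardized GA at correlation `confounding_strength`. Baselines are
#' chosen so beta values mostly fall in (0.05, 0.95). Detection p-values
#' exceed 0.05 for `detection_fail_rate` of (probe, sample) pairs.
#'
#' @param config A [simulation_config()].
#' @param manifest Manifest list from [simulate_manifest()] (or its
#'   `$manifest` data.frame).
#' @return A list with `dataset` (an M-scale [methylation_dataset()]) and
#'   `truth` (class `synthetic_truth`: `causal_probe_ids`, `causal_slopes`
#'   (full named vector, 0 for non-causal), `latent_scores`,
#'   `latent_loadings`, `ga`, `exposure_effects`).
#' @export
simulate_methylation <- function(config, manifest) {
  stopifnot(inherits(config, "simulation_config"))
  man <- if (is.data.frame(manifest)) manifest else manifest$manifest
  np <- nrow(man)
  n <- config$n_samples
  K <- config$n_latent
  sample_ids <- sprintf("S%04d", seq_len(n))

  ga <- .with_seed(.sub_seed(config$seed, 3),
                   .rtruncnorm(n, config$ga_mean, config$ga_sd,
                               config$ga_range[1], config$ga_range[2]))
  ga_c <- ga - config$ga_mean
  ga_std <- as.numeric(scale(ga))

  latent <- .with_seed(.sub_seed(config$seed, 4), {
    if (K == 0) matrix(0, n, 0) else {
      rho <- config$confounding_strength
      z <- matrix(stats::rnorm(n * K), n, K)
      rho * ga_std + sqrt(1 - rho^2) * z
    }
  })
  loadings <- .with_seed(.sub_seed(config$seed, 5), {
    if (K == 0) matrix(0, np, 0) else
      matrix(stats::rnorm(np * K, 0, config$latent_loading_sd), np, K)
  })

  n_causal <- round(config$frac_causal * np)
  slopes <- stats::setNames(numeric(np), man$probe_id)
  causal <- .with_seed(.sub_seed(config$seed, 6), {
    if (n_causal > 0) {
      idx <- sample(np, n_causal)
      list(idx = idx, slopes = stats::rnorm(n_causal, 0, config$effect_sd))
    } else list(idx = integer(0), slopes = numeric(0))
  })
  slopes[causal$idx] <- causal$slopes
  causal_ids <- man$probe_id[sort(causal$idx)]

  baseline <- .with_seed(.sub_seed(config$seed, 7),
                         beta_to_m(stats::runif(np, 0.1, 0.9)))
  noise_sd <- .with_seed(.sub_seed(config$seed, 8),
                         stats::runif(np, config$noise_sd_range[1],
                                      config$noise_sd_range[2]))

  # designated probe subsets with sex / race effects (nuisance covariates)
  demo <- .with_seed(.sub_seed(config$seed, 9), {
    sex <- sample(c("male", "female"), n, replace = TRUE,
                  prob = c(0.51, 0.49))
    race <- sample(c("AfricanAmerican", "EuropeanAmerican", "Other"), n,
                   replace = TRUE, prob = c(0.62, 0.24, 0.14))
    sex_idx <- sample(np, round(0.02 * np))
    race_idx <- sample(np, round(0.02 * np))
    sex_eff <- stats::setNames(stats::rnorm(length(sex_idx), 0, 0.3),
                               man$probe_id[sex_idx])
    race_eff <- stats::setNames(stats::rnorm(length(race_idx), 0, 0.2),
                                man$probe_id[race_idx])
    list(sex = sex, race = race, sex_eff = sex_eff, race_eff = race_eff)
  })

  M <- matrix(baseline, np, n) + outer(slopes, ga_c) +
    loadings %*% t(latent)
  sex_ind <- as.numeric(demo$sex == "female")
  race_ind <- as.numeric(demo$race != "AfricanAmerican")
  if (length(demo$sex_eff))
    M[match(names(demo$sex_eff), man$probe_id), ] <-
      M[match(names(demo$sex_eff), man$probe_id), ] +
      outer(demo$sex_eff, sex_ind)
  if (length(demo$race_eff))
    M[match(names(demo$race_eff), man$probe_id), ] <-
      M[match(names(demo$race_eff), man$probe_id), ] +
      outer(demo$race_eff, race_ind)
  M <- M + .with_seed(.sub_seed(config$seed, 10),
                      matrix(stats::rnorm(np * n, 0, noise_sd), np, n))
  dimnames(M) <- list(man$probe_id, sample_ids)

  detp <- .with_seed(.sub_seed(config$seed, 11), {
    fail <- matrix(stats::runif(np * n) < config$detection_fail_rate, np, n)
    d <- matrix(stats::runif(np * n, 0, 1e-3), np, n)
    d[fail] <- stats::runif(sum(fail), 0.05 + 1e-9, 1)
    dimnames(d) <- dimnames(M)
    d
  })
  man$detection_fail_fraction <- detection_fail_fraction(detp, 0.05)

  samples <- data.frame(sample_id = sample_ids, ga = ga, sex = demo$sex,
                        race = demo$race, stringsAsFactors = FALSE)
  ds <- methylation_dataset(M, "M", man, samples, detection_p = detp)
  truth <- structure(
    list(causal_probe_ids = causal_ids, causal_slopes = slopes,
         latent_scores = latent, latent_loadings = loadings, ga = ga,
         exposure_effects = config$exposure_effects),
    class = "synthetic_truth")
  list(dataset = ds, truth = truth)
}

# tilt a category probability with GA so the regression slope of
# GA ~ indicator equals `effect` days in expectation
.tilt_prob <- function(base_p, ga, effect) {
  k <- effect * base_p * (1 - base_p) / stats::var(ga)
  pmin(pmax(base_p + k * (ga - mean(ga)), 0.001), 0.999)
}

#' Simulate a prenatal/perinatal exposure sheet
#'
#' Emits 22 exposures mixing continuous, binary, and categorical variables
#' with cohort-realistic marginals (maternal/paternal age, BMI, birth-weight
#' z-score, parity, marital status, household income, education, delivery
#' mode, smoking, pets, ...). Exposures named in `truth$exposure_effects`
#' are drawn conditionally on GA so that a univariate regression of GA on
#' the exposure recovers the stated day-shift in expectation; all other
#' exposures are independent of GA. Binary/categorical effects are named
#' either by the exposure (binary) or `exposure_level` (e.g.
#' `delivery_planned_csection`).
#'
#' @param config A [simulation_config()].
#' @param ga Numeric vector of GA in days (length `n_samples`).
#' @param truth Optional `synthetic_truth` carrying `exposure_effects`;
#'   defaults to `config$exposure_effects`.
#' @return data.frame of exposures, one row per sample, first column
#'   `sample_id`.
#' @export
simulate_exposures <- function(config, ga, truth = NULL) {
  stopifnot(length(ga) == config$n_samples)
  effects <- if (!is.null(truth)) truth$exposure_effects else
    config$exposure_effects
  n <- length(ga)
  .with_seed(.sub_seed(config$seed, 12), {
    rbern <- function(nm, p) {
      pv <- if (nm %in% names(effects)) .tilt_prob(p, ga, effects[[nm]])
      else rep(p, n)
      stats::runif(n) < pv
    }
    rcat <- function(nm, levels, probs) {
      pm <- matrix(probs, n, length(levels), byrow = TRUE)
      for (j in seq_along(levels)) {
        key <- paste0(nm, "_", levels[j])
        if (key %in% names(effects)) {
          pj <- .tilt_prob(probs[j], ga, effects[[key]])
          # renormalize the other levels proportionally
          rest <- 1 - pm[, j]
          pm[, -j] <- pm[, -j] * (1 - pj) / rest
          pm[, j] <- pj
        }
      }
      levels[max.col(log(pm) + matrix(-log(-log(stats::runif(n *
        length(levels)))), n, length(levels)))]  # Gumbel-max draw
    }
    df <- data.frame(
      sample_id = sprintf("S%04d", seq_len(n)),
      maternal_age = round(stats::rnorm(n, 30.0, 5.3), 1),
      paternal_age = round(stats::rnorm(n, 32.6, 6.9), 1),
      bmi_first = round(stats::rnorm(n, 30.5, 8.4), 1),
      bmi_last = round(stats::rnorm(n, 35.0, 7.9), 1),
      birth_weight_z = round(stats::rnorm(n, 0, 0.98), 2),
      parity = stats::rpois(n, 1.1),
      married = rbern("married", 0.67),
      urban = rbern("urban", 0.57),
      income = rcat("income", c("lt20k", "20to40k", "40to80k", "80to100k",
                                "gt100k", "refused"),
                    c(0.13, 0.21, 0.27, 0.13, 0.14, 0.12)),
      education = rcat("education", c("lt_hs", "hs", "some_college",
                                      "bachelor"),
                       c(0.04, 0.14, 0.47, 0.35)),
      delivery = rcat("delivery", c("vaginal", "planned_csection",
                                    "unplanned_csection"),
                      c(0.64, 0.19, 0.17)),
      first_born = rbern("first_born", 0.35),
      prev_births = rcat("prev_births", c("0", "1", "2", "3", "4plus"),
                         c(0.23, 0.23, 0.25, 0.14, 0.15)),
      female = rbern("female", 0.49),
      antibiotic_use = rbern("antibiotic_use", 0.55),
      antifungal_use = rbern("antifungal_use", 0.18),
      ets = rbern("ets", 0.25),
      smoking = rbern("smoking", 0.11),
      indoor_pets = rbern("indoor_pets", 0.37),
      outdoor_pets = rbern("outdoor_pets", 0.04),
      born_season = rcat("born_season", c("winter", "spring", "summer",
                                          "fall"),
                         c(0.21, 0.22, 0.28, 0.29)),
      mom_race = rcat("mom_race", c("AfricanAmerican", "EuropeanAmerican",
                                    "Other"), c(0.61, 0.24, 0.15)),
      infant_race = rcat("infant_race", c("AfricanAmerican",
                                          "EuropeanAmerican", "Other"),
                         c(0.62, 0.24, 0.14)),
      stringsAsFactors = FALSE)
    df
  })
}

#' Simulate a complete cohort
#'
#' Convenience wrapper: [simulate_manifest()], [simulate_methylation()],
#' [simulate_exposures()], with exposures merged into the dataset's sample
#' metadata.
#'
#' @param config A [simulation_config()].
#' @return list with `dataset`, `truth`, `models`, `exposures`.
#' @export
simulate_cohort <- function(config) {
  man <- simulate_manifest(config)
  sim <- simulate_methylation(config, man)
  expo <- simulate_exposures(config, sim$truth$ga, sim$truth)
  stopifnot(identical(expo$sample_id, sim$dataset$samples$sample_id))
  sim$dataset$samples <- cbind(sim$dataset$samples,
                               expo[, -1, drop = FALSE])
  list(dataset = sim$dataset, truth = sim$truth, models = man$models,
       exposures = expo)
}
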