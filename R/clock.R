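#' Deterministic train/test split
#'
#' The test set holds `floor(n * (1 - train_frac))` samples (for 391
#' samples at 0.8 this gives 313 training / 78 test), drawn uniformly at
#' random under the seed.
#'
#' @param sample_ids Character vector of sample ids.
#' @param train_frac Training fraction in (0, 1).
#' @param seed Integer seed.
#' @return List with `train` and `test` id vectors (disjoint, exhaustive).
#' @export
split_train_test <- function(sample_ids, train_frac = 0.8, seed = 1L) {
  n <- length(sample_ids)
  if (train_frac <= 0 || train_frac >= 1)
    stop("train_frac must be in (0, 1)")
  n_test <- floor(n * (1 - train_frac))
  if (n_test < 1) stop("test set would be empty")
  test <- .with_seed(seed, sample(sort(sample_ids), n_test))
  list(train = setdiff(sample_ids, test), test = test)
}

#' Select clock features from a training-set EWAS
#'
#' Probes below the FDR threshold in an EWAS computed on training samples
#' only (no test-set leakage). A threshold of 1 (or more) returns every
#' tested probe.
#'
#' @param ewas An `EWASResult` computed on the training samples.
#' @param q_threshold FDR threshold (default 0.05).
#' @return Character vector of probe ids (possibly empty).
#' @export
select_features <- function(ewas, q_threshold = 0.05) {
  ok <- ewas$ok & !is.na(ewas$q)
  sel <- if (q_threshold >= 1) ok else ok & ewas$q < q_threshold
  ewas$probe_id[sel]
}

#' Elastic-net fit with unpenalized covariates
#'
#' Minimizes `(1/2n) ||y - X b - Z g||^2 + lambda (alpha ||b||_1 +
#' (1-alpha)/2 ||b||_2^2)` with the covariate coefficients `g` unpenalized
#' (penalty factor 0). CpG columns are standardized internally by
#' \pkg{glmnet}; coefficients are returned on the original scale. When
#' `lambda` is `NULL` it is chosen by internal k-fold cross-validation
#' minimizing mean squared error over a 100-point log grid (deterministic
#' fold assignment under the seed).
#'
#' @param X_penalized Samples x CpGs matrix (the penalized block).
#' @param X_unpenalized Optional samples x covariates matrix (unpenalized).
#' @param y GA in days.
#' @param alpha Elastic-net mixing in \[0, 1\] (default 0.5).
#' @param lambda Optional fixed penalty (a scalar); `NULL` = CV choice.
#' @param cv_folds Internal CV folds (default 5).
#' @param seed Integer seed for fold assignment.
#' @return Object of class `ClockModel`: `probe_ids` and `weights` (nonzero
#'   CpG terms only), `intercept`, `covariate_terms`, `alpha`, `lambda`,
#'   `training_ids`, `features_offered`.
#' @export
fit_elastic_net <- function(X_penalized, X_unpenalized = NULL, y,
                            alpha = 0.5, lambda = NULL, cv_folds = 5,
                            seed = 1L) {
  if (ncol(X_penalized) < 1) stop("no features offered")
  if (stats::var(y) == 0) stop("outcome has zero variance")
  if (all(apply(X_penalized, 2, stats::var) == 0))
    stop("all features have zero variance")
  p_pen <- ncol(X_penalized)
  Z <- if (is.null(X_unpenalized)) NULL else as.matrix(X_unpenalized)
  x <- if (is.null(Z)) X_penalized else cbind(X_penalized, Z)
  pf <- c(rep(1, p_pen), rep(0, if (is.null(Z)) 0 else ncol(Z)))
  n <- nrow(x)
  if (is.null(lambda)) {
    foldid <- .with_seed(seed,
                         sample(rep(seq_len(cv_folds), length.out = n)))
    cvfit <- glmnet::cv.glmnet(x, y, alpha = alpha, penalty.factor = pf,
                               foldid = foldid, nlambda = 100,
                               standardize = TRUE)
    lambda_use <- cvfit$lambda.min
    fit <- cvfit$glmnet.fit
  } else {
    # embed the requested lambda at the end of a decreasing path so
    # coordinate descent warm-starts reliably (exact at lambda = 0 too)
    lam_max <- max(abs(crossprod(x, y - mean(y)))) / n
    path <- sort(unique(c(exp(seq(log(lam_max + 1), log(1e-4),
                                  length.out = 30)) - 1, lambda)),
                 decreasing = TRUE)
    path <- path[path >= lambda]
    fit <- glmnet::glmnet(x, y, alpha = alpha, penalty.factor = pf,
                          lambda = path, standardize = TRUE,
                          thresh = 1e-14, maxit = 1e6)
    lambda_use <- lambda
  }
  cf <- as.numeric(stats::coef(fit, s = lambda_use))
  names(cf) <- c("(Intercept)", colnames(x))
  beta <- cf[1 + seq_len(p_pen)]
  keep <- beta != 0
  gamma <- if (is.null(Z)) numeric(0) else cf[1 + p_pen + seq_len(ncol(Z))]
  structure(list(probe_ids = colnames(X_penalized)[keep],
                 weights = unname(beta[keep]),
                 intercept = unname(cf[1]),
                 covariate_terms = gamma,
                 alpha = alpha, lambda = lambda_use,
                 training_ids = rownames(x),
                 features_offered = p_pen),
            class = "ClockModel")
}

#' @export
print.ClockModel <- function(x, ...) {
  cat(sprintf(
    "ClockModel: %d CpGs (of %d offered), alpha = %.2f, lambda = %.4g\n",
    length(x$probe_ids), x$features_offered, x$alpha, x$lambda))
  invisible(x)
}

#' Predict epigenetic gestational age
#'
#' `EGA = intercept + M[selected probes, ] . weights + Z . gamma`.
#'
#' @param object A `ClockModel`.
#' @param m Probes x samples M-value matrix containing the model's probes.
#' @param covariates Optional samples x covariates matrix matching the
#'   model's covariate terms (by name).
#' @param ... Unused.
#' @return Named vector of EGA in days.
#' @export
predict.ClockModel <- function(object, m, covariates = NULL, ...) {
  pred <- rep(object$intercept, ncol(m))
  names(pred) <- colnames(m)
  if (length(object$probe_ids)) {
    miss <- setdiff(object$probe_ids, rownames(m))
    if (length(miss)) stop("matrix missing model probes: ",
                           paste(utils::head(miss, 3), collapse = ", "))
    pred <- pred + as.numeric(crossprod(m[object$probe_ids, , drop = FALSE],
                                        object$weights))
  }
  if (length(object$covariate_terms)) {
    Z <- as.matrix(covariates)[, names(object$covariate_terms),
                               drop = FALSE]
    pred <- pred + as.numeric(Z %*% object$covariate_terms)
  }
  pred
}

#' Flag samples with extreme clock residuals
#'
#' Flags samples whose absolute residual exceeds `multiplier` times the
#' mean absolute residual. (The mean of signed residuals is ~0 for any
#' least-squares fit, so the rule operates on magnitudes.)
#'
#' @param residuals Named numeric vector of residuals (days).
#' @param multiplier Threshold multiplier (default 20).
#' @return Names (or indices) of flagged samples; empty when none.
#' @export
flag_outlier_samples <- function(residuals, multiplier = 20) {
  if (!length(residuals)) return(character(0))
  thr <- multiplier * mean(abs(residuals))
  flagged <- which(abs(residuals) > thr)
  if (!is.null(names(residuals))) names(residuals)[flagged] else flagged
}

#' Epigenetic gestational age acceleration
#'
#' `EGAA = EGA - observed GA`; positive values mean the methylome looks
#' older than the chronological estimate.
#'
#' @param ega Predicted EGA (days).
#' @param ga Observed chronological GA (days).
#' @return EGAA in days.
#' @export
compute_egaa <- function(ega, ga) {
  stopifnot(length(ega) == length(ga))
  ega - ga
}

#' Agreement metrics between predicted and observed GA
#'
#' Pearson r, R^2 (squared Pearson correlation, the variance in the
#' observed values explained by regressing on the predictions), ICC
#' (two-way, absolute-agreement, single-measures, from the two-column ANOVA
#' decomposition), and Bland-Altman mean difference with 1.96 SD limits of
#' agreement.
#'
#' @param pred Predicted EGA (days).
#' @param obs Observed GA (days).
#' @return Object of class `ClockMetrics`: `r`, `r2`, `icc`,
#'   `ba_mean_diff`, `ba_limits` (low, high).
#' @export
agreement_metrics <- function(pred, obs) {
  n <- length(pred)
  stopifnot(n == length(obs), n >= 3)
  r <- stats::cor(pred, obs)
  d <- pred - obs
  # two-way ANOVA on the n x 2 (subject x rater) layout
  k <- 2
  grand <- mean(c(pred, obs))
  row_means <- (pred + obs) / 2
  col_means <- c(mean(pred), mean(obs))
  msr <- k * sum((row_means - grand)^2) / (n - 1)
  msc <- n * sum((col_means - grand)^2) / (k - 1)
  sse <- sum((pred - row_means - col_means[1] + grand)^2) +
    sum((obs - row_means - col_means[2] + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  structure(list(r = r, r2 = r^2, icc = icc,
                 ba_mean_diff = mean(d),
                 ba_limits = mean(d) + c(-1.96, 1.96) * stats::sd(d)),
            class = "ClockMetrics")
}

#' @export
print.ClockMetrics <- function(x, ...) {
  cat(sprintf(
    "r = %.3f, R2 = %.3f, ICC = %.3f, BA mean diff = %.3f d [%.2f, %.2f]\n",
    x$r, x$r2, x$icc, x$ba_mean_diff, x$ba_limits[1], x$ba_limits[2]))
  invisible(x)
}

# subset a dataset to a sample id vector
.subset_samples <- function(ds, ids) {
  keep <- match(ids, ds$samples$sample_id)
  ds$values <- ds$values[, keep, drop = FALSE]
  if (!is.null(ds$detection_p))
    ds$detection_p <- ds$detection_p[, keep, drop = FALSE]
  ds$samples <- ds$samples[keep, , drop = FALSE]
  rownames(ds$samples) <- NULL
  ds
}

# covariate design without intercept/GA, for the unpenalized clock block.
# When `spec` is NULL it is derived from the data (dummy columns for every
# non-largest category level); passing a training spec reproduces the same
# columns on new samples, keeping train/test designs aligned.
.covariate_design <- function(samples, covariates, spec = NULL) {
  if (is.null(spec)) {
    spec <- list()
    for (v in covariates) {
      x <- samples[[v]]
      if (is.null(x)) next
      if (is.numeric(x)) {
        spec[[length(spec) + 1]] <- list(var = v, level = NULL)
      } else {
        tab <- sort(table(x), decreasing = TRUE)
        for (lev in setdiff(names(tab), names(tab)[1]))
          spec[[length(spec) + 1]] <- list(var = v, level = lev)
      }
    }
  }
  cols <- lapply(spec, function(s) {
    x <- samples[[s$var]]
    if (is.null(s$level)) as.numeric(x) else as.numeric(x == s$level)
  })
  X <- if (length(cols)) do.call(cbind, cols) else
    matrix(0, nrow(samples), 0)
  colnames(X) <- vapply(spec, function(s)
    if (is.null(s$level)) s$var else paste0(s$var, "_", s$level),
    character(1))
  attr(X, "spec") <- spec
  X
}

# fit one clock on a training dataset: latent estimation, EWAS feature
# selection, elastic net; returns the model plus the latent object for
# projecting new samples
.fit_clock_once <- function(ds_train, k_latent, q_threshold, alpha,
                            cv_folds, seed, max_k = 10, n_perm = 10) {
  Z0 <- .covariate_design(ds_train$samples, c("sex", "race"))
  if (identical(k_latent, "auto")) {
    # GA enters the permutation design so the outcome's own association
    # signature is not counted as a latent factor
    k_use <- estimate_num_factors(ds_train$values,
                                  cbind(1, Z0, ds_train$samples$ga),
                                  max_k = max_k, n_perm = n_perm,
                                  seed = seed)
  } else k_use <- as.integer(k_latent)
  factors <- estimate_latent_factors(ds_train$values, cbind(1, Z0),
                                     outcome = ds_train$samples$ga,
                                     K = k_use)
  ew <- run_ewas(ds_train, factors)
  feats <- select_features(ew, q_threshold)
  if (!length(feats)) stop("no features selected on the training set")
  Z <- if (k_use > 0) {
    sc <- factors$scores
    colnames(sc) <- paste0("latent", seq_len(ncol(sc)))
    cbind(Z0, sc)
  } else Z0
  Xp <- t(ds_train$values[feats, , drop = FALSE])
  rownames(Xp) <- ds_train$samples$sample_id
  model <- fit_elastic_net(Xp, Z, ds_train$samples$ga, alpha = alpha,
                           cv_folds = cv_folds, seed = seed)
  list(model = model, factors = factors, features = feats,
       k_latent = k_use, cov_spec = attr(Z0, "spec"))
}

# covariate matrix (incl. projected latent scores) for prediction
.predict_covariates <- function(fit, ds_new) {
  Z0 <- .covariate_design(ds_new$samples, c("sex", "race"),
                          spec = fit$cov_spec)
  if (fit$k_latent > 0) {
    sc <- project_latent(fit$factors, ds_new$values, cbind(1, Z0))
    colnames(sc) <- paste0("latent", seq_len(ncol(sc)))
    Z0 <- cbind(Z0, sc)
  }
  Z0
}

#' Train and evaluate a gestational-age clock
#'
#' The full training procedure: (1) deterministic 80/20 split; (2) on the
#' training set, latent-factor estimation, EWAS, FDR feature selection and
#' an elastic-net fit with unpenalized covariates; (3) five-fold
#' cross-validated EGA within the training set to flag residual outliers
#' (> `outlier_multiplier` x mean |residual|), which are removed and the
#' model refit once; (4) application to the held-out test set with
#' agreement metrics.
#'
#' @param ds An M-scale QC'd [methylation_dataset()] whose samples carry
#'   `ga`, `sex`, `race`.
#' @param train_frac Training fraction (default 0.8).
#' @param q_threshold Feature-selection FDR threshold (default 0.05).
#' @param alpha Elastic-net mixing (default 0.5).
#' @param k_latent `"auto"` (parallel analysis, re-estimated on the
#'   training set) or an integer count.
#' @param cv_folds Folds for internal lambda CV and the outlier CV pass.
#' @param outlier_multiplier Residual-outlier rule multiplier (default 20).
#' @param seed Integer seed governing split, folds and lambda CV.
#' @return List with `model` (`ClockModel`), `metrics` (`ClockMetrics` on
#'   the test set), `test_ega` (an `EgaTable` for the test samples),
#'   `outliers` (flagged training ids), `split`.
#' @export
train_clock <- function(ds, train_frac = 0.8, q_threshold = 0.05,
                        alpha = 0.5, k_latent = "auto", cv_folds = 5,
                        outlier_multiplier = 20, seed = 1L) {
  sp <- split_train_test(ds$samples$sample_id, train_frac, seed)
  ds_tr <- .subset_samples(ds, sp$train)
  ds_te <- .subset_samples(ds, sp$test)
  # CV pass within the training set to find residual outliers
  cv <- cross_validated_ega(ds_tr, folds = cv_folds, seed = seed,
                            q_threshold = q_threshold, alpha = alpha,
                            k_latent = k_latent)
  resid <- stats::setNames(cv$egaa, cv$sample_id)
  outliers <- flag_outlier_samples(resid[!is.na(resid)],
                                   outlier_multiplier)
  if (length(outliers))
    ds_tr <- .subset_samples(ds_tr,
                             setdiff(ds_tr$samples$sample_id, outliers))
  fit <- .fit_clock_once(ds_tr, k_latent, q_threshold, alpha, cv_folds,
                         seed)
  Zte <- .predict_covariates(fit, ds_te)
  ega <- predict(fit$model, ds_te$values, Zte)
  metrics <- agreement_metrics(ega, ds_te$samples$ga)
  test_ega <- data.frame(sample_id = ds_te$samples$sample_id,
                         ga_observed = ds_te$samples$ga, ega = ega,
                         egaa = compute_egaa(ega, ds_te$samples$ga),
                         fold = NA_integer_, row.names = NULL)
  list(model = fit$model, metrics = metrics, test_ega = test_ega,
       outliers = outliers, split = sp)
}

#' Cross-validated epigenetic gestational age for a whole cohort
#'
#' Each sample is apportioned into one of `folds` folds (deterministic
#' under the seed). Per fold, the full training procedure - latent-factor
#' estimation, EWAS, FDR feature selection, elastic-net fit - runs on the
#' other folds only, and EGA is predicted for the held-out fold, so every
#' sample receives exactly one out-of-fold prediction and nothing leaks
#' from a sample into its own model. A fold whose training selection comes
#' up empty is flagged and its predictions left missing.
#'
#' @inheritParams train_clock
#' @param folds Number of folds (default 5).
#' @return data.frame of class `EgaTable`: `sample_id`, `ga_observed`,
#'   `ega`, `egaa` (= ega - ga), `fold`. Failed folds are listed in the
#'   `"failed_folds"` attribute.
#' @export
cross_validated_ega <- function(ds, folds = 5, seed = 1L,
                                q_threshold = 0.05, alpha = 0.5,
                                k_latent = "auto") {
  ids <- ds$samples$sample_id
  n <- length(ids)
  # fold assignment is keyed to sorted ids so it is invariant to the input
  # sample order
  sorted <- sort(ids)
  fold_of <- stats::setNames(
    .with_seed(.sub_seed(seed, 101),
               sample(rep(seq_len(folds), length.out = n))), sorted)
  out <- data.frame(sample_id = ids, ga_observed = ds$samples$ga,
                    ega = NA_real_, egaa = NA_real_,
                    fold = unname(fold_of[ids]))
  failed <- integer(0)
  for (f in seq_len(folds)) {
    tr_ids <- sorted[fold_of[sorted] != f]
    te_ids <- sorted[fold_of[sorted] == f]
    ds_tr <- .subset_samples(ds, tr_ids)
    ds_te <- .subset_samples(ds, te_ids)
    fit <- tryCatch(
      .fit_clock_once(ds_tr, k_latent, q_threshold, alpha, cv_folds = 5,
                      seed = .sub_seed(seed, 200 + f)),
      error = function(e) NULL)
    if (is.null(fit)) { failed <- c(failed, f); next }
    Zte <- .predict_covariates(fit, ds_te)
    ega <- predict(fit$model, ds_te$values, Zte)
    out$ega[match(te_ids, out$sample_id)] <- ega
  }
  out$egaa <- out$ega - out$ga_observed
  attr(out, "failed_folds") <- failed
  class(out) <- c("EgaTable", class(out))
  out
}

#' Serialize / deserialize a clock model as JSON
#'
#' The schema (probe ids, weights, intercept, covariate terms,
#' hyperparameters) also accepts externally published clock coefficient
#' files, so other cord-blood clocks can be applied with
#' [predict.ClockModel()].
#'
#' @param model A `ClockModel`.
#' @param path JSON file path.
#' @export
write_clock_model <- function(model, path) {
  jsonlite::write_json(
    list(probe_ids = model$probe_ids, weights = model$weights,
         intercept = model$intercept,
         covariate_terms = as.list(model$covariate_terms),
         alpha = model$alpha, lambda = model$lambda,
         training_ids = model$training_ids,
         features_offered = model$features_offered),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_clock_model
#' @export
read_clock_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$covariate_terms <- unlist(x$covariate_terms)
  if (is.null(x$covariate_terms)) x$covariate_terms <- numeric(0)
  structure(x, class = "ClockModel")
}
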