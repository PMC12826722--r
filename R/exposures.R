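#' Single-exposure linear model for a gestational-age outcome
#'
#' Unadjusted OLS of the outcome (GA, EGA or EGAA, in days) on one
#' exposure. Categorical exposures are dummy-coded against a stated
#' reference level; one result row is produced per non-reference level,
#' with the 95% CI `estimate +/- t(0.975, df) * SE` and the overall F-test
#' of the exposure term against the intercept-only model. Complete cases
#' within this exposure only.
#'
#' @param outcome Numeric outcome vector (days).
#' @param exposure Exposure vector (numeric, logical, or
#'   character/factor).
#' @param exposure_name Label used in the output.
#' @param reference Reference level for categorical exposures (default:
#'   first sorted level).
#' @return data.frame with `exposure`, `level` (`""` for continuous),
#'   `coefficient`, `ci_low`, `ci_high`, `p_level` (per-level t-test),
#'   `f_p` (overall F), `n`.
#' @export
fit_exposure_model <- function(outcome, exposure,
                               exposure_name = "exposure",
                               reference = NULL) {
  cc <- stats::complete.cases(outcome, exposure)
  y <- outcome[cc]
  x <- exposure[cc]
  if (length(y) < 3) stop("fewer than 3 complete cases")
  if (is.logical(x)) x <- ifelse(x, "yes", "no")
  categorical <- is.character(x) || is.factor(x)
  if (categorical) {
    x <- as.character(x)
    levs <- sort(unique(x))
    if (length(levs) < 2) stop("exposure is constant")
    if (!is.null(reference)) {
      stopifnot(reference %in% levs)
      levs <- c(reference, setdiff(levs, reference))
    }
    x <- factor(x, levels = levs)
  } else if (stats::var(x) == 0) stop("exposure is constant")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  f_p <- stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
  ci <- stats::confint(fit, level = 0.95)
  co <- sm$coefficients
  idx <- setdiff(rownames(co), "(Intercept)")
  data.frame(
    exposure = exposure_name,
    level = if (categorical) sub("^x", "", idx) else "",
    coefficient = co[idx, "Estimate"],
    ci_low = ci[idx, 1], ci_high = ci[idx, 2],
    p_level = co[idx, "Pr(>|t|)"],
    f_p = unname(f_p), n = length(y), row.names = NULL)
}

#' All single-exposure models with per-outcome FDR
#'
#' Fits [fit_exposure_model()] for every exposure column against every
#' outcome column and attaches a BH q-value per outcome across exposures
#' (one p per exposure: its overall F-test).
#'
#' @param outcomes data.frame of outcome columns (e.g. `ga`, `ega`,
#'   `egaa`), all in days.
#' @param exposures data.frame of exposure columns (a `sample_id` column is
#'   ignored).
#' @param references Optional named list of reference levels per exposure.
#' @return data.frame of stacked `ExposureResult` rows with an `outcome`
#'   column and `q`.
#' @export
run_all_exposures <- function(outcomes, exposures, references = list()) {
  exposures <- exposures[, setdiff(names(exposures), "sample_id"),
                         drop = FALSE]
  out <- list()
  for (oc in names(outcomes)) {
    y <- outcomes[[oc]]
    if (stats::var(y, na.rm = TRUE) == 0)
      stop("outcome '", oc, "' has zero variance (degenerate)")
    rows <- lapply(names(exposures), function(ex) {
      fit_exposure_model(y, exposures[[ex]], exposure_name = ex,
                         reference = references[[ex]])
    })
    tab <- do.call(rbind, rows)
    tab <- cbind(outcome = oc, tab)
    fp_by_exposure <- tab$f_p[!duplicated(tab$exposure)]
    q_by_exposure <- stats::setNames(bh_fdr(fp_by_exposure),
                                     unique(tab$exposure))
    tab$q <- unname(q_by_exposure[tab$exposure])
    out[[oc]] <- tab
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# AIC without additive constants: n*log(RSS/n) + 2k, k = estimated
# coefficients (matches stats::extractAIC for lm)
.aic_rss <- function(fit) {
  n <- length(fit$residuals)
  rss <- sum(fit$residuals^2)
  k <- fit$rank
  n * log(rss / n) + 2 * k
}

#' Backward model selection by AIC over candidate exposures
#'
#' Starts from the full model containing every candidate exposure
#' (categoricals as whole dummy-coded terms) and greedily drops the term
#' whose removal most decreases `AIC = n log(RSS/n) + 2k`, stopping when no
#' drop decreases it. The sample is fixed to complete cases across all
#' candidates before stepping so AIC values stay comparable.
#'
#' @param outcome Numeric outcome (days).
#' @param exposures data.frame of candidate exposure columns (a
#'   `sample_id` column is ignored).
#' @return Object of class `SelectionResult`: `retained_exposures`,
#'   `coefficients` (of the final model), `aic_trace` (data.frame: step,
#'   dropped, aic), `r2`, `adj_r2`, `final_fit` (the `lm` object), `n`.
#' @export
backward_select_aic <- function(outcome, exposures) {
  exposures <- exposures[, setdiff(names(exposures), "sample_id"),
                         drop = FALSE]
  cc <- stats::complete.cases(outcome, exposures)
  dat <- data.frame(.y = outcome[cc], exposures[cc, , drop = FALSE])
  terms_all <- names(exposures)
  full <- stats::lm(stats::reformulate(terms_all, ".y"), data = dat)
  if (nrow(dat) <= full$rank) stop("more parameters than observations")
  current <- terms_all
  aic_cur <- .aic_rss(full)
  trace <- data.frame(step = 0L, dropped = "<full>", aic = aic_cur)
  repeat {
    if (!length(current)) break
    cand <- vapply(current, function(tm) {
      rest <- setdiff(current, tm)
      f <- if (length(rest)) stats::reformulate(rest, ".y") else .y ~ 1
      .aic_rss(stats::lm(f, data = dat))
    }, numeric(1))
    best <- which.min(cand)
    if (cand[best] >= aic_cur) break
    aic_cur <- cand[best]
    dropped <- current[best]
    current <- setdiff(current, dropped)
    trace <- rbind(trace, data.frame(step = nrow(trace),
                                     dropped = dropped, aic = aic_cur))
  }
  f_final <- if (length(current)) stats::reformulate(current, ".y") else
    .y ~ 1
  fit <- stats::lm(f_final, data = dat)
  sm <- summary(fit)
  structure(list(retained_exposures = current,
                 coefficients = stats::coef(fit),
                 aic_trace = trace, r2 = sm$r.squared,
                 adj_r2 = sm$adj.r.squared, final_fit = fit,
                 n = nrow(dat)),
            class = "SelectionResult")
}

#' @export
print.SelectionResult <- function(x, ...) {
  cat(sprintf("Backward AIC selection: %d terms retained (n = %d)\n",
              length(x$retained_exposures), x$n))
  cat("  retained:", paste(x$retained_exposures, collapse = ", "), "\n")
  cat(sprintf("  R2 = %.3f, adjusted R2 = %.3f\n", x$r2, x$adj_r2))
  invisible(x)
}
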