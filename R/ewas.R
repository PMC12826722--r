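#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted q-values: `q_i = min_{j: p_(j) >= p_(i)} m * p_(j) / j`,
#' capped at 1 and returned in the input order. `NA` entries are excluded
#' from the test count `m` and propagate as `NA`.
#'
#' @param p Numeric vector of p-values in \[0, 1\] (NA allowed).
#' @return Vector of q-values, same length and order.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Genomic inflation factor
#'
#' `lambda = median(qchisq(1 - p, 1)) / qchisq(0.5, 1)`. Values near 1
#' indicate a calibrated test; inflation (> 1) suggests unmodelled
#' confounding or stratification. Zero p-values are clamped to the smallest
#' positive double with a warning.
#'
#' @param p Non-empty vector of p-values.
#' @return List with `lambda` and `qq`, a data.frame of expected vs observed
#'   -log10 p coordinates for a QQ plot.
#' @export
genomic_inflation <- function(p) {
  p <- p[!is.na(p)]
  if (!length(p)) stop("no p-values")
  if (any(p == 0)) {
    warning("p-values of 0 clamped for inflation estimate")
    p[p == 0] <- .Machine$double.xmin
  }
  chisq <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  lambda <- stats::median(chisq) / stats::qchisq(0.5, 1)
  s <- sort(p)
  qq <- data.frame(expected = -log10(stats::ppoints(length(s))),
                   observed = -log10(s))
  list(lambda = lambda, qq = qq)
}

#' Single-site linear regression
#'
#' Ordinary least squares of one probe's M-values on a design matrix;
#' returns the estimate, standard error, t and two-sided p for one
#' coefficient (by default the second column, conventionally the GA term).
#'
#' @param y Response vector (M-values across samples).
#' @param X Design matrix including an intercept column.
#' @param coef Column (index or name) to report.
#' @return List with `estimate`, `se`, `t`, `p`, `df`.
#' @export
fit_site_regression <- function(y, X, coef = 2) {
  X <- as.matrix(X)
  n <- length(y)
  if (n <= ncol(X)) stop("need more samples than design columns")
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("design matrix rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  fit <- stats::lm.fit(X, y)
  df <- n - qx$rank
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / df
  xtx_inv <- solve(crossprod(X))
  j <- if (is.character(coef)) match(coef, colnames(X)) else coef
  est <- unname(fit$coefficients[j])
  se <- sqrt(sigma2 * xtx_inv[j, j])
  tval <- if (se == 0) 0 else est / se
  list(estimate = est, se = se, t = tval,
       p = 2 * stats::pt(-abs(tval), df), df = df)
}

# design matrix: intercept + ga + sex + race dummies (largest level as
# reference) + latent factor scores
.ewas_design <- function(samples, factors = NULL,
                         covariates = c("sex", "race")) {
  X <- cbind(`(Intercept)` = 1, ga = samples$ga)
  for (v in covariates) {
    if (is.null(samples[[v]])) next
    x <- samples[[v]]
    if (is.numeric(x)) {
      X <- cbind(X, stats::setNames(data.frame(x), v))
      next
    }
    tab <- sort(table(x), decreasing = TRUE)
    ref <- names(tab)[1]
    for (lev in setdiff(names(tab), ref)) {
      col <- as.numeric(x == lev)
      X <- cbind(X, col)
      colnames(X)[ncol(X)] <- paste0(v, "_", lev)
    }
  }
  X <- as.matrix(X)
  if (!is.null(factors) && factors$K > 0) {
    sc <- factors$scores
    colnames(sc) <- paste0("latent", seq_len(ncol(sc)))
    X <- cbind(X, sc)
  }
  X
}

#' Epigenome-wide association study of gestational age
#'
#' Per-probe OLS of M-values on GA, adjusting for sex, race (dummy-coded,
#' largest category as reference) and optional latent factor scores. All
#' probes sharing the design are fit in one pass through a common QR
#' decomposition; probes with missing values fall back to per-probe
#' complete-case fits, and zero-variance probes are flagged (`ok = FALSE`)
#' rather than aborting the scan.
#'
#' @param ds An M-scale [methylation_dataset()].
#' @param factors Optional `LatentFactors` from [estimate_latent_factors()].
#' @param covariates Sample metadata columns to adjust for.
#' @return data.frame of class `EWASResult` with columns `probe_id`,
#'   `estimate` (M-units/day), `se`, `t`, `p`, `q` (BH), `n`, `direction`,
#'   `ok`. The attribute `summary` reports q < 0.05 hit counts by direction;
#'   `design` keeps the design column names.
#' @export
run_ewas <- function(ds, factors = NULL, covariates = c("sex", "race")) {
  stopifnot(inherits(ds, "MethylationDataset"))
  if (ds$scale != "M") stop("run_ewas expects an M-scale dataset")
  X <- .ewas_design(ds$samples, factors, covariates)
  Y <- t(ds$values)                       # samples x probes
  n <- nrow(Y)
  np <- ncol(Y)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("design matrix rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  df <- n - qx$rank
  out <- data.frame(probe_id = colnames(Y), estimate = NA_real_,
                    se = NA_real_, t = NA_real_, p = NA_real_,
                    n = n, ok = TRUE, stringsAsFactors = FALSE)
  var0 <- apply(Y, 2, function(col) stats::var(col, na.rm = TRUE)) == 0
  has_na <- colSums(is.na(Y)) > 0
  easy <- !var0 & !has_na
  if (any(easy)) {
    B <- qr.coef(qx, Y[, easy, drop = FALSE])
    R <- qr.resid(qx, Y[, easy, drop = FALSE])
    sigma2 <- colSums(R^2) / df
    xtx_inv <- solve(crossprod(X))
    j <- match("ga", colnames(X))
    se <- sqrt(sigma2 * xtx_inv[j, j])
    est <- B[j, ]
    tv <- ifelse(se == 0, 0, est / se)
    out$estimate[easy] <- est
    out$se[easy] <- se
    out$t[easy] <- tv
    out$p[easy] <- 2 * stats::pt(-abs(tv), df)
  }
  for (k in which(has_na & !var0)) {
    cc <- !is.na(Y[, k])
    if (sum(cc) <= ncol(X)) { out$ok[k] <- FALSE; next }
    f <- tryCatch(fit_site_regression(Y[cc, k], X[cc, , drop = FALSE],
                                      coef = "ga"),
                  error = function(e) NULL)
    if (is.null(f)) { out$ok[k] <- FALSE; next }
    out$estimate[k] <- f$estimate; out$se[k] <- f$se
    out$t[k] <- f$t; out$p[k] <- f$p; out$n[k] <- sum(cc)
  }
  out$ok[var0] <- FALSE
  out$q <- bh_fdr(out$p)
  out$direction <- sign(out$estimate)
  hits <- out$q < 0.05 & out$ok
  attr(out, "summary") <- list(
    n_tested = sum(out$ok), n_hits = sum(hits, na.rm = TRUE),
    n_hits_positive = sum(hits & out$direction > 0, na.rm = TRUE),
    n_hits_negative = sum(hits & out$direction < 0, na.rm = TRUE))
  attr(out, "design") <- colnames(X)
  class(out) <- c("EWASResult", class(out))
  out
}
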