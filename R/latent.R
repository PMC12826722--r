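#' Choose the number of latent factors by parallel analysis
#'
#' The methylation matrix is residualized on the covariates and its singular
#' values compared against a permutation null: each residual column (probe)
#' is independently permuted across samples, destroying sample-level
#' structure while preserving per-probe distributions. K is the number of
#' leading observed singular values exceeding the 95th percentile of the
#' corresponding permuted singular values (stopping at the first failure).
#'
#' @param m Probes x samples matrix (M-values), or a
#'   [methylation_dataset()].
#' @param covariates Design matrix of known covariates (an intercept is
#'   added when missing).
#' @param max_k Maximum K considered; must be positive and smaller than both
#'   dimensions.
#' @param n_perm Number of permutations (default 20).
#' @param seed Integer seed for the permutations.
#' @return Integer K in `0..max_k`.
#' @export
estimate_num_factors <- function(m, covariates = NULL, max_k = 10,
                                 n_perm = 20, seed = 1L) {
  if (inherits(m, "MethylationDataset")) m <- m$values
  if (max_k <= 0) stop("max_k must be positive")
  Y <- t(m)                               # samples x probes
  n <- nrow(Y)
  if (max_k >= min(dim(Y))) stop("max_k must be < min(dim)")
  R <- .residualize(Y, covariates)
  d_obs <- svd(R, nu = 0, nv = 0)$d[seq_len(max_k)]
  d_perm <- matrix(NA_real_, n_perm, max_k)
  .with_seed(seed, {
    for (b in seq_len(n_perm)) {
      Rp <- apply(R, 2, sample)
      d_perm[b, ] <- svd(Rp, nu = 0, nv = 0)$d[seq_len(max_k)]
    }
  })
  thresh <- apply(d_perm, 2, stats::quantile, probs = 0.95)
  above <- d_obs > thresh
  K <- if (all(above)) max_k else which.min(above) - 1L
  as.integer(K)
}

.residualize <- function(Y, covariates) {
  n <- nrow(Y)
  X <- if (is.null(covariates)) matrix(1, n, 1) else as.matrix(covariates)
  if (!any(apply(X, 2, function(c) all(c == c[1]))))
    X <- cbind(1, X)                      # ensure an intercept
  qx <- qr(X)
  qr.resid(qx, Y)
}

#' Estimate latent factor scores
#'
#' Residualize-then-SVD approximation to outcome-aware confounder
#' estimators. Without an `outcome`, scores are the top-K left singular
#' vectors of the matrix residualized on the known covariates. With an
#' `outcome` (GA), the factor *loadings* are learned from the matrix
#' residualized on covariates and outcome - so the loading patterns cannot
#' be the outcome's own association signature - while the *scores* are the
#' projection of the covariate-only residual onto those loadings, so they
#' remain free to correlate with the outcome and can absorb genuine
#' confounding. Scores are exactly centered and mutually orthonormal
#' (Gram-Schmidt with positive diagonal, deterministic); each loading's
#' sign is fixed so its largest-magnitude entry is positive.
#'
#' @param m Probes x samples matrix or [methylation_dataset()].
#' @param covariates Known-covariate design matrix (intercept added if
#'   missing).
#' @param outcome Optional outcome vector (GA in days) to protect.
#' @param K Number of factors (from [estimate_num_factors()] or user-set).
#' @return Object of class `LatentFactors`: `scores` (samples x K),
#'   `loadings` (probes x K), `d` (singular values), `K`, `method_tag`,
#'   `variance_explained`, plus the residualization coefficients needed to
#'   project new samples with [project_latent()].
#' @export
estimate_latent_factors <- function(m, covariates = NULL, outcome = NULL,
                                    K) {
  if (inherits(m, "MethylationDataset")) m <- m$values
  Y <- t(m)
  n <- nrow(Y)
  X <- if (is.null(covariates)) matrix(1, n, 1) else as.matrix(covariates)
  if (!any(apply(X, 2, function(c) all(c == c[1])))) X <- cbind(1, X)
  qx <- qr(X)
  if (K > min(dim(Y)) - qx$rank) stop("K exceeds residual rank")
  B <- qr.coef(qx, Y)
  B[is.na(B)] <- 0
  R <- Y - X %*% B
  if (K == 0) {
    return(structure(list(scores = matrix(0, n, 0),
                          loadings = matrix(0, ncol(Y), 0),
                          d = numeric(0), K = 0L,
                          method_tag = "residual-svd",
                          variance_explained = numeric(0),
                          covariate_coef = B, covariates = X),
                     class = "LatentFactors"))
  }
  Rp <- if (is.null(outcome)) R else .residualize(Y, cbind(X, outcome))
  sv <- svd(Rp, nu = 0, nv = K)
  signs <- vapply(seq_len(K), function(k) {
    v <- sv$v[, k]
    if (v[which.max(abs(v))] >= 0) 1 else -1
  }, numeric(1))
  loadings <- sweep(sv$v[, seq_len(K), drop = FALSE], 2, signs, `*`)
  d <- sv$d[seq_len(K)]
  raw <- R %*% loadings %*% diag(1 / d, K)
  # center, then orthonormalize deterministically (QR with positive diag);
  # keep center and transform so new samples can be mapped onto the same
  # basis by project_latent()
  center <- colMeans(raw)
  cen <- sweep(raw, 2, center)
  qs <- qr(cen)
  rdiag <- diag(qr.R(qs))
  flip <- diag(sign(rdiag + (rdiag == 0)), K)
  scores <- qr.Q(qs) %*% flip
  transform <- backsolve(qr.R(qs), flip)
  rownames(scores) <- rownames(Y)
  rownames(loadings) <- colnames(Y)
  structure(list(scores = scores, loadings = loadings,
                 d = d, K = as.integer(K),
                 method_tag = if (is.null(outcome)) "residual-svd" else
                   "residual-svd-protected",
                 variance_explained = d^2 / sum(sv$d^2),
                 covariate_coef = B, covariates = X,
                 score_center = center, score_transform = transform),
            class = "LatentFactors")
}

#' Project new samples onto estimated latent factors
#'
#' Uses the training residualization coefficients, loadings and score
#' basis: `u_new = ((m_new - X_new B) V D^-1 - center) T`, where `T` is the
#' training orthonormalization transform. Needed when a clock trained with
#' latent covariates predicts held-out samples.
#'
#' @param factors A `LatentFactors` object.
#' @param m_new Probes x new-samples matrix (same probe order as training).
#' @param covariates_new Covariate design for the new samples, with the same
#'   columns as the training design.
#' @return New-samples x K score matrix.
#' @export
project_latent <- function(factors, m_new, covariates_new) {
  if (factors$K == 0) return(matrix(0, ncol(m_new), 0))
  Yn <- t(m_new)
  Xn <- as.matrix(covariates_new)
  if (ncol(Xn) == ncol(factors$covariates) - 1) Xn <- cbind(1, Xn)
  Rn <- Yn - Xn %*% factors$covariate_coef
  raw <- Rn %*% factors$loadings %*% diag(1 / factors$d, factors$K)
  sweep(raw, 2, factors$score_center) %*% factors$score_transform
}
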