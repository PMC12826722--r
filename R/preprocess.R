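#' Beta to M-value conversion
#'
#' M = log2(beta / (1 - beta)), the logit (base 2) of the methylated
#' proportion. Regression on the M scale avoids the severe
#' heteroscedasticity of beta values near 0 and 1. Values of exactly 0 or 1
#' are clamped to `clamp` / `1 - clamp` before the transform so the result
#' stays finite; the clamp is reported by [filter_probes()]'s QC report when
#' it fires during preprocessing.
#'
#' @param beta Numeric vector/matrix of proportions in \[0, 1\].
#' @param clamp Lower clamp bound (default `1e-6`).
#' @return M-values, same shape as the input.
#' @export
beta_to_m <- function(beta, clamp = 1e-6) {
  if (any(beta < 0 | beta > 1, na.rm = TRUE))
    stop("beta values must lie in [0, 1]")
  b <- pmin(pmax(beta, clamp), 1 - clamp)
  out <- log2(b / (1 - b))
  if (is.matrix(beta)) dimnames(out) <- dimnames(beta)
  out
}

#' @rdname beta_to_m
#' @param m M-values.
#' @export
m_to_beta <- function(m) {
  2^m / (1 + 2^m)
}

#' Quality-control configuration for probe filtering
#'
#' @param detection_p_threshold Detection p-value above which a (probe,
#'   sample) measurement counts as failed. Default 0.05.
#' @param detection_fail_fraction_max Maximum tolerated fraction of samples
#'   failing detection before the probe is dropped. The default 0 removes a
#'   probe if ANY sample fails - the strictest reading of a "detection p >
#'   0.05" exclusion rule.
#' @param drop_snp Drop probes with a SNP at the 3' or 5' position.
#' @param drop_sex Drop probes on sex chromosomes.
#' @param drop_off_target Drop probes flagged as not capturing their intended
#'   target.
#' @return A list of class `QCConfig`.
#' @export
qc_config <- function(detection_p_threshold = 0.05,
                      detection_fail_fraction_max = 0,
                      drop_snp = TRUE, drop_sex = TRUE,
                      drop_off_target = TRUE) {
  stopifnot(detection_p_threshold >= 0, detection_p_threshold <= 1,
            detection_fail_fraction_max >= 0,
            detection_fail_fraction_max <= 1)
  structure(list(detection_p_threshold = detection_p_threshold,
                 detection_fail_fraction_max = detection_fail_fraction_max,
                 drop_snp = drop_snp, drop_sex = drop_sex,
                 drop_off_target = drop_off_target),
            class = "QCConfig")
}

#' Per-probe detection failure fractions
#'
#' @param detection_p Matrix of detection p-values (probes x samples).
#' @param threshold Failure threshold (default 0.05).
#' @return Fraction of samples failing per probe.
#' @export
detection_fail_fraction <- function(detection_p, threshold = 0.05) {
  rowMeans(detection_p > threshold)
}

#' Probe QC filtering
#'
#' Removes probes failing any enabled exclusion rule: detection failures in
#' more than the tolerated fraction of samples, SNPs at the 3'/5' probe ends,
#' sex-chromosome location, or off-target capture. Samples are never removed.
#'
#' @param ds A [methylation_dataset()] whose manifest flags are populated.
#'   If the dataset carries a `detection_p` matrix, per-probe failure
#'   fractions are (re)computed from it at `qc$detection_p_threshold`;
#'   otherwise the manifest's `detection_fail_fraction` column is used as-is.
#' @param qc A [qc_config()].
#' @return A list with `dataset` (the filtered [methylation_dataset()]) and
#'   `report` (counts removed per rule, total retained, rule settings).
#' @export
filter_probes <- function(ds, qc = qc_config()) {
  man <- ds$manifest
  fail_frac <- if (!is.null(ds$detection_p)) {
    detection_fail_fraction(ds$detection_p, qc$detection_p_threshold)
  } else {
    man$detection_fail_fraction
  }
  rule <- list(
    detection = fail_frac > qc$detection_fail_fraction_max,
    snp = if (qc$drop_snp) man$snp_3p_flag | man$snp_5p_flag else
      rep(FALSE, nrow(man)),
    sex_chromosome = if (qc$drop_sex) man$sex_chromosome else
      rep(FALSE, nrow(man)),
    off_target = if (qc$drop_off_target) man$off_target else
      rep(FALSE, nrow(man))
  )
  drop <- Reduce(`|`, rule)
  if (all(drop)) stop("all probes removed by QC filtering")
  keep <- !drop
  ds$values <- ds$values[keep, , drop = FALSE]
  ds$manifest <- man[keep, , drop = FALSE]
  rownames(ds$manifest) <- NULL
  if (!is.null(ds$detection_p))
    ds$detection_p <- ds$detection_p[keep, , drop = FALSE]
  report <- list(
    n_input = nrow(man),
    removed = vapply(rule, sum, integer(1)),
    n_removed_total = sum(drop),
    n_retained = sum(keep),
    config = unclass(qc)
  )
  list(dataset = ds, report = report)
}

#' Quantile normalization across samples
#'
#' Each sample's sorted values are replaced by the across-sample mean of the
#' order statistics, forcing all samples onto a common distribution while
#' preserving within-sample ranks. Ties share the mean of their tied ranks'
#' reference values (average-rank convention, deterministic). Delegates to
#' \pkg{limma}'s `normalizeQuantiles`.
#'
#' @param values Probes x samples numeric matrix without missing values.
#' @return Normalized matrix, same dimnames.
#' @export
quantile_normalize <- function(values) {
  if (!is.matrix(values)) values <- as.matrix(values)
  if (anyNA(values)) stop("missing values not supported")
  if (ncol(values) < 2) {
    warning("single-sample input: quantile normalization is the identity")
    return(values)
  }
  out <- limma::normalizeQuantiles(values, ties = TRUE)
  dimnames(out) <- dimnames(values)
  out
}

#' Full preprocessing pipeline: filter, quantile-normalize, convert to M
#'
#' Applies [filter_probes()], then [quantile_normalize()] on the beta scale,
#' then [beta_to_m()], mirroring the normalize-then-logit order of standard
#' array pipelines. Datasets already on the M scale are converted to beta
#' first so normalization always operates on proportions.
#'
#' @inheritParams filter_probes
#' @return A list with `dataset` (M-scale, QC'd, normalized) and `report`.
#' @export
preprocess_dataset <- function(ds, qc = qc_config()) {
  flt <- filter_probes(ds, qc)
  out <- convert_scale(flt$dataset, "beta")
  out$values <- quantile_normalize(out$values)
  out <- convert_scale(out, "M")
  list(dataset = out, report = flt$report)
}
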