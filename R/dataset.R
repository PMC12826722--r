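#' Methylation dataset container
#'
#' Bundles a probes x samples value matrix with an aligned probe manifest and
#' sample metadata table. All pipeline stages consume and return this object.
#'
#' @param values Numeric matrix, probes in rows, samples in columns. Row names
#'   are probe ids, column names sample ids.
#' @param scale Either `"beta"` (proportions in \[0, 1\]) or `"M"` (log2 ratio
#'   scale).
#' @param manifest Probe manifest `data.frame` (see [simulate_manifest()] for
#'   the column contract); its row order must match `rownames(values)`.
#' @param samples Sample metadata `data.frame` with at least `sample_id` and
#'   `ga` (gestational age in days); row order must match `colnames(values)`.
#' @param detection_p Optional matrix of detection p-values, same shape as
#'   `values`.
#'
#' @return An object of class `MethylationDataset`: a list with elements
#'   `values`, `scale`, `manifest`, `samples` and optionally `detection_p`.
#' @export
methylation_dataset <- function(values, scale = c("M", "beta"), manifest,
                                samples, detection_p = NULL) {
  scale <- match.arg(scale)
  if (!is.matrix(values)) stop("'values' must be a matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' needs probe row names and sample column names")
  if (anyDuplicated(rownames(values))) stop("duplicated probe ids")
  if (anyDuplicated(colnames(values))) stop("duplicated sample ids")
  if (!identical(as.character(manifest$probe_id), rownames(values)))
    stop("manifest row order must match rownames(values)")
  if (!identical(as.character(samples$sample_id), colnames(values)))
    stop("sample metadata order must match colnames(values)")
  if (scale == "beta" && (min(values, na.rm = TRUE) < 0 ||
                          max(values, na.rm = TRUE) > 1))
    stop("scale 'beta' but values outside [0, 1]")
  structure(
    list(values = values, scale = scale, manifest = manifest,
         samples = samples, detection_p = detection_p),
    class = "MethylationDataset"
  )
}

#' @export
print.MethylationDataset <- function(x, ...) {
  cat(sprintf("MethylationDataset: %d probes x %d samples (%s scale)\n",
              nrow(x$values), ncol(x$values), x$scale))
  invisible(x)
}

#' @export
dim.MethylationDataset <- function(x) dim(x$values)

#' Convert a dataset between beta and M scales
#'
#' @param ds A [methylation_dataset()].
#' @param to Target scale, `"M"` or `"beta"`.
#' @return The dataset on the requested scale (a no-op when already there).
#' @export
convert_scale <- function(ds, to = c("M", "beta")) {
  to <- match.arg(to)
  if (ds$scale == to) return(ds)
  ds$values <- if (to == "M") beta_to_m(ds$values) else m_to_beta(ds$values)
  ds$scale <- to
  ds
}

# --- plain-text IO -----------------------------------------------------------

#' Write / read a probes x samples matrix as TSV
#'
#' The first column holds probe ids, the header row sample ids.
#' @param m Numeric matrix with dimnames.
#' @param path File path.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(probe_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write / read a data frame as TSV (manifest, exposures, results tables)
#' @param df A data.frame without list columns.
#' @param path File path.
#' @export
write_table_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table_tsv
#' @export
read_table_tsv <- function(path) {
  utils::read.delim(path, check.names = FALSE)
}
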