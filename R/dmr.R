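#' Distance-binned autocorrelation of EWAS p-values
#'
#' Converts p-values to probit scores `z = qnorm(1 - p)` and, for every
#' intra-chromosome probe pair whose distance falls in a bin, computes the
#' Pearson correlation of the paired z scores. This is the correlation
#' structure used to combine nearby p-values without over-counting
#' spatially redundant evidence.
#'
#' @param p Per-probe p-values.
#' @param chrom,pos Probe chromosome and position (positions must be sorted
#'   within chromosome).
#' @param max_dist Maximum pair distance considered (bp).
#' @param bin_width Bin width (bp).
#' @return Object of class `AcfEstimate`: data.frame with `bin_lo`,
#'   `bin_hi`, `correlation`, `n_pairs`, `sparse` (TRUE when a bin had < 10
#'   pairs and its correlation was set to 0). A zero-distance bin with
#'   correlation 1 leads the table.
#' @export
estimate_acf <- function(p, chrom, pos, max_dist = 1000, bin_width = 50) {
  if (max_dist <= 0) stop("max_dist must be positive")
  stopifnot(length(p) == length(chrom), length(p) == length(pos),
            bin_width > 0)
  ok <- stats::ave(pos, chrom, FUN = function(x) all(diff(x) >= 0))
  if (any(ok == 0)) stop("positions must be sorted within chromosome")
  z <- stats::qnorm(1 - pmin(pmax(p, 1e-15), 1 - 1e-15))
  acc_d <- list(); acc_1 <- list(); acc_2 <- list()
  for (cc in unique(chrom)) {
    idx <- which(chrom == cc)
    po <- pos[idx]; zz <- z[idx]
    nn <- length(idx)
    if (nn < 2) next
    j_hi <- findInterval(po + max_dist, po)
    for (i in seq_len(nn - 1)) {
      if (j_hi[i] <= i) next
      js <- (i + 1):j_hi[i]
      m <- length(acc_d) + 1
      acc_d[[m]] <- po[js] - po[i]
      acc_1[[m]] <- rep(zz[i], length(js))
      acc_2[[m]] <- zz[js]
    }
  }
  d_all <- unlist(acc_d); z1 <- unlist(acc_1); z2 <- unlist(acc_2)
  if (is.null(d_all)) { d_all <- numeric(0); z1 <- z2 <- numeric(0) }
  edges <- seq(0, max_dist, by = bin_width)
  if (edges[length(edges)] < max_dist) edges <- c(edges, max_dist)
  nb <- length(edges) - 1
  out <- data.frame(bin_lo = c(0, edges[-length(edges)]),
                    bin_hi = c(0, edges[-1]),
                    correlation = c(1, rep(0, nb)),
                    n_pairs = c(NA_integer_, rep(0L, nb)),
                    sparse = c(FALSE, rep(FALSE, nb)))
  if (length(d_all)) {
    bin <- findInterval(d_all, edges, left.open = TRUE,
                        rightmost.closed = TRUE)
    for (b in seq_len(nb)) {
      sel <- bin == b
      npairs <- sum(sel)
      out$n_pairs[b + 1] <- npairs
      if (npairs >= 10) {
        r <- stats::cor(z1[sel], z2[sel])
        out$correlation[b + 1] <- if (is.na(r)) 0 else max(min(r, 1), -1)
      } else {
        out$sparse[b + 1] <- npairs > 0
      }
    }
  }
  structure(out, bin_width = bin_width, max_dist = max_dist,
            class = c("AcfEstimate", class(out)))
}

# correlation for a vector of pairwise distances under an AcfEstimate;
# distances beyond max_dist get 0, distance 0 gets 1
acf_correlation <- function(acf, dist) {
  bw <- attr(acf, "bin_width")
  md <- attr(acf, "max_dist")
  out <- numeric(length(dist))
  out[dist == 0] <- 1
  pos <- dist > 0 & dist <= md
  if (any(pos)) {
    b <- pmin(ceiling(dist[pos] / bw), nrow(acf) - 1L)
    out[pos] <- acf$correlation[b + 1L]
  }
  out
}

#' Stouffer-Liptak combination of correlated p-values
#'
#' Combines k p-values through summed normal quantiles normalized by the
#' correlation structure: `z_i = qnorm(1 - p_i)`, combined
#' `z = sum(z_i) / sqrt(sum(sigma))`, returned as `1 - pnorm(z)`. With k = 1
#' the input p is returned unchanged; with full redundancy (all correlations
#' 1) the combination degenerates to the common p. A non-positive-definite
#' sigma is repaired to the nearest correlation matrix (flagged via the
#' `"repaired"` attribute).
#'
#' @param p Vector of k p-values.
#' @param sigma k x k correlation matrix (unit diagonal).
#' @return Combined p-value.
#' @export
stouffer_liptak <- function(p, sigma = NULL) {
  k <- length(p)
  if (k == 0) stop("no p-values to combine")
  if (k == 1) return(p)
  if (is.null(sigma)) sigma <- diag(k)
  stopifnot(nrow(sigma) == k, ncol(sigma) == k)
  repaired <- FALSE
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    sigma <- as.matrix(Matrix::nearPD(sigma, corr = TRUE)$mat)
    repaired <- TRUE
  }
  z <- stats::qnorm(1 - pmin(pmax(p, 1e-15), 1 - 1e-15))
  denom <- sum(sigma)
  if (denom <= 0) denom <- k
  out <- 1 - stats::pnorm(sum(z) / sqrt(denom))
  attr(out, "repaired") <- repaired
  out
}

#' Neighborhood-corrected site p-values
#'
#' Replaces each site's p-value by the Stouffer-Liptak combination of all
#' sites within `window` bp on the same chromosome (itself included), with
#' pairwise correlations looked up from the distance-binned ACF. Sites with
#' no neighbors keep their p unchanged; concordant low p-values among
#' near-independent neighbors strengthen (lower) the corrected p.
#'
#' @inheritParams estimate_acf
#' @param acf An [estimate_acf()] result.
#' @param window Neighborhood half-width in bp.
#' @return Vector of adjusted p-values, same order as the input.
#' @export
adjust_site_pvalues <- function(p, chrom, pos, acf, window = 1000) {
  n <- length(p)
  out <- numeric(n)
  for (cc in unique(chrom)) {
    idx <- which(chrom == cc)
    po <- pos[idx]
    lo <- findInterval(po - window, po, left.open = TRUE) + 1L
    hi <- findInterval(po + window, po)
    for (t in seq_along(idx)) {
      nb <- lo[t]:hi[t]
      pp <- p[idx[nb]]
      if (length(nb) == 1) { out[idx[t]] <- pp; next }
      dd <- abs(outer(po[nb], po[nb], `-`))
      sig <- matrix(acf_correlation(acf, as.vector(dd)), length(nb))
      diag(sig) <- 1
      out[idx[t]] <- as.numeric(stouffer_liptak(pp, sig))
    }
  }
  out
}

#' Find candidate regions from corrected site p-values
#'
#' Maximal runs of probes with adjusted p below `seed_p`, consecutive
#' members at most `max_gap` bp apart, and at least two probes. Each
#' region's combined p is the Stouffer-Liptak combination over its member
#' sites with ACF-derived correlations.
#'
#' @param adjusted_p Site p-values from [adjust_site_pvalues()].
#' @inheritParams adjust_site_pvalues
#' @param seed_p Seed threshold for region membership.
#' @param max_gap Maximum within-region gap (bp).
#' @param probe_ids Optional probe ids carried into the output.
#' @return data.frame of regions: `chromosome`, `start`, `end` (1-based
#'   inclusive), `n_probes`, `probe_ids` (comma-joined), `p_combined`.
#' @export
find_regions <- function(adjusted_p, chrom, pos, seed_p = 0.05,
                         max_gap = 1000, acf = NULL, probe_ids = NULL) {
  if (is.null(probe_ids)) probe_ids <- as.character(seq_along(adjusted_p))
  regions <- list()
  for (cc in unique(chrom)) {
    idx <- which(chrom == cc)
    po <- pos[idx]
    sig <- adjusted_p[idx] < seed_p
    run_id <- 0L; current <- integer(0)
    flush <- function(members) {
      if (length(members) < 2) return(NULL)
      pp <- adjusted_p[idx[members]]
      dd <- abs(outer(po[members], po[members], `-`))
      sg <- if (is.null(acf)) diag(length(members)) else
        matrix(acf_correlation(acf, as.vector(dd)), length(members))
      diag(sg) <- 1
      data.frame(chromosome = cc, start = min(po[members]),
                 end = max(po[members]), n_probes = length(members),
                 probe_ids = paste(probe_ids[idx[members]], collapse = ","),
                 p_combined = as.numeric(stouffer_liptak(pp, sg)))
    }
    for (t in seq_along(idx)) {
      if (sig[t]) {
        if (length(current) && po[t] - po[current[length(current)]] >
            max_gap) {
          regions[[length(regions) + 1]] <- flush(current)
          current <- integer(0)
        }
        current <- c(current, t)
      } else if (length(current)) {
        regions[[length(regions) + 1]] <- flush(current)
        current <- integer(0)
      }
    }
    if (length(current)) regions[[length(regions) + 1]] <- flush(current)
  }
  regions <- Filter(Negate(is.null), regions)
  if (!length(regions))
    return(data.frame(chromosome = character(), start = numeric(),
                      end = numeric(), n_probes = integer(),
                      probe_ids = character(), p_combined = numeric()))
  out <- do.call(rbind, regions)
  rownames(out) <- NULL
  out
}

#' Sidak correction of a region p-value for effective search space
#'
#' `p_sidak = 1 - (1 - p_combined)^(total_span / region_span)`, capped at 1.
#' The exponent is the number of region-sized windows in the searched span,
#' i.e. the effective number of tests of this size.
#'
#' @param p_combined Combined region p-value.
#' @param region_span Region width in bp.
#' @param total_span Total searched bp (probe positions +/- window, summed
#'   over chromosomes; see [total_probe_span()]).
#' @return Corrected p-value.
#' @export
region_pvalue_sidak <- function(p_combined, region_span, total_span) {
  stopifnot(region_span > 0, total_span > 0)
  m <- total_span / region_span
  pmin(1, 1 - (1 - p_combined)^m)
}

#' Effective search space for the Sidak correction
#'
#' Total bp covered by the union of probe-centered windows (pos +/- window)
#' per chromosome, summed. This is the searched span, not genome length.
#'
#' @inheritParams estimate_acf
#' @param window Half-width in bp.
#' @return Total covered bp.
#' @export
total_probe_span <- function(chrom, pos, window = 1000) {
  total <- 0
  for (cc in unique(chrom)) {
    po <- sort(pos[chrom == cc])
    s <- pmax(po - window, 1); e <- po + window
    cov <- 0; cur_s <- s[1]; cur_e <- e[1]
    for (i in seq_along(po)[-1]) {
      if (s[i] <= cur_e) cur_e <- max(cur_e, e[i])
      else { cov <- cov + (cur_e - cur_s + 1); cur_s <- s[i]; cur_e <- e[i] }
    }
    total <- total + cov + (cur_e - cur_s + 1)
  }
  total
}

#' Call differentially methylated regions from an EWAS
#'
#' Full regional pipeline: distance-binned ACF estimation, neighborhood
#' p-value correction, seeded region finding, Stouffer-Liptak region
#' combination, Sidak search-space correction, and BH-FDR across regions.
#'
#' @param ewas An `EWASResult` from [run_ewas()].
#' @param manifest Annotated probe manifest (same probes as `ewas`).
#' @param seed_p Seed threshold (default 0.05).
#' @param window Neighborhood / gap width in bp (default 1000).
#' @param max_gap Maximum within-region gap (default `window`).
#' @param bin_width,max_dist ACF binning (defaults 50 bp bins to 1000 bp).
#' @return data.frame of class `Region` with `chromosome`, `start`, `end`,
#'   `n_probes`, `probe_ids`, `p_combined`, `p_sidak`, `q`; the ACF estimate
#'   is kept in the `"acf"` attribute.
#' @export
call_dmrs <- function(ewas, manifest, seed_p = 0.05, window = 1000,
                      max_gap = window, bin_width = 50, max_dist = 1000) {
  stopifnot(identical(ewas$probe_id, manifest$probe_id))
  ok <- ewas$ok & !is.na(ewas$p)
  p <- ewas$p[ok]
  chrom <- manifest$chromosome[ok]
  pos <- manifest$position[ok]
  ids <- ewas$probe_id[ok]
  acf <- estimate_acf(p, chrom, pos, max_dist = max_dist,
                      bin_width = bin_width)
  adj <- adjust_site_pvalues(p, chrom, pos, acf, window = window)
  # the adjusted p of nearby sites share underlying observations, so the
  # region-level combination needs the autocorrelation of the *adjusted*
  # p-values, extended to twice the window (beyond which neighborhoods no
  # longer overlap)
  acf_adj <- estimate_acf(adj, chrom, pos, max_dist = 2 * window,
                          bin_width = bin_width)
  reg <- find_regions(adj, chrom, pos, seed_p = seed_p, max_gap = max_gap,
                      acf = acf_adj, probe_ids = ids)
  if (nrow(reg)) {
    total <- total_probe_span(chrom, pos, window = window)
    reg$p_sidak <- region_pvalue_sidak(reg$p_combined,
                                       reg$end - reg$start + 1, total)
    reg$q <- bh_fdr(reg$p_sidak)
  } else {
    reg$p_sidak <- numeric(0)
    reg$q <- numeric(0)
  }
  attr(reg, "acf") <- acf
  class(reg) <- c("Region", class(reg))
  reg
}

#' Write regions as BED (0-based half-open)
#'
#' @param regions A `Region` data.frame from [call_dmrs()].
#' @param path Output file.
#' @export
write_regions_bed <- function(regions, path) {
  bed <- data.frame(chrom = regions$chromosome,
                    start = regions$start - 1L,
                    end = regions$end,
                    name = sprintf("dmr_%d", seq_len(nrow(regions))),
                    score = round(-10 * log10(pmax(regions$p_sidak,
                                                   1e-30))))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
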