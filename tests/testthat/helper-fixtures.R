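# Shared fixture builders. Everything is generated in code at test time.

# a tiny fully-annotated manifest with hand-set QC flags
toy_manifest <- function() {
  data.frame(
    probe_id = sprintf("cg%02d", 1:10),
    chromosome = rep(c("chr1", "chrX"), c(8, 2)),
    position = c(100, 200, 300, 1400, 2500, 3600, 4700, 5800, 100, 200),
    snp_3p_flag = c(FALSE, TRUE, rep(FALSE, 8)),
    snp_5p_flag = FALSE,
    sex_chromosome = rep(c(FALSE, TRUE), c(8, 2)),
    off_target = FALSE,
    detection_fail_fraction = c(0, 0, 0.5, rep(0, 7)),
    gene = NA_character_, category = NA_character_,
    stringsAsFactors = FALSE)
}

toy_dataset <- function(n_samples = 4, seed = 1) {
  man <- toy_manifest()
  set.seed(seed)
  vals <- matrix(rnorm(nrow(man) * n_samples), nrow(man), n_samples,
                 dimnames = list(man$probe_id,
                                 sprintf("S%02d", seq_len(n_samples))))
  samples <- data.frame(sample_id = colnames(vals),
                        ga = seq(250, by = 10, length.out = n_samples),
                        sex = rep(c("male", "female"),
                                  length.out = n_samples),
                        race = rep("A", n_samples))
  methylation_dataset(vals, "M", man, samples)
}

# a simple two-exon plus-strand gene for annotation fixtures:
# TSS 10000, exon1 10000-10200 (5'UTR 10000-10080), intron 10201-10999,
# exon2 11000-11400 (3'UTR 11320-11400), TES 11400
toy_gene_plus <- function() {
  gene_models(data.frame(
    gene = "TOY1", chromosome = "chr1", strand = "+",
    tss = 10000, tes = 11400,
    exon_starts = I(list(c(10000, 11000))),
    exon_ends = I(list(c(10200, 11400))),
    utr5_start = 10000, utr5_end = 10080,
    utr3_start = 11320, utr3_end = 11400))
}

# same structure on the minus strand: TSS 11400 (right end)
toy_gene_minus <- function() {
  gene_models(data.frame(
    gene = "TOY2", chromosome = "chr2", strand = "-",
    tss = 11400, tes = 10000,
    exon_starts = I(list(c(11000, 10000))),
    exon_ends = I(list(c(11400, 10200))),
    utr5_start = 11320, utr5_end = 11400,
    utr3_start = 10000, utr3_end = 10080))
}

# add a GA-proportional slope to `k` clustered probes (within `span` bp on
# one chromosome); returns the modified dataset plus the planted probe ids
plant_cluster <- function(ds, k = 5, slope = 0.02, span = 1000) {
  man <- ds$manifest
  found <- NULL
  for (cc in unique(man$chromosome)) {
    idx <- which(man$chromosome == cc)
    po <- man$position[idx]
    for (i in seq_along(idx)) {
      j <- which(po >= po[i] & po <= po[i] + span)
      if (length(j) >= k) { found <- idx[j[seq_len(k)]]; break }
    }
    if (!is.null(found)) break
  }
  stopifnot(!is.null(found))
  ga_c <- ds$samples$ga - mean(ds$samples$ga)
  ds$values[found, ] <- ds$values[found, ] + outer(rep(slope, k), ga_c)
  list(dataset = ds, planted_ids = man$probe_id[found])
}

# brute-force BH step-up (double loop), the independent oracle
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    rank_i <- which(ord == i)
    cands <- vapply(seq(rank_i, m), function(j) m * p[ord[j]] / j,
                    numeric(1))
    q[i] <- min(1, min(cands))
  }
  q
}

# region membership check: does any significant region contain a planted id
region_hits_planted <- function(regions, planted_ids, q_cut = 0.05) {
  hit <- regions[regions$q < q_cut, , drop = FALSE]
  if (!nrow(hit)) return(FALSE)
  any(vapply(strsplit(hit$probe_ids, ","),
             function(x) any(x %in% planted_ids), logical(1)))
}
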