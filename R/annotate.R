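#' Gene model table
#'
#' A minimal transcript-level gene model: TSS/TES, strand, exon structure and
#' (optionally) UTR intervals. Exons are ordered 5' to 3' along the strand.
#'
#' @param df A data.frame with columns `gene`, `chromosome`, `strand`
#'   (`"+"`/`"-"`), `tss`, `tes`, list columns `exon_starts` and `exon_ends`
#'   (numeric vectors, 5'->3' order), and optional `utr5_start`, `utr5_end`,
#'   `utr3_start`, `utr3_end` (NA when absent).
#' @return The validated data.frame with class `gene_models`.
#' @export
gene_models <- function(df) {
  need <- c("gene", "chromosome", "strand", "tss", "tes",
            "exon_starts", "exon_ends")
  if (!all(need %in% names(df)))
    stop("gene model table missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  if (!all(df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  for (u in c("utr5_start", "utr5_end", "utr3_start", "utr3_end"))
    if (is.null(df[[u]])) df[[u]] <- NA_real_
  class(df) <- c("gene_models", class(df))
  df
}

# label set, in precedence order (promoters first, intergenic last)
.category_levels <- c("Promoter (<=1kb)", "Promoter (1-2kb)", "Promoter (2-3kb)",
                      "5' UTR", "3' UTR", "1st Exon", "Other Exon",
                      "1st Intron", "Other Intron", "Downstream (<=300)",
                      "Distal Intergenic")

#' Functional category labels
#'
#' The eleven genomic-feature categories used for probe annotation and
#' enrichment, in precedence order.
#' @return Character vector of category names.
#' @export
functional_categories <- function() .category_levels

# category of one position relative to one gene model row
.categorize_one <- function(pos, g) {
  d <- if (g$strand == "+") pos - g$tss else g$tss - pos
  if (d < 0) {
    if (d >= -1000) return("Promoter (<=1kb)")
    if (d >= -2000) return("Promoter (1-2kb)")
    if (d >= -3000) return("Promoter (2-3kb)")
    return("Distal Intergenic")
  }
  in_iv <- function(s, e) !is.na(s) && !is.na(e) && pos >= s && pos <= e
  if (in_iv(g$utr5_start, g$utr5_end)) return("5' UTR")
  if (in_iv(g$utr3_start, g$utr3_end)) return("3' UTR")
  es <- g$exon_starts[[1]]; ee <- g$exon_ends[[1]]
  hit <- which(pos >= es & pos <= ee)
  if (length(hit)) return(if (1 %in% hit) "1st Exon" else "Other Exon")
  # gene body but not exonic -> intron; which intron, 5'->3'?
  left <- min(g$tss, g$tes); right <- max(g$tss, g$tes)
  if (pos >= left && pos <= right) {
    # intron index: number of exons fully 5' of the position
    n5 <- if (g$strand == "+") sum(ee < pos) else sum(es > pos)
    if (n5 >= 1)
      return(if (n5 == 1) "1st Intron" else "Other Intron")
    return("Distal Intergenic")  # between TSS and first exon (degenerate)
  }
  d_tes <- if (g$strand == "+") pos - g$tes else g$tes - pos
  if (d_tes > 0 && d_tes <= 300) return("Downstream (<=300)")
  "Distal Intergenic"
}

#' Assign probes to nearest genes and functional categories
#'
#' The nearest gene is the one with minimal absolute strand-aware TSS
#' distance (ties broken alphabetically by symbol); the functional category
#' is then determined relative to that gene. Promoter tiers cover upstream
#' distance bands (<=1 kb, 1-2 kb, 2-3 kb from the TSS); positions at or
#' downstream of the TSS fall through UTR, exon, intron and downstream
#' (<=300 bp past the TES) logic, defaulting to distal intergenic.
#'
#' @param chromosome Character vector of probe chromosomes.
#' @param position Numeric vector of probe positions (1-based bp).
#' @param models A [gene_models()] table.
#' @return data.frame with columns `gene` (NA when no gene on the
#'   chromosome), `category`, and `tss_distance` (signed, negative =
#'   upstream).
#' @export
assign_functional_category <- function(chromosome, position, models) {
  stopifnot(length(chromosome) == length(position))
  n <- length(position)
  gene <- rep(NA_character_, n)
  category <- rep("Distal Intergenic", n)
  tssd <- rep(NA_real_, n)
  by_chr <- split(seq_len(nrow(models)), models$chromosome)
  for (i in seq_len(n)) {
    idx <- by_chr[[chromosome[i]]]
    if (is.null(idx) || !length(idx)) next
    g <- models[idx, , drop = FALSE]
    d <- ifelse(g$strand == "+", position[i] - g$tss, g$tss - position[i])
    ord <- order(abs(d), g$gene)
    best <- ord[1]
    gene[i] <- g$gene[best]
    tssd[i] <- d[best]
    category[i] <- .categorize_one(position[i], g[best, , drop = FALSE])
  }
  data.frame(gene = gene, category = category, tss_distance = tssd,
             stringsAsFactors = FALSE)
}

#' Fill the gene/category columns of a probe manifest
#'
#' @param manifest Probe manifest data.frame with `chromosome`, `position`.
#' @param models A [gene_models()] table.
#' @return The manifest with `gene`, `category` and `tss_distance` columns
#'   (re)filled.
#' @export
annotate_probes <- function(manifest, models) {
  ann <- assign_functional_category(manifest$chromosome, manifest$position,
                                    models)
  manifest$gene <- ann$gene
  manifest$category <- ann$category
  manifest$tss_distance <- ann$tss_distance
  manifest
}

#' Hypergeometric enrichment of functional categories
#'
#' For each category, tests whether significant probes fall into it more
#' (overrepresentation) or less (underrepresentation) often than expected
#' from the category's share of the array background. With `K` background
#' probes in the category, `n` significant probes drawn from a background of
#' `N`, and `x` observed: `p_over = P(X >= x)` and `p_under = P(X <= x)` for
#' `X ~ Hypergeometric(N, K, n)`.
#'
#' @param sig_probe_ids Significant probe ids (subset of `all_probe_ids`).
#' @param all_probe_ids Background probe ids (the array after QC).
#' @param manifest Annotated manifest covering all background probes.
#' @return data.frame with one row per category present on the array:
#'   `category`, `observed`, `array_count`, `expected`, `p_under`, `p_over`.
#' @export
category_enrichment <- function(sig_probe_ids, all_probe_ids, manifest) {
  if (!all(sig_probe_ids %in% all_probe_ids))
    stop("significant probes must be a subset of the background")
  man <- manifest[match(all_probe_ids, manifest$probe_id), ]
  if (anyNA(man$probe_id)) stop("background probes missing from manifest")
  N <- length(all_probe_ids)
  n <- length(sig_probe_ids)
  sig_cat <- man$category[match(sig_probe_ids, man$probe_id)]
  cats <- intersect(.category_levels, unique(man$category))
  rows <- lapply(cats, function(cc) {
    K <- sum(man$category == cc)
    x <- sum(sig_cat == cc)
    data.frame(category = cc, observed = x, array_count = K,
               expected = n * K / N,
               p_under = stats::phyper(x, K, N - K, n),
               p_over = stats::phyper(x - 1, K, N - K, n,
                                      lower.tail = FALSE))
  })
  do.call(rbind, rows)
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file: one set per line, tab-separated
#'   `name<TAB>description<TAB>gene1<TAB>gene2...`.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(x) unique(x[-(1:2)]))
  names(sets) <- vapply(parts, `[`, character(1), 1)
  sets
}

#' Fisher-exact gene-set enrichment against an array background
#'
#' One-sided (enrichment) Fisher exact test per gene set on the 2x2 table
#' (in set / not in set) x (hit / not hit), restricted to the background of
#' genes annotated to probes on the array. Sets with no background overlap
#' are excluded and reported in the `note` column of the attribute
#' `excluded`.
#'
#' @param hit_genes Character vector of genes of interest (subset of
#'   `background_genes`).
#' @param background_genes All genes annotated to array probes.
#' @param gene_sets Named list of character vectors (see [read_gmt()]).
#' @return data.frame with `set`, `n_set_background`, `n_hit_in_set`,
#'   `n_hit`, `p`, `q` (BH across sets).
#' @export
gene_set_enrichment <- function(hit_genes, background_genes, gene_sets) {
  hit_genes <- unique(hit_genes)
  background_genes <- unique(background_genes)
  if (!all(hit_genes %in% background_genes))
    stop("hit genes must be a subset of the background")
  N <- length(background_genes)
  n <- length(hit_genes)
  keep <- vapply(gene_sets, function(s) any(s %in% background_genes),
                 logical(1))
  excluded <- names(gene_sets)[!keep]
  gene_sets <- gene_sets[keep]
  rows <- lapply(names(gene_sets), function(nm) {
    s <- intersect(gene_sets[[nm]], background_genes)
    K <- length(s)
    x <- length(intersect(s, hit_genes))
    tab <- matrix(c(x, K - x, n - x, N - K - (n - x)), nrow = 2)
    p <- stats::fisher.test(tab, alternative = "greater")$p.value
    data.frame(set = nm, n_set_background = K, n_hit_in_set = x, n_hit = n,
               p = p)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(set = character(), n_set_background =
    integer(), n_hit_in_set = integer(), n_hit = integer(), p = numeric())
  out$q <- bh_fdr(out$p)
  attr(out, "excluded") <- excluded
  out
}

#' Read / write gene models as TSV
#'
#' Plain-text schema for gene models: one row per gene with columns `gene`,
#' `chromosome`, `strand`, `tss`, `tes`, `exon_starts`, `exon_ends`
#' (comma-joined, 5'->3' order) and optional `utr5_start`, `utr5_end`,
#' `utr3_start`, `utr3_end`.
#'
#' @param models A [gene_models()] table.
#' @param path File path.
#' @export
write_gene_models <- function(models, path) {
  df <- as.data.frame(models)
  df$exon_starts <- vapply(df$exon_starts, paste, character(1),
                           collapse = ",")
  df$exon_ends <- vapply(df$exon_ends, paste, character(1),
                         collapse = ",")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_gene_models
#' @export
read_gene_models <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  df$exon_starts <- I(lapply(strsplit(as.character(df$exon_starts), ","),
                             as.numeric))
  df$exon_ends <- I(lapply(strsplit(as.character(df$exon_ends), ","),
                           as.numeric))
  gene_models(df)
}
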