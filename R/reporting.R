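#' Pearson chi-square test on a contingency table
#'
#' Yates continuity correction is applied if and only if the table is 2x2 -
#' the convention under which printed two-group cohort-description p-values
#' reproduce from their count tables.
#'
#' @param counts r x c matrix of non-negative counts (>= 2 rows and
#'   columns).
#' @return List of class `SummaryTest`: `kind`, `statistic`, `df`, `p`,
#'   `table`.
#' @export
chi_square_test <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (nrow(counts) < 2 || ncol(counts) < 2)
    stop("need at least a 2 x 2 table")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero marginal in contingency table")
  correct <- nrow(counts) == 2 && ncol(counts) == 2
  ct <- suppressWarnings(stats::chisq.test(counts, correct = correct))
  structure(list(kind = "chi-square", statistic = unname(ct$statistic),
                 df = unname(ct$parameter), p = ct$p.value, table = counts,
                 yates = correct),
            class = "SummaryTest")
}

#' Pooled two-sample t-test from group summaries
#'
#' Student's t with pooled variance, computed directly from (mean, SD, n)
#' per group so printed summary tables can be re-tested without raw data.
#' `df = n1 + n2 - 2`, two-sided p.
#'
#' @param mean1,sd1,n1 First group summary.
#' @param mean2,sd2,n2 Second group summary.
#' @return List of class `SummaryTest`.
#' @export
t_test_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop("need n >= 2 per group")
  if (sd1 <= 0 || sd2 <= 0) stop("SDs must be positive")
  df <- n1 + n2 - 2
  sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df)
  tval <- unname((mean1 - mean2) / (sp * sqrt(1 / n1 + 1 / n2)))
  structure(list(kind = "t-test", statistic = tval, df = df,
                 p = 2 * stats::pt(-abs(tval), df),
                 table = data.frame(group = c(1, 2),
                                    mean = c(mean1, mean2),
                                    sd = c(sd1, sd2), n = c(n1, n2))),
            class = "SummaryTest")
}

#' @export
print.SummaryTest <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, df = %s, p = %.4g\n", x$kind,
              x$statistic, format(x$df), x$p))
  invisible(x)
}

#' Cohort description table with two-group tests
#'
#' Stratifies sample metadata by a two-level grouping column (e.g. data
#' availability), applying [chi_square_test()] to categorical variables and
#' a pooled [t_test_from_summary()] to continuous ones. Missing values are
#' tolerated per variable (complete cases within each variable). Cells are
#' rendered "count (column %)" for categorical and "mean (SD)" for
#' continuous variables.
#'
#' @param samples data.frame of sample metadata.
#' @param group Name of the two-level grouping column.
#' @param variables Variables to summarize (default: every column except
#'   `sample_id` and the group).
#' @return List with `tests` (named list of `SummaryTest`) and `table`
#'   (formatted data.frame: variable, level, one column per group, p).
#' @export
build_table_one <- function(samples, group,
                            variables = setdiff(names(samples),
                                                c("sample_id", group))) {
  g <- samples[[group]]
  if (is.null(g)) stop("grouping column not found")
  glev <- sort(unique(stats::na.omit(as.character(g))))
  if (length(glev) != 2) stop("grouping column must have two levels")
  tests <- list()
  rows <- list()
  for (v in variables) {
    x <- samples[[v]]
    cc <- !is.na(x) & !is.na(g)
    xv <- x[cc]; gv <- as.character(g)[cc]
    if (is.numeric(xv) && length(unique(xv)) > 5) {
      s <- vapply(glev, function(l) {
        c(mean(xv[gv == l]), stats::sd(xv[gv == l]), sum(gv == l))
      }, numeric(3))
      tst <- t_test_from_summary(s[1, 1], s[2, 1], s[3, 1],
                                 s[1, 2], s[2, 2], s[3, 2])
      cells <- sprintf("%.2f (%.2f)", s[1, ], s[2, ])
      rows[[length(rows) + 1]] <- data.frame(
        variable = v, level = "", g1 = cells[1], g2 = cells[2],
        p = tst$p)
    } else {
      xv <- as.character(xv)
      tab <- table(xv, gv)[, glev, drop = FALSE]
      tst <- chi_square_test(tab)
      pct <- sweep(tab, 2, colSums(tab), "/") * 100
      for (li in seq_len(nrow(tab))) {
        rows[[length(rows) + 1]] <- data.frame(
          variable = v, level = rownames(tab)[li],
          g1 = sprintf("%d (%.1f)", tab[li, 1], pct[li, 1]),
          g2 = sprintf("%d (%.1f)", tab[li, 2], pct[li, 2]),
          p = if (li == 1) tst$p else NA_real_)
      }
    }
    tests[[v]] <- tst
  }
  table <- do.call(rbind, rows)
  names(table)[3:4] <- glev
  rownames(table) <- NULL
  list(tests = tests, table = table)
}

#' Write stage outputs with a reproducible run manifest
#'
#' Writes each object to `dir` (data.frames as TSV, lists as JSON) and a
#' `run_manifest.json` recording the package version, seed, configuration
#' hash, and an md5 digest per file, so identical configurations reproduce
#' identical manifests.
#'
#' @param dir Output directory (created if needed).
#' @param objects Named list of objects to write.
#' @param config List of run parameters (hashed into the manifest).
#' @param seed The run seed.
#' @return Invisibly, the manifest list.
#' @export
write_results <- function(dir, objects, config = list(), seed = NA) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (nm in names(objects)) {
    ob <- objects[[nm]]
    if (is.data.frame(ob)) {
      f <- file.path(dir, paste0(nm, ".tsv"))
      write_table_tsv(as.data.frame(ob), f)
    } else if (is.matrix(ob)) {
      f <- file.path(dir, paste0(nm, ".tsv"))
      write_matrix_tsv(ob, f)
    } else {
      f <- file.path(dir, paste0(nm, ".json"))
      jsonlite::write_json(ob, f, digits = NA, auto_unbox = TRUE,
                           force = TRUE)
    }
    files[nm] <- f
  }
  cfg_file <- tempfile()
  jsonlite::write_json(config, cfg_file, digits = NA, auto_unbox = TRUE,
                       force = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("gaclock")),
    seed = seed,
    config = config,
    config_hash = unname(tools::md5sum(cfg_file)),
    files = as.list(stats::setNames(unname(tools::md5sum(files)),
                                    basename(files))))
  unlink(cfg_file)
  jsonlite::write_json(manifest, file.path(dir, "run_manifest.json"),
                       digits = NA, auto_unbox = TRUE, force = TRUE)
  invisible(manifest)
}
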