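# Descriptive and nonparametric comparison of utility-class samples across
# terminologies. The data are ordinal (classes 1-5), so the primary
# descriptives are median and mode; mean and standard deviation are reported
# too, though less informative for ordinal data. Group comparison uses the
# Kruskal-Wallis test (omnibus) and pairwise two-sided Wilcoxon rank-sum
# tests at alpha = .05, with NO multiple-testing correction -- the report
# format mirrors the analysis as performed, and says so in its header.

#' Construct a utility-class sample
#'
#' @param x Named list: terminology -> non-empty integer vector of utility
#'   classes in `{1..5}`.
#' @return An object of class `class_sample`.
#' @export
class_sample <- function(x) {
  if (!is.list(x) || is.null(names(x)) || any(!nzchar(names(x)))) {
    stop("`x` must be a named list of class vectors", call. = FALSE)
  }
  x <- lapply(x, function(v) {
    v <- as.integer(v)
    if (!length(v)) stop("empty class vector", call. = FALSE)
    if (anyNA(v) || any(v < 1L | v > 5L)) {
      stop("utility classes must lie in 1..5", call. = FALSE)
    }
    v
  })
  structure(x, class = "class_sample")
}

#' Read a class sample from CSV
#'
#' Expected columns: `terminology`, `exam_code` (ignored beyond ordering),
#' `class`.
#'
#' @param path CSV path.
#' @return A [class_sample()].
#' @export
read_class_sample <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("terminology", "class") %in% names(df)))
  class_sample(split(as.integer(df$class), df$terminology))
}

.pooled_mean_ranks <- function(sample) {
  values <- unlist(sample, use.names = FALSE)
  group <- rep(names(sample), lengths(sample))
  r <- rank(values)  # mid-ranks for ties
  vapply(split(r, group)[names(sample)], mean, numeric(1))
}

#' Descriptive statistics per terminology
#'
#' Median, mode (ties broken toward the smaller class), arithmetic mean,
#' sample standard deviation, and Kruskal-Wallis mean rank on the pooled
#' mid-ranks.
#'
#' @param sample A [class_sample()].
#' @return `data.frame` with one row per terminology, columns `terminology`,
#'   `n`, `median`, `mode`, `mean`, `sd`, `mean_rank`.
#' @export
describe_classes <- function(sample) {
  sample <- class_sample(sample)
  mr <- .pooled_mean_ranks(sample)
  rows <- lapply(names(sample), function(g) {
    v <- sample[[g]]
    tab <- tabulate(v, nbins = 5L)
    data.frame(terminology = g, n = length(v),
               median = stats::median(v),
               mode = which.max(tab),  # which.max takes the first = smallest
               mean = mean(v),
               sd = stats::sd(v),
               mean_rank = mr[[g]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Kruskal-Wallis omnibus test across terminologies
#'
#' Tie-corrected H statistic with a chi-square reference distribution on
#' k - 1 degrees of freedom (via [stats::kruskal.test()]), plus the group
#' mean ranks.
#'
#' @param sample A [class_sample()] with at least two groups.
#' @return List with `H`, `df`, `p_value`, `mean_ranks`.
#' @export
kruskal_wallis <- function(sample) {
  sample <- class_sample(sample)
  if (length(sample) < 2L) stop("need at least two groups", call. = FALSE)
  values <- unlist(sample, use.names = FALSE)
  group <- factor(rep(names(sample), lengths(sample)), levels = names(sample))
  kt <- stats::kruskal.test(values, group)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value, mean_ranks = .pooled_mean_ranks(sample))
}

#' Pairwise Wilcoxon rank-sum tests
#'
#' Two-sided rank-sum test for every unordered pair of terminologies, using
#' the normal approximation with continuity and tie correction (appropriate
#' for samples of ~100 heavily tied ordinal values). No multiple-testing
#' correction is applied.
#'
#' @param sample A [class_sample()] with at least two groups.
#' @param alpha Significance level for the flags (default .05).
#' @return List with `p` (symmetric matrix, `NA` diagonal), `significant`
#'   (logical matrix, `p < alpha`), `alpha`.
#' @export
wilcoxon_pairwise <- function(sample, alpha = 0.05) {
  sample <- class_sample(sample)
  if (length(sample) < 2L) stop("need at least two groups", call. = FALSE)
  stopifnot(alpha > 0, alpha < 1)
  k <- length(sample)
  nm <- names(sample)
  p <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k - 1L)) {
    for (j in seq((i + 1L), k)) {
      pv <- stats::wilcox.test(sample[[i]], sample[[j]], exact = FALSE,
                               correct = TRUE)$p.value
      p[i, j] <- p[j, i] <- pv
    }
  }
  sig <- p < alpha
  list(p = p, significant = sig, alpha = alpha)
}

#' Assemble the full comparison report
#'
#' Combines the per-terminology descriptives, the Kruskal-Wallis omnibus
#' test, and the pairwise Wilcoxon matrix into one report object that can be
#' printed or written as CSV/JSON.
#'
#' @param sample A [class_sample()].
#' @param alpha Significance level (default .05).
#' @return An object of class `comparison_report`.
#' @export
comparison_report <- function(sample, alpha = 0.05) {
  sample <- class_sample(sample)
  structure(list(descriptives = describe_classes(sample),
                 kruskal = kruskal_wallis(sample),
                 pairwise = wilcoxon_pairwise(sample, alpha),
                 alpha = alpha,
                 note = paste("Unadjusted p-values: no multiple-testing",
                              "correction applied.")),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("Terminology utility class comparison\n")
  cat("(", x$note, ")\n\n", sep = "")
  print(x$descriptives, row.names = FALSE)
  cat(sprintf("\nKruskal-Wallis: H = %.3f, df = %d, p = %.4g\n",
              x$kruskal$H, x$kruskal$df, x$kruskal$p_value))
  cat(sprintf("\nPairwise Wilcoxon rank-sum p-values (alpha = %.2f):\n",
              x$alpha))
  print(round(x$pairwise$p, 4))
  invisible(x)
}

#' Render the report as a descriptive-statistics table
#'
#' One column per terminology, one row per statistic, matching the layout
#' used to summarise utility classes over a code sample.
#'
#' @param report A [comparison_report()].
#' @return `data.frame` with a `statistic` column followed by one column per
#'   terminology.
#' @export
report_table <- function(report) {
  stopifnot(inherits(report, "comparison_report"))
  d <- report$descriptives
  stats_rows <- rbind(
    median = d$median, mode = d$mode, mean = round(d$mean, 2),
    sd = round(d$sd, 2), mean_rank = round(d$mean_rank, 2))
  out <- data.frame(statistic = c("Median terminology utility class",
                                  "Mode terminology utility class",
                                  "Mean terminology utility class",
                                  "Standard deviation of mean",
                                  "Kruskal-Wallis mean rank class"),
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(d))) out[[d$terminology[i]]] <- stats_rows[, i]
  out
}

#' Write a comparison report to CSV (+ optional JSON)
#'
#' @param report A [comparison_report()].
#' @param csv_path Output CSV path (descriptives table; the pairwise matrix
#'   is appended below a header line).
#' @param json_path Optional JSON path for the full report.
#' @return `csv_path`, invisibly.
#' @export
write_report <- function(report, csv_path, json_path = NULL) {
  tbl <- report_table(report)
  con <- file(csv_path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", report$note), con)
  utils::write.csv(tbl, con, row.names = FALSE)
  writeLines("# pairwise Wilcoxon rank-sum p-values", con)
  utils::write.csv(as.data.frame(report$pairwise$p), con, row.names = TRUE)
  if (!is.null(json_path)) {
    jsonlite::write_json(list(
      descriptives = report$descriptives,
      kruskal = report$kruskal[c("H", "df", "p_value")],
      pairwise_p = as.data.frame(report$pairwise$p),
      alpha = report$alpha, note = report$note),
      json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(csv_path)
}
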