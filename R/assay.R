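#' ChIP-qPCR percent input
#'
#' Normalises an IP cycle threshold against diluted input chromatin:
#' the input Ct is first adjusted for the dilution
#' (`adjusted = ct_input - log2(1 / input_fraction)`), then
#' `percent = 100 * 2^(adjusted - ct_ip)`. One extra IP cycle halves the
#' percentage. The dilution factor is a required input (it is
#' experiment-specific).
#'
#' @param ct_ip IP cycle threshold(s), positive.
#' @param ct_input Input cycle threshold(s), positive.
#' @param input_fraction Fraction of chromatin used as input, in (0, 1].
#' @return Percent-input value(s).
#' @export
percent_input <- function(ct_ip, ct_input, input_fraction) {
  if (any(input_fraction <= 0) || any(input_fraction > 1)) {
    stop("input_fraction must lie in (0, 1]")
  }
  if (any(ct_ip <= 0) || any(ct_input <= 0) ||
      any(!is.finite(ct_ip)) || any(!is.finite(ct_input))) {
    stop("cycle thresholds must be finite and positive")
  }
  adjusted <- ct_input - log2(1 / input_fraction)
  100 * 2^(adjusted - ct_ip)
}

paired_result <- function(t, df, p, tail, log_scale, indeterminate = FALSE) {
  structure(list(t = t, df = df, p_value = p, tail = tail,
                 log_scale = log_scale, indeterminate = indeterminate),
            class = "paired_test_result")
}

#' @export
print.paired_test_result <- function(x, ...) {
  if (x$indeterminate) {
    cat("paired t-test: indeterminate (zero variance of the differences)\n")
  } else {
    cat(sprintf("paired t-test (%s%s-tailed): t = %.4g, df = %d, p = %.4g\n",
                if (x$log_scale) "ratio, " else "", x$tail, x$t, x$df,
                x$p_value))
  }
  invisible(x)
}

#' Ratio paired t-test
#'
#' The conventional realisation of a "ratio paired t-test": a paired t-test
#' on `log2(x_i / y_i)`. Base 2 matches qPCR cycle arithmetic. One-tailed
#' tests the alternative x > y (positive mean log-ratio). Zero variance of
#' the log-ratios yields an indeterminate result (flagged, no numeric p)
#' rather than a degenerate p-value.
#'
#' @param x,y Equal-length vectors of positive values, n >= 2.
#' @param tail `"two"` (default) or `"one"`.
#' @return A `paired_test_result`: `t`, `df = n - 1`, `p_value`, `tail`,
#'   `log_scale`, `indeterminate`.
#' @export
ratio_paired_ttest <- function(x, y, tail = c("two", "one")) {
  tail <- match.arg(tail)
  if (any(x <= 0) || any(y <= 0)) stop("ratio test needs positive values")
  paired_ttest(log2(x), log2(y), tail = tail, log_scale = TRUE)
}

#' Paired t-test on raw differences
#'
#' @inheritParams ratio_paired_ttest
#' @param log_scale Internal flag marking a log-ratio test.
#' @return A `paired_test_result`.
#' @export
paired_ttest <- function(x, y, tail = c("two", "one"), log_scale = FALSE) {
  tail <- match.arg(tail)
  if (length(x) != length(y)) stop("paired test needs equal lengths")
  if (length(x) < 2) stop("paired test needs n >= 2")
  d <- x - y
  if (stats::sd(d) == 0) {
    return(paired_result(NA_real_, length(d) - 1L, NA_real_, tail,
                         log_scale, indeterminate = TRUE))
  }
  alt <- if (tail == "one") "greater" else "two.sided"
  ht <- stats::t.test(x, y, paired = TRUE, alternative = alt)
  paired_result(unname(ht$statistic), as.integer(unname(ht$parameter)),
                ht$p.value, tail, log_scale)
}

#' Differential-expression threshold filter
#'
#' Filters a differential-expression results table at
#' `log2fc > lfc_min` and `padj < padj_max` (both strict). The
#' direction-aware variant (`direction = "absolute"`) uses
#' `|log2fc| > lfc_min`. Rows with a missing adjusted p-value are skipped
#' with a warning.
#'
#' @param table data.frame with columns `gene_id`, `log2fc`, `padj`.
#' @param lfc_min Log2 fold-change threshold (default 1.5).
#' @param padj_max Adjusted-p threshold (default 0.1).
#' @param direction `"up"` (default) or `"absolute"`.
#' @return Sorted character vector of passing gene ids.
#' @export
de_filter <- function(table, lfc_min = 1.5, padj_max = 0.1,
                      direction = c("up", "absolute")) {
  direction <- match.arg(direction)
  stopifnot(all(c("gene_id", "log2fc", "padj") %in% names(table)))
  miss <- is.na(table$padj)
  if (any(miss)) {
    warning(sum(miss), " row(s) with missing padj skipped")
    table <- table[!miss, , drop = FALSE]
  }
  lfc <- if (direction == "absolute") abs(table$log2fc) else table$log2fc
  sort(unique(table$gene_id[!is.na(lfc) & lfc > lfc_min &
                            table$padj < padj_max]))
}
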