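## Usage--expression and gene--gene correlation with an OLS regression
## line and a 95% mean-response confidence band.

#' Correlate two numeric vectors with a regression confidence band
#'
#' Pairwise-complete Pearson (default) or Spearman correlation with a
#' two-sided p-value; for Pearson the p comes from
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on n - 2 degrees of freedom.
#' An ordinary least-squares fit of `y ~ x` provides the regression line
#' and a mean-response confidence band at the requested level, evaluated
#' at the observed x values (the band widens away from `mean(x)`).
#'
#' @param x,y numeric vectors of equal length (pairs with any missing
#'   value are dropped).
#' @param method `"pearson"` (the default; the relationship studied is
#'   linear) or `"spearman"`.
#' @param level confidence level of the mean-response band (default 0.95).
#' @param log2_y if `TRUE`, y is transformed to `log2(y + 1)` before
#'   analysis (useful for TPM expression).
#' @return an object of class `"corr_result"`: list with `n`, `r`, `p`,
#'   `slope`, `intercept`, `method` and `band` (data.frame `x`, `fit`,
#'   `lwr`, `upr` sorted by x).
#' @export
correlate <- function(x, y, method = c("pearson", "spearman"),
                      level = 0.95, log2_y = FALSE) {
  method <- match.arg(method)
  .assert(length(x) == length(y), "x and y lengths differ")
  keep <- !is.na(x) & !is.na(y)
  x <- as.numeric(x[keep]); y <- as.numeric(y[keep])
  if (log2_y) y <- log2(y + 1)
  n <- length(x)
  .assert(n >= 3, "need >= 3 complete pairs, have %d", n)
  .assert(stats::sd(x) > 0, "x is constant; correlation undefined")
  .assert(stats::sd(y) > 0, "y is constant; correlation undefined")
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = method, alternative = "two.sided",
                    exact = FALSE))
  fit <- stats::lm(y ~ x)
  ord <- order(x)
  pred <- stats::predict(fit, newdata = data.frame(x = x[ord]),
                         interval = "confidence", level = level)
  structure(list(n = n, r = unname(ct$estimate), p = ct$p.value,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 method = method, level = level,
                 band = data.frame(x = x[ord], fit = pred[, "fit"],
                                   lwr = pred[, "lwr"], upr = pred[, "upr"])),
            class = "corr_result")
}

#' @export
print.corr_result <- function(x, ...) {
  cat(sprintf("corr_result (%s): n = %d, r = %.4f, p = %.3g, y = %.4g + %.4g x\n",
              x$method, x$n, x$r, x$p, x$intercept, x$slope))
  invisible(x)
}

#' Correlate two genes' expression rows
#'
#' Convenience wrapper of [correlate()] for evaluating co-regulation
#' between two genes from an expression matrix.
#'
#' @param expression an [expression_matrix()].
#' @param gene_a,gene_b feature ids present in the matrix.
#' @inheritParams correlate
#' @return a `"corr_result"`.
#' @export
correlate_genes <- function(expression, gene_a, gene_b,
                            method = c("pearson", "spearman"),
                            level = 0.95, log2_y = FALSE) {
  .assert(gene_a %in% rownames(expression), "unknown feature '%s'", gene_a)
  .assert(gene_b %in% rownames(expression), "unknown feature '%s'", gene_b)
  correlate(expression[gene_a, ], expression[gene_b, ],
            method = method, level = level, log2_y = log2_y)
}

#' Screen features for usage--expression correlation
#'
#' Matches features by id between a usage matrix and an expression
#' matrix, correlates each feature's usage with its expression over the
#' shared samples, and keeps features passing both gates
#' `|r| > r_min` and `p < alpha` (defaults 0.3 and 0.05). Results are
#' sorted by `|r|` descending. Optionally restricted to one group of a
#' [group_assignment()] or run per group.
#'
#' @param usage a [usage_matrix()] (features are gene/transcript ids that
#'   also appear in `expression`; see [gene_usage()]).
#' @param expression an [expression_matrix()].
#' @param r_min,alpha screen gates.
#' @param groups optional [group_assignment()]; when given, the screen is
#'   run within each group and a `group` column is added.
#' @inheritParams correlate
#' @return data.frame with columns `feature_x`, `feature_y`, `group`,
#'   `n`, `r`, `p`, `slope`, `intercept`.
#' @export
screen_correlated <- function(usage, expression, r_min = 0.3, alpha = 0.05,
                              groups = NULL, method = c("pearson", "spearman"),
                              log2_y = FALSE) {
  method <- match.arg(method)
  .assert(inherits(usage, "usage_matrix"), "usage must be a usage_matrix")
  shared <- intersect(colnames(usage$values), colnames(expression))
  .assert(length(shared) >= 3, "need >= 3 shared samples, have %d", length(shared))
  feats <- intersect(rownames(usage$values), rownames(expression))
  sample_sets <- if (is.null(groups)) list(all = shared) else {
    gs <- split(groups$sample_id, groups$group)
    lapply(gs, intersect, x = shared)
  }
  rows <- list()
  for (gname in names(sample_sets)) {
    ss <- sample_sets[[gname]]
    for (f in feats) {
      cr <- tryCatch(
        correlate(usage$values[f, ss], expression[f, ss],
                  method = method, log2_y = log2_y),
        error = function(e) NULL)
      if (is.null(cr)) next
      if (abs(cr$r) > r_min && cr$p < alpha) {
        rows[[length(rows) + 1L]] <- data.frame(
          feature_x = f, feature_y = f, group = gname, n = cr$n,
          r = cr$r, p = cr$p, slope = cr$slope, intercept = cr$intercept,
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- if (length(rows)) do.call(rbind, rows) else
    data.frame(feature_x = character(0), feature_y = character(0),
               group = character(0), n = integer(0), r = numeric(0),
               p = numeric(0), slope = numeric(0), intercept = numeric(0))
  res <- res[order(-abs(res$r)), ]
  rownames(res) <- NULL
  res
}
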