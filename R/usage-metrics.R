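## Differential APA usage: PAU computation, group mean differences
## (delta-PAU / delta-PDUI), nonparametric tests, BH adjustment and
## 3'UTR lengthening/shortening trend calls.

#' Compute PAU from transcript TPM values of one gene in one sample
#'
#' PolyA site usage (PAU) is the proportion of the gene's transcript
#' expression attributed to each APA isoform: `PAU_i = TPM_i / sum(TPM)`.
#' When the gene is entirely unexpressed (`sum(TPM) == 0`) all PAUs are
#' missing — absence of usage evidence is not zero usage.
#'
#' @param tpm non-negative TPM values of the gene's transcripts.
#' @return numeric vector of PAUs summing to 1, or all-`NA`.
#' @export
compute_pau <- function(tpm) {
  .assert(is.numeric(tpm), "TPM values must be numeric")
  .assert(all(tpm >= 0, na.rm = TRUE), "negative TPM values are invalid")
  tot <- sum(tpm, na.rm = TRUE)
  if (!is.finite(tot) || tot == 0) return(rep(NA_real_, length(tpm)))
  tpm / tot
}

.split_groups <- function(values, groups) {
  .assert(inherits(groups, "group_assignment"), "groups must be a group_assignment")
  v <- values[groups$sample_id]
  .assert(!any(is.na(names(v))), "usage values must be named by sample id")
  split(unname(v), groups$group)
}

#' Group mean difference of a usage row (delta-PAU / delta-PDUI)
#'
#' The lengthening/shortening effect size is the difference between the
#' group mean usage indices, `mean(group1) - mean(group2)` in the caller's
#' declared group order; missing values are dropped per group.
#'
#' @param values named numeric vector (one usage-matrix row, names are
#'   sample ids).
#' @param groups a [group_assignment()] with exactly 2 groups.
#' @return the signed mean difference, with attribute `groups` recording
#'   the order used.
#' @export
delta_usage <- function(values, groups) {
  gs <- .split_groups(values, groups)
  .assert(length(gs) == 2, "delta_usage() needs exactly 2 groups, got %d", length(gs))
  n <- vapply(gs, function(x) sum(!is.na(x)), integer(1))
  .assert(all(n >= 1), "group '%s' has no non-missing usage values",
          names(gs)[which(n < 1)[1]])
  d <- mean(gs[[1]], na.rm = TRUE) - mean(gs[[2]], na.rm = TRUE)
  attr(d, "groups") <- names(gs)
  d
}

#' Nonparametric differential usage test for one feature
#'
#' Two groups are compared with the two-sided Mann-Whitney (Wilcoxon
#' rank-sum) test — exact enumeration when both groups have at most 8
#' non-missing values and no ties, the normal approximation with tie
#' correction otherwise; more than two groups use the Kruskal-Wallis
#' test.
#'
#' @inheritParams delta_usage
#' @param groups a [group_assignment()] (2 or more groups).
#' @return list with `statistic`, `p`, and `method`.
#' @export
test_diff <- function(values, groups) {
  gs <- .split_groups(values, groups)
  gs <- lapply(gs, function(x) x[!is.na(x)])
  usable <- vapply(gs, function(x) length(x) >= 2, logical(1))
  .assert(sum(usable) >= 2, "need >= 2 groups with >= 2 non-missing values")
  gs <- gs[usable]
  if (length(unique(unlist(gs))) == 1L) {
    ## fully tied input: no rank information, statistic degenerates to 0
    stat <- if (length(gs) == 2) length(gs[[1]]) * length(gs[[2]]) / 2 else 0
    return(list(statistic = stat, p = 1,
                method = if (length(gs) == 2) "mann-whitney-degenerate"
                         else "kruskal-wallis"))
  }
  if (length(gs) == 2) {
    ties <- anyDuplicated(c(gs[[1]], gs[[2]])) > 0
    exact <- length(gs[[1]]) <= 8 && length(gs[[2]]) <= 8 && !ties
    wt <- suppressWarnings(
      stats::wilcox.test(gs[[1]], gs[[2]], alternative = "two.sided",
                         exact = exact, correct = !exact))
    list(statistic = unname(wt$statistic), p = wt$p.value,
         method = if (exact) "mann-whitney-exact" else "mann-whitney-normal")
  } else {
    kt <- stats::kruskal.test(gs)
    list(statistic = unname(kt$statistic), p = kt$p.value,
         method = "kruskal-wallis")
  }
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate control across all features tested in one
#' analysis run.
#'
#' @param p raw p-values in \[0,1\] (`NA` allowed, passed through).
#' @return adjusted q-values.
#' @export
adjust_bh <- function(p) {
  .assert(all(p >= 0 & p <= 1, na.rm = TRUE), "p-values must lie in [0,1]")
  stats::p.adjust(p, method = "BH")
}

#' Classify a 3'UTR length trend from effect size and significance
#'
#' Assumes "higher usage = longer 3'UTR" polarity (PDUI, or distal-site
#' PAU): a feature is called `lengthened` when `delta >= min_delta` and
#' `q < alpha`, `shortened` when `delta <= -min_delta` and `q < alpha`,
#' and `unchanged` otherwise.
#'
#' @param delta signed usage difference (group1 - group2).
#' @param q adjusted p-value.
#' @param min_delta minimum absolute effect size (default 0.1).
#' @param alpha significance level (default 0.05).
#' @return character vector over `{lengthened, shortened, unchanged}`.
#' @export
classify_trend <- function(delta, q, min_delta = 0.1, alpha = 0.05) {
  out <- rep("unchanged", length(delta))
  sig <- !is.na(q) & q < alpha & !is.na(delta)
  out[sig & delta >= min_delta] <- "lengthened"
  out[sig & delta <= -min_delta] <- "shortened"
  out
}

#' Split samples into top-n and bottom-n usage groups
#'
#' Used for high-vs-low usage comparisons (e.g. the top 30 and bottom 30
#' samples by PDUI). Ties at a boundary are broken by lexicographic
#' sample-id order so the split is deterministic across runs.
#'
#' @param values named numeric vector (usage row; names are sample ids).
#' @param n samples per group (default 30).
#' @return a [group_assignment()] with levels `c("low", "high")`.
#' @export
top_bottom_split <- function(values, n = 30) {
  v <- values[!is.na(values)]
  .assert(length(v) >= 2 * n,
          "need >= %d non-missing samples for a top/bottom-%d split, have %d",
          2 * n, n, length(v))
  o <- order(v, names(v))                    # value, then sample id: stable
  low <- names(v)[o[seq_len(n)]]
  high <- names(v)[o[seq.int(length(v) - n + 1, length(v))]]
  group_assignment(c(low, high), rep(c("low", "high"), each = n),
                   levels = c("low", "high"))
}

#' Differential APA usage across all features of a usage matrix
#'
#' Runs [delta_usage()] (2 groups) and [test_diff()] per feature, adjusts
#' p-values across the run with [adjust_bh()], and calls trends with
#' [classify_trend()]. Features where any group has fewer than 2
#' non-missing values are skipped and reported in the `skipped` attribute.
#'
#' @param usage a [usage_matrix()].
#' @param groups a [group_assignment()].
#' @param min_delta,alpha trend-call gates, see [classify_trend()].
#' @param gene_symbol optional named character vector feature id -> symbol.
#' @return data.frame with columns `feature_id`, `gene_symbol`,
#'   `mean_<group1>`, `mean_<group2>` (two-group case), `delta`,
#'   `statistic`, `p`, `q`, `trend`, `n1`, `n2`.
#' @export
diff_usage <- function(usage, groups, min_delta = 0.1, alpha = 0.05,
                       gene_symbol = NULL) {
  .assert(inherits(usage, "usage_matrix"), "usage must be a usage_matrix")
  shared <- intersect(colnames(usage$values), groups$sample_id)
  .assert(length(shared) > 0, "no shared samples between usage and groups")
  groups <- group_assignment(shared,
                             groups$group[match(shared, groups$sample_id)],
                             levels = levels(groups$group))
  lev <- levels(groups$group)
  two <- length(lev) == 2

  rows <- vector("list", nrow(usage$values))
  skipped <- character(0)
  for (i in seq_len(nrow(usage$values))) {
    fid <- rownames(usage$values)[i]
    v <- usage$values[i, ]
    gs <- lapply(.split_groups(v, groups), function(x) x[!is.na(x)])
    if (sum(lengths(gs) >= 2) < 2) {
      skipped <- c(skipped, fid)
      next
    }
    tt <- test_diff(v, groups)
    means <- vapply(gs, function(x) if (length(x)) mean(x) else NA_real_,
                    numeric(1))
    delta <- if (two) unname(means[1] - means[2]) else NA_real_
    rows[[i]] <- data.frame(
      feature_id = fid,
      gene_symbol = if (is.null(gene_symbol)) NA_character_
                    else unname(gene_symbol[fid]),
      mean1 = unname(means[1]), mean2 = unname(means[2]),
      delta = delta, statistic = tt$statistic, p = tt$p,
      n1 = length(gs[[1]]), n2 = length(gs[[2]]),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  .assert(!is.null(res), "no feature had enough usable values in every group")
  res$q <- adjust_bh(res$p)
  res$trend <- if (two) classify_trend(res$delta, res$q, min_delta, alpha)
               else "unchanged"
  names(res)[names(res) == "mean1"] <- paste0("mean_", lev[1])
  names(res)[names(res) == "mean2"] <- paste0("mean_", lev[2])
  res <- res[, c("feature_id", "gene_symbol",
                 paste0("mean_", lev[1:2]), "delta", "statistic",
                 "p", "q", "trend", "n1", "n2")]
  rownames(res) <- NULL
  attr(res, "skipped") <- skipped
  attr(res, "groups") <- lev
  res
}

#' Gene-level usage with "higher = longer" polarity
#'
#' For PAU data (per-site features) the gene-level usage index is the PAU
#' of the gene's distal-ranked site, so that higher values always mean a
#' longer 3'UTR and delta-PAU is sign-comparable with delta-PDUI. PDUI
#' data already has this polarity and is returned per feature unchanged.
#'
#' @param dataset an [apa_dataset()].
#' @return a [usage_matrix()] whose features are gene ids (PAU input) or
#'   the original features (PDUI input).
#' @export
gene_usage <- function(dataset) {
  .assert(inherits(dataset, "apa_dataset"), "dataset must be an apa_dataset")
  if (dataset$usage$kind != "PAU") return(dataset$usage)
  s <- dataset$sites
  distal <- s[s$rank %in% c("distal", "single") & s$site_id %in%
                rownames(dataset$usage$values), ]
  distal <- distal[!duplicated(distal$gene_id), ]
  m <- dataset$usage$values[distal$site_id, , drop = FALSE]
  rownames(m) <- distal$gene_id
  usage_matrix(m, kind = "PAU")
}
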