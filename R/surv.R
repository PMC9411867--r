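## APA-index survival analysis: median split on a usage row, Kaplan-Meier
## product-limit curves, two-group log-rank test and an O/E hazard-ratio
## estimate (Pike). No covariate model is fitted.

#' Split samples at the median of a usage row
#'
#' The median of the APA index is the threshold: samples with values at or
#' below the median form the `low` group, values strictly above form the
#' `high` group. The tie-at-median convention (ties go low) is
#' deterministic and keeps both groups non-empty for non-constant input.
#'
#' @param values named numeric vector (usage row; names are sample ids).
#' @return a [group_assignment()] with levels `c("low", "high")` and a
#'   `threshold` attribute.
#' @export
median_split <- function(values) {
  v <- values[!is.na(values)]
  .assert(length(v) >= 2, "need >= 2 non-missing values for a median split, have %d",
          length(v))
  .assert(stats::sd(v) > 0, "split undefined: all usage values are equal")
  med <- stats::median(v)
  g <- ifelse(v <= med, "low", "high")
  if (!any(g == "high")) {
    ## median equal to the maximum (heavy upper ties): put strict-max ties high
    g[v == max(v)] <- "high"
  }
  ga <- group_assignment(names(v), g, levels = c("low", "high"))
  attr(ga, "threshold") <- med
  ga
}

#' Kaplan-Meier product-limit estimate
#'
#' Right-censored survival curve: censored samples leave the risk set
#' without contributing an event step. The median survival time is the
#' earliest event time at which the curve drops to 0.5 or below,
#' and is `NA` when the curve never reaches 0.5.
#'
#' @param time non-negative follow-up times.
#' @param event 1 = event observed, 0 = censored.
#' @return list with `curve` (data.frame `time`, `n_risk`, `n_event`,
#'   `n_censor`, `surv`) and `median`.
#' @export
km_estimate <- function(time, event) {
  .assert(length(time) > 0, "empty survival input")
  .assert(all(time >= 0), "times must be >= 0")
  .assert(all(event %in% c(0, 1)), "event must be 0/1")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  curve <- data.frame(time = fit$time, n_risk = fit$n.risk,
                      n_event = fit$n.event, n_censor = fit$n.censor,
                      surv = fit$surv)
  hit <- which(curve$surv <= 0.5 & curve$n_event > 0)
  list(curve = curve,
       median = if (length(hit)) curve$time[hit[1]] else NA_real_)
}

#' Two-group log-rank test with an O/E hazard-ratio estimate
#'
#' Standard log-rank chi-square on 1 degree of freedom over the pooled
#' event-time risk sets; p from the upper chi-square tail. The hazard
#' ratio (second group vs first, i.e. high vs low for a median split) is
#' the Pike observed/expected estimate
#' `(O2/E2) / (O1/E1)`; it is flagged unstable when a group has no
#' events.
#'
#' @param time,event survival data over both groups.
#' @param group factor with exactly 2 levels (first = reference, e.g.
#'   `low`).
#' @return an object of class `"survival_result"`: list with `groups`,
#'   per-group `n`, `events`, `median`, plus `chi_square`, `p`, `hr`,
#'   `hr_stable`.
#' @export
logrank <- function(time, event, group) {
  group <- droplevels(as.factor(group))
  .assert(nlevels(group) == 2, "logrank() needs exactly 2 groups, got %d",
          nlevels(group))
  lev <- levels(group)
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group)
  chisq <- unname(sd_$chisq)
  p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  obs <- as.numeric(sd_$obs); expd <- as.numeric(sd_$exp)
  hr_stable <- all(obs > 0) && all(expd > 0)
  hr <- if (hr_stable) (obs[2] / expd[2]) / (obs[1] / expd[1]) else NA_real_
  med <- vapply(lev, function(l) {
    km_estimate(time[group == l], event[group == l])$median
  }, numeric(1))
  structure(list(groups = lev,
                 n = as.numeric(table(group)),
                 events = vapply(lev, function(l) sum(event[group == l]), numeric(1)),
                 median = med,
                 chi_square = chisq, p = p, hr = hr, hr_stable = hr_stable,
                 hr_polarity = sprintf("%s vs %s", lev[2], lev[1])),
            class = "survival_result")
}

#' @export
print.survival_result <- function(x, ...) {
  cat(sprintf("log-rank: chi-square = %.3f, p = %.3g; HR (%s) = %s\n",
              x$chi_square, x$p, x$hr_polarity,
              if (x$hr_stable) sprintf("%.3f", x$hr) else "unstable"))
  for (i in seq_along(x$groups)) {
    cat(sprintf("  %-6s n = %d, events = %d, median survival = %s\n",
                x$groups[i], x$n[i], x$events[i],
                ifelse(is.na(x$median[i]), "not reached", x$median[i])))
  }
  invisible(x)
}

#' Survival analysis of one APA feature
#'
#' Median-splits the samples on the feature's usage index and compares
#' the two groups with the log-rank test. Samples missing either the
#' usage value or survival data are dropped and recorded.
#'
#' @param values named numeric usage row (names are sample ids).
#' @param clinical a [clinical_table()].
#' @return a `"survival_result"` with extra elements `dropped` (sample
#'   ids excluded for missingness) and `threshold` (the median used).
#' @export
survival_by_apa <- function(values, clinical) {
  .assert(inherits(clinical, "clinical_table"), "clinical must be a clinical_table")
  cl <- clinical[!is.na(clinical$survival_time) & !is.na(clinical$event), ]
  usable <- intersect(names(values)[!is.na(values)], cl$sample_id)
  dropped <- setdiff(union(names(values), clinical$sample_id), usable)
  .assert(length(usable) >= 4,
          "need >= 4 samples with both usage and survival data, have %d",
          length(usable))
  split_ <- median_split(values[usable])
  cl <- cl[match(split_$sample_id, cl$sample_id), ]
  res <- logrank(cl$survival_time, cl$event, split_$group)
  res$dropped <- dropped
  res$threshold <- attr(split_, "threshold")
  res
}

#' Flatten survival results to an exportable table
#'
#' @param results a `"survival_result"` or list of them (named by
#'   feature id).
#' @return data.frame with columns `feature_id`, `n_low`, `n_high`,
#'   `events_low`, `events_high`, `median_low`, `median_high`,
#'   `chi_square`, `p`, `hr`.
#' @export
survival_table <- function(results) {
  if (inherits(results, "survival_result")) results <- list(feature = results)
  do.call(rbind, lapply(names(results), function(fid) {
    x <- results[[fid]]
    data.frame(feature_id = fid, n_low = x$n[1], n_high = x$n[2],
               events_low = x$events[1], events_high = x$events[2],
               median_low = x$median[1], median_high = x$median[2],
               chi_square = x$chi_square, p = x$p, hr = x$hr,
               stringsAsFactors = FALSE)
  }))
}
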