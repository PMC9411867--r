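## Synthetic APA data with known ground truth: usage matrices with injected
## group shifts, expression rows coupled to usage at a target correlation,
## survival times coupled to usage at a chosen hazard ratio, and fixture
## writers emitting the QAPA / DaPars / generic dialects.

#' Generate a usage matrix with injected group differences
#'
#' Baseline per-feature usage is uniform on \[0.2, 0.8\]; every sample
#' gets gaussian noise (`noise_sd`) and values are clipped to \[0,1\].
#' For a fraction `frac_affected` of features the injected group
#' difference is `delta`, defined as `mean(group1) - mean(group2)` before
#' noise and clipping (the second group's mean is shifted by `-delta`),
#' so `delta = -0.3` emulates 3'UTR shortening in group 1. Null features
#' have no shift.
#'
#' @param n_features number of features (default 500).
#' @param n_per_group samples per group (default 30; groups `g1`, `g2`).
#' @param frac_affected fraction of features carrying the shift
#'   (default 0.2).
#' @param delta injected usage difference in \[-1, 1\] (default -0.3).
#' @param noise_sd gaussian noise standard deviation (default 0.1).
#' @param missing_rate fraction of cells set to missing (default 0).
#' @param seed integer seed; identical seeds give identical output.
#' @return list with `usage` (a [usage_matrix()], kind PDUI), `groups`
#'   (a [group_assignment()] with levels `c("g1", "g2")`) and `truth`
#'   (data.frame `feature_id`, `true_delta`, `affected`).
#' @export
gen_usage <- function(n_features = 500, n_per_group = 30,
                      frac_affected = 0.2, delta = -0.3, noise_sd = 0.1,
                      missing_rate = 0, seed = 1) {
  .assert(n_features >= 1 && n_per_group >= 1, "empty design")
  .assert(delta >= -1 && delta <= 1, "delta must lie in [-1, 1]")
  .assert(noise_sd > 0, "noise_sd must be > 0")
  set.seed(seed)
  fid <- sprintf("G%04d", seq_len(n_features))
  samples <- c(sprintf("s1_%03d", seq_len(n_per_group)),
               sprintf("s2_%03d", seq_len(n_per_group)))
  grp <- rep(c("g1", "g2"), each = n_per_group)
  n_aff <- round(frac_affected * n_features)
  affected <- seq_len(n_features) <= n_aff     # fixed ids, shuffled values anyway
  base <- stats::runif(n_features, 0.2, 0.8)
  mu <- matrix(rep(base, times = 2 * n_per_group), nrow = n_features)
  mu[affected, grp == "g2"] <- mu[affected, grp == "g2"] - delta
  vals <- mu + matrix(stats::rnorm(n_features * 2 * n_per_group, sd = noise_sd),
                      nrow = n_features)
  vals <- pmin(pmax(vals, 0), 1)
  if (missing_rate > 0) {
    vals[matrix(stats::runif(length(vals)) < missing_rate, nrow = n_features)] <- NA
  }
  vals <- round(vals, 6)
  dimnames(vals) <- list(fid, samples)
  list(usage = usage_matrix(vals, kind = "PDUI"),
       groups = group_assignment(samples, grp, levels = c("g1", "g2")),
       truth = data.frame(feature_id = fid,
                          true_delta = ifelse(affected, delta, 0),
                          affected = affected, stringsAsFactors = FALSE))
}

#' Generate an expression row coupled to a usage row
#'
#' Expression is a linear function of usage plus gaussian noise whose
#' variance is calibrated so the expected sample correlation equals
#' `target_r` (achieved within about 0.1 at n >= 100). The scale mimics
#' TPM: intercept 50, slope 100 (sign of `target_r`), clipped at 0.
#'
#' @param usage numeric usage row.
#' @param target_r target Pearson correlation in \[-1, 1\].
#' @param seed integer seed.
#' @return numeric expression vector, named like `usage`.
#' @export
gen_coupled_expression <- function(usage, target_r, seed = 1) {
  .assert(abs(target_r) <= 1, "target_r must lie in [-1, 1]")
  set.seed(seed)
  a <- 100 * sign(target_r)
  s_u <- stats::sd(usage)
  expr <- if (target_r == 0) {
    50 + stats::rnorm(length(usage), sd = 20)
  } else {
    noise_sd <- abs(a) * s_u * sqrt(1 / target_r^2 - 1)
    50 + a * usage + stats::rnorm(length(usage), sd = noise_sd)
  }
  expr <- pmax(expr, 0)
  names(expr) <- names(usage)
  round(expr, 6)
}

#' Generate survival data coupled to a usage row
#'
#' Exponential survival with a log-hazard proportional to the
#' standardized usage: a sample one usage-SD above the mean has `hr`
#' times the baseline hazard (`hr = 1` gives a null relationship).
#' Censoring is independent exponential at rate
#' `lambda_0 * censor_rate / (1 - censor_rate)`, which censors roughly
#' the stated fraction under the null.
#'
#' @param usage numeric usage row.
#' @param hr per-SD hazard ratio (> 0).
#' @param baseline_scale mean baseline survival time (default 365, i.e.
#'   time in days).
#' @param censor_rate target censoring fraction in \[0, 1) (default 0.2).
#' @param seed integer seed.
#' @return data.frame with `sample_id` (names of `usage`), `time`,
#'   `event`.
#' @export
gen_coupled_survival <- function(usage, hr, baseline_scale = 365,
                                 censor_rate = 0.2, seed = 1) {
  .assert(hr > 0, "hr must be > 0")
  .assert(censor_rate >= 0 && censor_rate < 1, "censor_rate must lie in [0, 1)")
  set.seed(seed)
  z <- as.numeric(scale(usage))
  lambda0 <- 1 / baseline_scale
  rate <- lambda0 * hr^z
  t_event <- stats::rexp(length(usage), rate)
  if (censor_rate > 0) {
    t_cens <- stats::rexp(length(usage), lambda0 * censor_rate / (1 - censor_rate))
    data.frame(sample_id = names(usage) %||% as.character(seq_along(usage)),
               time = round(pmin(t_event, t_cens), 4),
               event = as.integer(t_event <= t_cens),
               stringsAsFactors = FALSE)
  } else {
    data.frame(sample_id = names(usage) %||% as.character(seq_along(usage)),
               time = round(t_event, 4), event = 1L, stringsAsFactors = FALSE)
  }
}

#' Write a generated usage dataset as a dialect fixture file
#'
#' Emits a file that round-trips through the matching parser: the QAPA
#' dialect writes one gene with a distal and a proximal isoform per
#' feature (distal PAU = the generated usage, proximal PAU = its
#' complement, TPM = 100 x PAU), the DaPars dialect one transcript row
#' per feature with PDUI sample columns, and the generic dialect the
#' documented fixed columns plus `_usage` sample columns. A ground-truth
#' TSV is written alongside.
#'
#' @param sim result of [gen_usage()].
#' @param dialect `"qapa"`, `"dapars"` or `"generic"`.
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths (`data`, `truth`).
#' @export
write_fixture <- function(sim, dialect = c("qapa", "dapars", "generic"),
                          dir = ".") {
  dialect <- match.arg(dialect)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  u <- sim$usage$values
  fid <- rownames(u)
  n <- length(fid)
  samples <- colnames(u)
  ## deterministic coordinates: one gene block per feature on chr1, strands
  ## alternating so both coordinate conventions are exercised
  b <- 1000000L + seq_len(n) * 10000L
  strand <- rep(c("+", "-"), length.out = n)
  prox_pos <- ifelse(strand == "+", b + 200L, b + 1801L)
  dist_pos <- ifelse(strand == "+", b + 1500L, b + 501L)
  data_path <- file.path(dir, paste0(dialect, "_fixture.tsv"))

  if (dialect == "qapa") {
    rows <- lapply(seq_len(n), function(i) {
      if (strand[i] == "+") {
        us <- rep(b[i] + 1L, 2); ue <- c(dist_pos[i], prox_pos[i])
      } else {
        us <- c(dist_pos[i], prox_pos[i]); ue <- rep(b[i] + 2000L, 2)
      }
      df <- data.frame(
        APA_ID = paste0(fid[i], c("_1_D", "_2_P")),
        Transcript = paste0(fid[i], c("_T1", "_T2")),
        Gene = fid[i], Gene_Name = paste0("SYM", fid[i]),
        Chr = "chr1", Strand = strand[i],
        UTR3.Start = us, UTR3.End = ue, Length = ue - us + 1L,
        Num_Events = 2L, stringsAsFactors = FALSE)
      pau <- rbind(u[i, ], 1 - u[i, ])
      tpm <- 100 * pau
      for (j in seq_along(samples)) {
        df[[paste0(samples[j], "_TPM")]] <- round(tpm[, j], 6)
        df[[paste0(samples[j], "_PAU")]] <- round(pau[, j], 6)
      }
      df
    })
    utils::write.table(do.call(rbind, rows), data_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else if (dialect == "dapars") {
    loc_start <- ifelse(strand == "+", b + 1L, dist_pos)
    loc_end <- ifelse(strand == "+", dist_pos, b + 2000L)
    df <- data.frame(
      Gene = paste(fid, fid, "chr1", strand, sep = "|"),
      fit_value = 0, Predicted_Proximal_APA = prox_pos,
      Loci = sprintf("chr1:%d-%d", loc_start, loc_end),
      stringsAsFactors = FALSE)
    for (j in seq_along(samples)) df[[paste0(samples[j], "_PDUI")]] <- u[, j]
    utils::write.table(df, data_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    df <- data.frame(feature_id = fid, gene_id = fid,
                     gene_symbol = paste0("SYM", fid), chrom = "chr1",
                     strand = strand, proximal_pos = prox_pos,
                     distal_pos = dist_pos, stringsAsFactors = FALSE)
    for (j in seq_along(samples)) df[[paste0(samples[j], "_usage")]] <- u[, j]
    utils::write.table(df, data_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  truth_path <- file.path(dir, "truth.tsv")
  write_results_tsv(sim$truth, truth_path)
  c(data = data_path, truth = truth_path)
}

#' A small worked-example fixture in the QAPA dialect
#'
#' Encodes a minus-strand two-isoform gene (JAK1-like, synthetic usage
#' values at the published site coordinates chr1:64833213 distal /
#' chr1:64834454 proximal, proximal 3'UTR length 107 bp) plus a
#' plus-strand demo gene, with four samples of PAU/TPM columns. Used in
#' the package examples and tests.
#'
#' @return data.frame in the QAPA output layout (write with
#'   [write_results_tsv()] and read back with [parse_qapa()]).
#' @export
jak1_fixture <- function() {
  pau_d <- c(0.82, 0.74, 0.31, 0.22)        # distal-isoform PAU, 4 samples
  tot <- c(50, 60, 40, 30)                  # gene TPM per sample
  samples <- paste0("s", 1:4)
  df <- data.frame(
    APA_ID = c("JAK1_1_D", "JAK1_2_P", "DEMO1_1_P", "DEMO1_2_D"),
    Transcript = c("JAK1_T1", "JAK1_T2", "DEMO1_T1", "DEMO1_T2"),
    Gene = c("ENSG_JAK1", "ENSG_JAK1", "ENSG_DEMO1", "ENSG_DEMO1"),
    Gene_Name = c("JAK1", "JAK1", "DEMO1", "DEMO1"),
    Chr = c("chr1", "chr1", "chr2", "chr2"),
    Strand = c("-", "-", "+", "+"),
    UTR3.Start = c(64833213L, 64834454L, 5001L, 5001L),
    UTR3.End = c(64834560L, 64834560L, 5100L, 5400L),
    Length = c(1348L, 107L, 100L, 400L),
    Num_Events = 2L, stringsAsFactors = FALSE)
  pau <- rbind(pau_d, 1 - pau_d, 1 - pau_d, pau_d)
  for (j in seq_along(samples)) {
    df[[paste0(samples[j], "_TPM")]] <- round(tot[j] * pau[, j], 4)
    df[[paste0(samples[j], "_PAU")]] <- pau[, j]
  }
  df
}
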