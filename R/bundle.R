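## Project bundles and the subcommand layer behind the `apakit` CLI.
## A bundle is a plain directory of normalized TSVs plus a JSON manifest
## (counts + checksums) -- transparent and diff-able, with no binary
## container. All subcommands write TSV results and are deterministic for
## identical inputs and seeds.

.write_usage_tsv <- function(usage, path) {
  df <- data.frame(feature_id = rownames(usage$values),
                   usage$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_results_tsv(df, path)
}

.read_usage_tsv <- function(path, kind) {
  df <- .read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  usage_matrix(m, kind = kind)
}

#' Ingest APA, expression and clinical files into a project bundle
#'
#' Parses the inputs, reconciles sample ids, and writes a normalized
#' bundle directory: `sites.tsv`, `utrs.tsv`, `usage.tsv`, optional
#' `expression.tsv` and `clinical.tsv`, plus `manifest.json` recording
#' the dialect, usage kind, table sizes and md5 checksums. Samples
#' missing from the clinical table are listed in the manifest, not
#' dropped.
#'
#' @param apa_file path to the APA quantification table.
#' @param dialect `"qapa"`, `"dapars"` or `"generic"`.
#' @param out_dir bundle directory to create.
#' @param expression_file optional expression TSV (see
#'   [parse_expression()]).
#' @param clinical_file optional clinical TSV (see [parse_clinical()]).
#' @param time_column,event_column,time_unit clinical column mapping.
#' @return the bundle directory, invisibly.
#' @export
apa_ingest <- function(apa_file, dialect = c("qapa", "dapars", "generic"),
                       out_dir, expression_file = NULL, clinical_file = NULL,
                       time_column = "survival_time", event_column = "event",
                       time_unit = "days") {
  dialect <- match.arg(dialect)
  ds <- switch(dialect, qapa = parse_qapa(apa_file),
               dapars = parse_dapars(apa_file),
               generic = parse_generic(apa_file))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_results_tsv(as.data.frame(ds$sites), file.path(out_dir, "sites.tsv"))
  write_results_tsv(as.data.frame(ds$utrs), file.path(out_dir, "utrs.tsv"))
  .write_usage_tsv(ds$usage, file.path(out_dir, "usage.tsv"))
  files <- c("sites.tsv", "utrs.tsv", "usage.tsv")

  if (!is.null(expression_file)) {
    expr <- parse_expression(expression_file)
    df <- data.frame(feature_id = rownames(expr), unclass(expr),
                     check.names = FALSE, stringsAsFactors = FALSE)
    write_results_tsv(df, file.path(out_dir, "expression.tsv"))
    files <- c(files, "expression.tsv")
  } else if (!is.null(ds$expression)) {
    df <- data.frame(feature_id = rownames(ds$expression),
                     unclass(ds$expression), check.names = FALSE,
                     stringsAsFactors = FALSE)
    write_results_tsv(df, file.path(out_dir, "expression.tsv"))
    files <- c(files, "expression.tsv")
  }

  unmatched_clinical <- character(0)
  if (!is.null(clinical_file)) {
    cl <- parse_clinical(clinical_file, time_column, event_column, time_unit)
    overlap <- intersect(cl$sample_id, colnames(ds$usage$values))
    .assert(length(overlap) > 0,
            "zero overlapping samples between APA data and clinical table")
    unmatched_clinical <- setdiff(colnames(ds$usage$values), cl$sample_id)
    if (length(unmatched_clinical)) {
      warning(sprintf("%d sample(s) missing from the clinical table: %s",
                      length(unmatched_clinical),
                      paste(utils::head(unmatched_clinical, 10), collapse = ", ")))
    }
    write_results_tsv(as.data.frame(cl), file.path(out_dir, "clinical.tsv"))
    files <- c(files, "clinical.tsv")
  }

  manifest <- list(
    source = ds$source, usage_kind = ds$usage$kind,
    n_sites = nrow(ds$sites), n_features = nrow(ds$usage$values),
    n_samples = ncol(ds$usage$values),
    time_unit = if (!is.null(clinical_file)) time_unit else NULL,
    samples_missing_clinical = unmatched_clinical,
    checksums = as.list(tools::md5sum(file.path(out_dir, files))))
  names(manifest$checksums) <- files
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(out_dir)
}

#' Load a project bundle written by [apa_ingest()]
#'
#' @param dir bundle directory.
#' @return list with `dataset` (an [apa_dataset()]), `clinical`
#'   (a [clinical_table()] or `NULL`) and `manifest`.
#' @export
read_bundle <- function(dir) {
  mf_path <- file.path(dir, "manifest.json")
  .assert(file.exists(mf_path), "no manifest.json in '%s'; not a bundle", dir)
  mf <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  sites <- .read_tsv(file.path(dir, "sites.tsv"))
  class(sites) <- c("apa_sites", "data.frame")
  utrs <- .read_tsv(file.path(dir, "utrs.tsv"))
  class(utrs) <- c("utr_regions", "data.frame")
  usage <- .read_usage_tsv(file.path(dir, "usage.tsv"), kind = mf$usage_kind)
  expr <- NULL
  if (file.exists(file.path(dir, "expression.tsv"))) {
    expr <- parse_expression(file.path(dir, "expression.tsv"))
  }
  cl <- NULL
  if (file.exists(file.path(dir, "clinical.tsv"))) {
    cl <- parse_clinical(file.path(dir, "clinical.tsv"),
                         time_unit = mf$time_unit %||% "days")
  }
  ds <- apa_dataset(sites, utrs, usage, expression = expr, source = mf$source)
  list(dataset = ds, clinical = cl, manifest = mf)
}

.bundle_groups <- function(bundle, group_column = NULL, group_samples = NULL) {
  if (!is.null(group_samples)) {
    .assert(is.list(group_samples) && length(group_samples) >= 2 &&
              !is.null(names(group_samples)),
            "group_samples must be a named list of >= 2 sample-id vectors")
    return(group_assignment(unlist(group_samples, use.names = FALSE),
                            rep(names(group_samples), lengths(group_samples)),
                            levels = names(group_samples)))
  }
  .assert(!is.null(bundle$clinical), "no clinical table in bundle; cannot group")
  .assert(group_column %in% names(bundle$clinical),
          "grouping column '%s' not in clinical table", group_column)
  keep <- !is.na(bundle$clinical[[group_column]])
  group_assignment(bundle$clinical$sample_id[keep],
                   bundle$clinical[[group_column]][keep])
}

#' Differential APA usage over a bundle
#'
#' Runs [diff_usage()] on the bundle's gene-level usage (see
#' [gene_usage()]) with groups taken from a clinical column or explicit
#' sample lists, and writes `diff.tsv` in the output directory.
#'
#' @param bundle_dir bundle directory from [apa_ingest()].
#' @param group_column clinical column defining the groups.
#' @param group_samples alternatively, a named list of sample-id vectors.
#' @param out_dir output directory (default: the bundle).
#' @inheritParams diff_usage
#' @return the result data.frame, invisibly.
#' @export
apa_diff <- function(bundle_dir, group_column = NULL, group_samples = NULL,
                     min_delta = 0.1, alpha = 0.05, out_dir = bundle_dir) {
  b <- read_bundle(bundle_dir)
  groups <- .bundle_groups(b, group_column, group_samples)
  gu <- gene_usage(b$dataset)
  sym <- b$dataset$sites$gene_symbol
  names(sym) <- b$dataset$sites$gene_id
  sym <- sym[!duplicated(names(sym))]
  res <- diff_usage(gu, groups, min_delta = min_delta, alpha = alpha,
                    gene_symbol = sym)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_results_tsv(res, file.path(out_dir, "diff.tsv"))
  invisible(res)
}

#' Usage--expression correlation screen over a bundle
#'
#' Matches gene-level usage with the bundle's expression matrix, applies
#' [screen_correlated()], and writes `corr.tsv`.
#'
#' @inheritParams apa_diff
#' @inheritParams screen_correlated
#' @return the result data.frame, invisibly.
#' @export
apa_corr <- function(bundle_dir, r_min = 0.3, alpha = 0.05,
                     method = "pearson", log2_y = FALSE,
                     out_dir = bundle_dir) {
  b <- read_bundle(bundle_dir)
  .assert(!is.null(b$dataset$expression), "bundle has no expression matrix")
  gu <- gene_usage(b$dataset)
  res <- screen_correlated(gu, b$dataset$expression, r_min = r_min,
                           alpha = alpha, method = method, log2_y = log2_y)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_results_tsv(res, file.path(out_dir, "corr.tsv"))
  invisible(res)
}

#' APA-index survival analysis over a bundle
#'
#' Median-splits the samples on one feature's gene-level usage and runs
#' the log-rank comparison; writes `surv.tsv` (summary) and
#' `km_curves.tsv` (per-group step-function points for plotting).
#'
#' @inheritParams apa_diff
#' @param feature feature id (gene id for PAU bundles, transcript/feature
#'   id for PDUI bundles).
#' @return the `"survival_result"`, invisibly.
#' @export
apa_surv <- function(bundle_dir, feature, out_dir = bundle_dir) {
  b <- read_bundle(bundle_dir)
  .assert(!is.null(b$clinical), "bundle has no clinical table")
  gu <- gene_usage(b$dataset)
  .assert(feature %in% rownames(gu$values), "unknown feature '%s'%s", feature,
          { near <- agrep(feature, rownames(gu$values), max.distance = 0.2,
                          value = TRUE)
            if (length(near)) paste0("; nearest matches: ",
                                     paste(utils::head(near, 3), collapse = ", "))
            else "" })
  res <- survival_by_apa(gu$values[feature, ], b$clinical)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_results_tsv(.surv_table_named(res, feature),
                    file.path(out_dir, "surv.tsv"))
  ## per-group KM curves for plotting
  split_ <- median_split(gu$values[feature, intersect(
    colnames(gu$values), b$clinical$sample_id[!is.na(b$clinical$survival_time)])])
  cl <- b$clinical[match(split_$sample_id, b$clinical$sample_id), ]
  curves <- do.call(rbind, lapply(levels(split_$group), function(g) {
    sel <- split_$group == g
    km <- km_estimate(cl$survival_time[sel], cl$event[sel])
    cbind(group = g, km$curve)
  }))
  write_results_tsv(curves, file.path(out_dir, "km_curves.tsv"))
  invisible(res)
}

.surv_table_named <- function(res, feature) {
  tab <- survival_table(stats::setNames(list(res), feature))
  tab
}

#' Annotate a bundle's sites with motifs and track overlaps
#'
#' Scans upstream windows from a FASTA for polyadenylation-signal motifs
#' (writes `motifs.tsv`) and/or overlaps sites with BED tracks (writes
#' `overlaps.tsv`).
#'
#' @inheritParams apa_diff
#' @param fasta optional FASTA with the reference sequences.
#' @param beds optional named character vector of BED paths.
#' @param window,motifs see [scan_upstream_motifs()].
#' @return list with `motifs` and `overlaps` (either may be `NULL`),
#'   invisibly.
#' @export
apa_annotate <- function(bundle_dir, fasta = NULL, beds = NULL,
                         window = 100, motifs = c("AATAAA", "ATTAAA", "TGTA"),
                         out_dir = bundle_dir) {
  b <- read_bundle(bundle_dir)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hits <- olaps <- NULL
  if (!is.null(fasta)) {
    hits <- scan_sites_fasta(b$dataset$sites, fasta, window = window,
                             motifs = motifs)
    write_results_tsv(hits, file.path(out_dir, "motifs.tsv"))
  }
  if (length(beds)) {
    if (is.null(names(beds))) names(beds) <- basename(beds)
    rows <- list()
    for (tn in names(beds)) {
      track <- parse_bed(beds[[tn]])
      ov <- overlap_tracks(b$dataset$sites, track)
      for (i in seq_along(ov)) {
        if (length(ov[[i]])) {
          rows[[length(rows) + 1L]] <- data.frame(
            site_id = b$dataset$sites$site_id[i], track = tn,
            feature = ov[[i]], stringsAsFactors = FALSE)
        }
      }
    }
    olaps <- if (length(rows)) do.call(rbind, rows) else
      data.frame(site_id = character(0), track = character(0),
                 feature = character(0))
    write_results_tsv(olaps, file.path(out_dir, "overlaps.tsv"))
  }
  invisible(list(motifs = hits, overlaps = olaps))
}

#' Generate a complete synthetic project (fixture + expression +
#' clinical)
#'
#' Produces a dialect fixture via [gen_usage()]/[write_fixture()], an
#' expression table whose first `n_coupled` features are coupled to
#' their usage at `target_r`, and a clinical table whose survival is
#' coupled to the first feature's usage at `hr`.
#'
#' @inheritParams gen_usage
#' @param dialect fixture dialect.
#' @param target_r usage--expression coupling for the coupled features.
#' @param n_coupled number of expression-coupled features (default 1).
#' @param hr per-SD hazard ratio tying survival to feature 1.
#' @param out_dir output directory.
#' @return named vector of written paths, invisibly.
#' @export
apa_simulate <- function(out_dir, dialect = c("qapa", "dapars", "generic"),
                         n_features = 100, n_per_group = 30,
                         frac_affected = 0.2, delta = -0.3, noise_sd = 0.1,
                         missing_rate = 0, target_r = 0.7, n_coupled = 1,
                         hr = 1, seed = 1) {
  dialect <- match.arg(dialect)
  sim <- gen_usage(n_features, n_per_group, frac_affected, delta, noise_sd,
                   missing_rate, seed = seed)
  paths <- write_fixture(sim, dialect, out_dir)
  u <- sim$usage$values
  expr <- t(vapply(seq_len(nrow(u)), function(i) {
    r <- if (i <= n_coupled) target_r else 0
    gen_coupled_expression(u[i, ], r, seed = seed + i)
  }, numeric(ncol(u))))
  dimnames(expr) <- dimnames(u)
  expr_df <- data.frame(feature_id = rownames(expr), expr,
                        check.names = FALSE, stringsAsFactors = FALSE)
  write_results_tsv(expr_df, file.path(out_dir, "expression.tsv"))
  surv <- gen_coupled_survival(u[1, ], hr = hr, seed = seed + 10000)
  cl <- data.frame(sample_id = surv$sample_id,
                   group = sub("_.*$", "", surv$sample_id),
                   survival_time = surv$time, event = surv$event,
                   stringsAsFactors = FALSE)
  write_results_tsv(cl, file.path(out_dir, "clinical.tsv"))
  invisible(c(paths, expression = file.path(out_dir, "expression.tsv"),
              clinical = file.path(out_dir, "clinical.tsv")))
}
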