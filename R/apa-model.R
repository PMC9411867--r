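#' apakit: analysis toolkit for alternative polyadenylation usage data
#'
#' Alternative polyadenylation (APA) produces mRNA isoforms that differ in
#' their 3'UTR length. Quantification tools report per-sample usage indices
#' in \[0,1\]: QAPA reports PAU (polyA site usage, the fraction of a gene's
#' transcript expression attributed to one isoform) and DaPars reports PDUI
#' (the fraction of transcripts using the distal site, so that 1 means an
#' all-long 3'UTR). apakit reads both dialects into one strand-aware model
#' and provides differential usage testing, lengthening/shortening calls,
#' usage--expression correlation, APA-index survival analysis, motif
#' scanning and track annotation.
#'
#' @keywords internal
"_PACKAGE"

## ---- validation helpers ------------------------------------------------

`%||%` <- function(a, b) if (is.null(a)) b else a

.assert <- function(ok, ...) {
  if (!isTRUE(ok)) stop(sprintf(...), call. = FALSE)
}

.check_strand <- function(strand) {
  .assert(all(strand %in% c("+", "-")),
          "strand must be '+' or '-', got: %s",
          paste(setdiff(unique(strand), c("+", "-")), collapse = ", "))
}

## ---- APASite -----------------------------------------------------------

#' Construct a table of APA cleavage sites
#'
#' One row per cleavage site, with a 1-based genomic coordinate of the
#' cleavage position (matching how site coordinates are conventionally
#' printed) and a proximal/distal rank along the transcript's sense
#' direction. Use [order_sites()] to assign ranks from coordinates.
#'
#' @param site_id,gene_id,gene_symbol,transcript_id character identifiers.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param cleavage_pos 1-based genomic coordinate of the cleavage site.
#' @param rank one of `"proximal"`, `"distal"`, `"internal"`, `"single"`,
#'   or `NA` if not yet assigned.
#' @return a `data.frame` with class `"apa_sites"`.
#' @export
apa_sites <- function(site_id, gene_id, gene_symbol = NA_character_,
                      transcript_id = NA_character_, chrom, strand,
                      cleavage_pos, rank = NA_character_) {
  .check_strand(strand)
  .assert(all(cleavage_pos >= 1), "cleavage_pos must be >= 1")
  .assert(!anyDuplicated(site_id), "site_id values must be unique")
  ok_rank <- is.na(rank) | rank %in% c("proximal", "distal", "internal", "single")
  .assert(all(ok_rank), "invalid rank value(s): %s",
          paste(unique(rank[!ok_rank]), collapse = ", "))
  df <- data.frame(site_id = as.character(site_id),
                   gene_id = as.character(gene_id),
                   gene_symbol = as.character(gene_symbol),
                   transcript_id = as.character(transcript_id),
                   chrom = as.character(chrom),
                   strand = as.character(strand),
                   cleavage_pos = as.integer(cleavage_pos),
                   rank = as.character(rank),
                   stringsAsFactors = FALSE)
  class(df) <- c("apa_sites", "data.frame")
  df
}

#' Assign proximal/distal ranks to one gene's APA sites
#'
#' The proximal site is the cleavage site nearest the stop codon along the
#' transcript's sense direction; the distal site is the farthest. On the
#' plus strand ranks therefore increase with the genomic coordinate; on the
#' minus strand they increase as the coordinate decreases. Sites between
#' the two extremes are ranked `internal`; a lone site is ranked `single`.
#'
#' @param sites an [apa_sites()] table for a single gene (one strand, one
#'   chromosome).
#' @return the same table with `rank` filled in; row order is preserved.
#' @export
order_sites <- function(sites) {
  .assert(nrow(sites) >= 1, "order_sites() needs at least one site")
  .assert(length(unique(sites$gene_id)) == 1,
          "order_sites() expects sites of a single gene, got: %s",
          paste(unique(sites$gene_id), collapse = ", "))
  .assert(length(unique(sites$strand)) == 1 && length(unique(sites$chrom)) == 1,
          "sites of gene %s mix strands or chromosomes", sites$gene_id[1])
  if (nrow(sites) == 1L) {
    sites$rank <- "single"
    return(sites)
  }
  ## sense-direction order: + ascending, - descending genomic coordinate
  o <- order(sites$cleavage_pos, decreasing = sites$strand[1] == "-")
  rank <- rep("internal", nrow(sites))
  rank[o[1]] <- "proximal"
  rank[o[length(o)]] <- "distal"
  sites$rank <- rank
  sites
}

## ---- UTRRegion ---------------------------------------------------------

#' Construct a table of 3'UTR regions
#'
#' Intervals are 0-based half-open genomic coordinates; `length` is always
#' `end - start` in nucleotides.
#'
#' @param transcript_id,chrom,strand as in [apa_sites()].
#' @param start,end 0-based half-open genomic interval.
#' @return a `data.frame` with class `"utr_regions"` and a derived
#'   `length` column.
#' @export
utr_regions <- function(transcript_id, chrom, strand, start, end) {
  .check_strand(strand)
  .assert(all(start < end), "UTR start must be < end")
  df <- data.frame(transcript_id = as.character(transcript_id),
                   chrom = as.character(chrom),
                   strand = as.character(strand),
                   start = as.integer(start),
                   end = as.integer(end),
                   length = as.integer(end - start),
                   stringsAsFactors = FALSE)
  class(df) <- c("utr_regions", "data.frame")
  df
}

## ---- UsageMatrix -------------------------------------------------------

#' Construct a usage matrix (PAU or PDUI)
#'
#' Features x samples matrix of usage indices in \[0,1\]. Missing cells
#' (DaPars emits NA PDUIs for low-coverage samples) are kept as `NA` and
#' dropped pairwise by downstream statistics, never imputed.
#'
#' @param values numeric matrix with feature row names and sample column
#'   names; entries in \[0,1\] or `NA`.
#' @param kind `"PAU"` or `"PDUI"` (`"PDUI"` polarity means higher = more
#'   distal usage = longer 3'UTR).
#' @return a list of class `"usage_matrix"` with elements `values` and
#'   `kind`.
#' @export
usage_matrix <- function(values, kind = c("PAU", "PDUI")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  .assert(is.numeric(values), "usage values must be numeric")
  .assert(!is.null(rownames(values)) && !is.null(colnames(values)),
          "usage matrix needs feature row names and sample column names")
  .assert(!anyDuplicated(rownames(values)), "duplicate feature ids in usage matrix")
  .assert(!anyDuplicated(colnames(values)), "duplicate sample ids in usage matrix")
  bad <- which(!is.na(values) & (values < 0 | values > 1), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("usage value out of [0,1] at feature '%s', sample '%s': %g",
                 rownames(values)[bad[1, 1]], colnames(values)[bad[1, 2]],
                 values[bad[1, , drop = FALSE]]), call. = FALSE)
  }
  structure(list(values = values, kind = kind), class = "usage_matrix")
}

#' @export
print.usage_matrix <- function(x, ...) {
  cat(sprintf("usage_matrix (%s): %d features x %d samples, %.1f%% missing\n",
              x$kind, nrow(x$values), ncol(x$values),
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' @export
dim.usage_matrix <- function(x) dim(x$values)

## ---- ExpressionMatrix --------------------------------------------------

#' Construct an expression matrix (TPM)
#'
#' @param values numeric matrix, features x samples, entries TPM >= 0 or
#'   `NA`; feature row names, sample column names.
#' @return the validated matrix with class `"expression_matrix"`.
#' @export
expression_matrix <- function(values) {
  values <- as.matrix(values)
  .assert(is.numeric(values), "expression values must be numeric")
  .assert(!is.null(rownames(values)) && !is.null(colnames(values)),
          "expression matrix needs feature row names and sample column names")
  .assert(!anyDuplicated(rownames(values)), "duplicate feature ids in expression matrix")
  .assert(!anyDuplicated(colnames(values)), "duplicate sample ids in expression matrix")
  .assert(all(values >= 0, na.rm = TRUE), "TPM values must be >= 0")
  class(values) <- c("expression_matrix", class(values))
  values
}

## ---- ClinicalTable -----------------------------------------------------

#' Construct a clinical table with survival columns
#'
#' @param data a data.frame containing `sample_id` plus covariates.
#' @param time_column,event_column names of the survival-time and event
#'   columns; the event column is coerced to 0 (censored) / 1 (event).
#' @param time_unit declared unit of survival time (e.g. `"days"`,
#'   `"months"`); recorded, never converted.
#' @return a `data.frame` of class `"clinical_table"` with canonical
#'   `survival_time` and `event` columns and a `time_unit` attribute.
#' @export
clinical_table <- function(data, time_column = "survival_time",
                           event_column = "event", time_unit = "days") {
  .assert("sample_id" %in% names(data), "clinical table needs a 'sample_id' column")
  .assert(!anyDuplicated(data$sample_id),
          "duplicate sample_id in clinical table: %s",
          paste(unique(data$sample_id[duplicated(data$sample_id)]), collapse = ", "))
  .assert(time_column %in% names(data), "time column '%s' not found", time_column)
  .assert(event_column %in% names(data), "event column '%s' not found", event_column)
  tt <- as.numeric(data[[time_column]])
  .assert(all(tt >= 0, na.rm = TRUE), "survival_time must be >= 0")
  ev <- data[[event_column]]
  if (is.logical(ev)) ev <- as.integer(ev)
  ev <- as.integer(ev)
  .assert(all(ev %in% c(0L, 1L) | is.na(ev)), "event must be 0/1")
  data$survival_time <- tt
  data$event <- ev
  data$sample_id <- as.character(data$sample_id)
  attr(data, "time_unit") <- time_unit
  class(data) <- c("clinical_table", "data.frame")
  data
}

## ---- GroupAssignment ---------------------------------------------------

#' Assign samples to named groups
#'
#' @param sample_id character vector of sample identifiers (unique).
#' @param group group label per sample; at least one sample per label.
#' @param levels optional label order; the first level is "group 1" for
#'   signed effect sizes such as delta-PAU/delta-PDUI.
#' @return a `data.frame` of class `"group_assignment"` whose `group`
#'   column is a factor in the declared order.
#' @export
group_assignment <- function(sample_id, group, levels = NULL) {
  .assert(length(sample_id) == length(group),
          "sample_id and group lengths differ")
  .assert(!anyDuplicated(sample_id), "a sample may belong to at most one group")
  levels <- levels %||% unique(as.character(group))
  g <- factor(as.character(group), levels = levels)
  .assert(!any(is.na(g)), "group labels outside declared levels")
  .assert(all(table(g) > 0), "every group must be non-empty")
  .assert(nlevels(g) >= 2, "need at least 2 groups")
  df <- data.frame(sample_id = as.character(sample_id), group = g,
                   stringsAsFactors = FALSE)
  class(df) <- c("group_assignment", "data.frame")
  df
}

## ---- APADataset --------------------------------------------------------

#' Bundle sites, UTRs, usage and expression into one dataset
#'
#' @param sites an [apa_sites()] table.
#' @param utrs a [utr_regions()] table.
#' @param usage a [usage_matrix()].
#' @param expression optional [expression_matrix()] (transcript- or
#'   gene-level TPM).
#' @param source provenance: `"qapa"`, `"dapars"` or `"generic"`.
#' @return a list of class `"apa_dataset"`.
#' @export
apa_dataset <- function(sites, utrs, usage, expression = NULL,
                        source = c("generic", "qapa", "dapars")) {
  source <- match.arg(source)
  feat <- rownames(usage$values)
  known <- unique(c(sites$site_id, sites$gene_id, sites$transcript_id))
  missing <- setdiff(feat, known)
  .assert(length(missing) == 0,
          "usage feature(s) not present among sites: %s",
          paste(utils::head(missing, 5), collapse = ", "))
  structure(list(sites = sites, utrs = utrs, usage = usage,
                 expression = expression, source = source),
            class = "apa_dataset")
}

#' @export
print.apa_dataset <- function(x, ...) {
  cat(sprintf("apa_dataset [%s]: %d sites / %d genes, %d samples (%s)\n",
              x$source, nrow(x$sites), length(unique(x$sites$gene_id)),
              ncol(x$usage$values), x$usage$kind))
  invisible(x)
}
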