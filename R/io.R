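## Readers and writers for the two APA quantification dialects (QAPA, DaPars),
## a documented generic dialect, expression/clinical tables and BED tracks.
## All delimited I/O is tab-separated UTF-8 with a header row; genomic
## intervals are 0-based half-open internally and in BED, 1-based in printed
## site coordinates.

.read_tsv <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    check.names = FALSE, stringsAsFactors = FALSE,
                    na.strings = c("NA", ""), fileEncoding = "UTF-8")
}

## locate one mandatory column among case-insensitive synonyms
.find_col <- function(df, synonyms, what) {
  hit <- which(tolower(names(df)) %in% tolower(synonyms))
  .assert(length(hit) >= 1, "missing mandatory column '%s' (accepted names: %s)",
          what, paste(synonyms, collapse = ", "))
  names(df)[hit[1]]
}

## columns whose terminal token (after '.' or '_', or the whole name) equals
## `suffix`; returns named character vector sample_id -> column name
.suffix_cols <- function(df, suffix) {
  pat <- paste0("(^|[._])", suffix, "$")
  cols <- grep(pat, names(df), value = TRUE)               # case-sensitive
  ids <- sub(paste0("[._]?", suffix, "$"), "", cols)
  ids[ids == ""] <- cols[ids == ""]
  stats::setNames(cols, ids)
}

.check_usage_range <- function(df, cols, label) {
  for (cn in cols) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    bad <- which(!is.na(v) & (v < 0 | v > 1))
    if (length(bad)) {
      stop(sprintf("%s value out of [0,1] in column '%s', row %d: %g",
                   label, cn, bad[1], v[bad[1]]), call. = FALSE)
    }
  }
}

.num_matrix <- function(df, cols, rownames) {
  m <- vapply(unname(cols), function(cn) suppressWarnings(as.numeric(df[[cn]])),
              numeric(nrow(df)))
  m <- matrix(m, nrow = nrow(df),
              dimnames = list(rownames, names(cols)))
  m
}

#' Read a QAPA output table
#'
#' QAPA reports one row per 3'UTR isoform with the gene/transcript
#' identifiers, last-exon and 3'UTR coordinates, and per-sample columns
#' identified by a terminal `TPM` (transcript expression) or `PAU`
#' (polyA site usage) suffix; sample names are the column names with the
#' suffix stripped. Coordinates in the table are taken as 1-based
#' inclusive and converted to 0-based half-open internally. The cleavage
#' site of each isoform is the sense-strand 3' end of its 3'UTR.
#'
#' @param path path to the tab-separated QAPA output.
#' @return an [apa_dataset()] with `usage$kind == "PAU"` (features are APA
#'   site ids) and a transcript-level [expression_matrix()].
#' @export
parse_qapa <- function(path) {
  df <- .read_tsv(path)
  c_gene <- .find_col(df, c("Gene", "Gene_ID"), "gene ID")
  c_sym  <- .find_col(df, c("Gene_Name", "Gene_Symbol", "Symbol"), "gene symbol")
  c_tx   <- .find_col(df, c("Transcript", "Transcript_ID"), "transcript ID")
  c_chr  <- .find_col(df, c("Chr", "Chrom", "Chromosome"), "chromosome")
  c_apa  <- .find_col(df, c("APA_ID"), "APA ID")
  c_str  <- .find_col(df, c("Strand"), "strand")
  c_us   <- .find_col(df, c("UTR3.Start", "UTR3_Start", "UTR_Start"), "3'UTR start")
  c_ue   <- .find_col(df, c("UTR3.End", "UTR3_End", "UTR_End"), "3'UTR end")

  tpm_cols <- .suffix_cols(df, "TPM")
  pau_cols <- .suffix_cols(df, "PAU")
  .assert(length(pau_cols) > 0, "missing mandatory column 'PAU-suffixed sample usage'")
  .assert(length(tpm_cols) > 0, "missing mandatory column 'TPM-suffixed sample expression'")
  .assert(setequal(names(tpm_cols), names(pau_cols)),
          "TPM and PAU sample sets disagree (TPM-only: %s; PAU-only: %s)",
          paste(setdiff(names(tpm_cols), names(pau_cols)), collapse = ","),
          paste(setdiff(names(pau_cols), names(tpm_cols)), collapse = ","))
  .check_usage_range(df, pau_cols, "PAU")

  utr_start1 <- as.integer(df[[c_us]])
  utr_end1 <- as.integer(df[[c_ue]])
  strand <- as.character(df[[c_str]])
  cleavage <- ifelse(strand == "+", utr_end1, utr_start1)

  sites <- apa_sites(site_id = df[[c_apa]], gene_id = df[[c_gene]],
                     gene_symbol = df[[c_sym]], transcript_id = df[[c_tx]],
                     chrom = df[[c_chr]], strand = strand,
                     cleavage_pos = cleavage)
  sites <- do.call(rbind, lapply(split(sites, sites$gene_id), order_sites))
  sites <- sites[match(df[[c_apa]], sites$site_id), ]
  rownames(sites) <- NULL
  class(sites) <- c("apa_sites", "data.frame")

  utrs <- utr_regions(transcript_id = df[[c_tx]], chrom = df[[c_chr]],
                      strand = strand, start = utr_start1 - 1L, end = utr_end1)

  pau_cols <- pau_cols[order(names(pau_cols))]
  tpm_cols <- tpm_cols[names(pau_cols)]
  usage <- usage_matrix(.num_matrix(df, pau_cols, df[[c_apa]]), kind = "PAU")
  expr <- expression_matrix(.num_matrix(df, tpm_cols, df[[c_tx]]))
  apa_dataset(sites, utrs, usage, expression = expr, source = "qapa")
}

#' Read a DaPars output table
#'
#' DaPars reports one row per transcript with a composite gene field
#' (`transcript|gene|chrom|strand`), the predicted proximal APA
#' coordinate, the 3'UTR locus as `chrom:start-end`, and per-sample PDUI
#' columns identified by a terminal `PDUI` suffix. Each row yields two
#' sites: the predicted proximal site, and the distal site at the
#' sense-strand 3'UTR end (locus end on `+`, locus start on `-`). `NA`
#' PDUI cells are kept as missing values.
#'
#' @param path path to the tab-separated DaPars output.
#' @return an [apa_dataset()] with `usage$kind == "PDUI"` (features are
#'   transcript ids) and no expression matrix.
#' @export
parse_dapars <- function(path) {
  df <- .read_tsv(path)
  c_gene <- .find_col(df, c("Gene"), "composite gene field")
  c_prox <- .find_col(df, c("Predicted_Proximal_APA", "Proximal_APA"),
                      "predicted proximal APA")
  c_loci <- .find_col(df, c("Loci", "Locus"), "3'UTR locus")
  pdui_cols <- .suffix_cols(df, "PDUI")
  .assert(length(pdui_cols) > 0, "missing mandatory column 'PDUI-suffixed sample usage'")
  .check_usage_range(df, pdui_cols, "PDUI")

  parts <- strsplit(as.character(df[[c_gene]]), "|", fixed = TRUE)
  .assert(all(lengths(parts) == 4),
          "composite gene field must be 'transcript|gene|chrom|strand' (row %d)",
          which(lengths(parts) != 4)[1])
  tx <- vapply(parts, `[`, "", 1)
  gene <- vapply(parts, `[`, "", 2)
  chrom <- vapply(parts, `[`, "", 3)
  strand <- vapply(parts, `[`, "", 4)

  m <- regmatches(df[[c_loci]],
                  regexec("^([^:]+):([0-9]+)-([0-9]+)$", as.character(df[[c_loci]])))
  bad <- which(lengths(m) != 4)
  .assert(length(bad) == 0, "malformed 3'UTR locus '%s' in row %d",
          as.character(df[[c_loci]])[bad[1]], if (length(bad)) bad[1] else 0L)
  loc_start <- vapply(m, function(x) as.integer(x[3]), integer(1))
  loc_end <- vapply(m, function(x) as.integer(x[4]), integer(1))

  prox <- as.integer(df[[c_prox]])
  distal <- ifelse(strand == "+", loc_end, loc_start)

  sites <- apa_sites(
    site_id = c(paste0(tx, "_P"), paste0(tx, "_D")),
    gene_id = rep(gene, 2), gene_symbol = rep(gene, 2),
    transcript_id = rep(tx, 2), chrom = rep(chrom, 2),
    strand = rep(strand, 2), cleavage_pos = c(prox, distal),
    rank = rep(c("proximal", "distal"), each = nrow(df)))
  utrs <- utr_regions(transcript_id = tx, chrom = chrom, strand = strand,
                      start = loc_start - 1L, end = loc_end)
  pdui_cols <- pdui_cols[order(names(pdui_cols))]
  usage <- usage_matrix(.num_matrix(df, pdui_cols, tx), kind = "PDUI")
  apa_dataset(sites, utrs, usage, source = "dapars")
}

#' Read the generic APA dialect
#'
#' A documented tab-separated format for APA data produced by other
#' quantification methods: fixed columns `feature_id`, `gene_id`,
#' `gene_symbol`, `chrom`, `strand`, `proximal_pos`, `distal_pos`
#' (1-based cleavage coordinates), followed by per-sample usage columns
#' with a terminal `usage` suffix. Usage values follow PDUI polarity
#' (higher = more distal usage = longer 3'UTR).
#'
#' @param path path to the tab-separated file.
#' @return an [apa_dataset()] with `usage$kind == "PDUI"`.
#' @export
parse_generic <- function(path) {
  df <- .read_tsv(path)
  for (cn in c("feature_id", "gene_id", "gene_symbol", "chrom", "strand",
               "proximal_pos", "distal_pos")) {
    .assert(cn %in% names(df), "missing mandatory column '%s'", cn)
  }
  use_cols <- .suffix_cols(df, "usage")
  .assert(length(use_cols) > 0, "missing mandatory column 'usage-suffixed sample usage'")
  .check_usage_range(df, use_cols, "usage")
  prox <- as.integer(df$proximal_pos)
  dist <- as.integer(df$distal_pos)
  sites <- apa_sites(
    site_id = c(paste0(df$feature_id, "_P"), paste0(df$feature_id, "_D")),
    gene_id = rep(df$gene_id, 2), gene_symbol = rep(df$gene_symbol, 2),
    transcript_id = rep(df$feature_id, 2), chrom = rep(df$chrom, 2),
    strand = rep(df$strand, 2), cleavage_pos = c(prox, dist),
    rank = rep(c("proximal", "distal"), each = nrow(df)))
  lo <- pmin(prox, dist); hi <- pmax(prox, dist)
  utrs <- utr_regions(transcript_id = df$feature_id, chrom = df$chrom,
                      strand = df$strand, start = lo - 1L, end = hi)
  use_cols <- use_cols[order(names(use_cols))]
  usage <- usage_matrix(.num_matrix(df, use_cols, df$feature_id), kind = "PDUI")
  apa_dataset(sites, utrs, usage, source = "generic")
}

#' Read an expression matrix (TSV, features x samples, TPM)
#'
#' @param path tab-separated file whose first column holds feature ids and
#'   whose remaining columns are per-sample TPM values.
#' @return an [expression_matrix()].
#' @export
parse_expression <- function(path) {
  df <- .read_tsv(path)
  .assert(ncol(df) >= 2, "expression table needs a feature column plus samples")
  feat <- as.character(df[[1]])
  .assert(!anyDuplicated(feat), "duplicate feature ids in expression table")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- feat
  expression_matrix(m)
}

#' Read a clinical table (TSV)
#'
#' @inheritParams clinical_table
#' @param path tab-separated file with a header containing `sample_id`,
#'   covariates, and the named survival time/event columns.
#' @return a [clinical_table()].
#' @export
parse_clinical <- function(path, time_column = "survival_time",
                           event_column = "event", time_unit = "days") {
  clinical_table(.read_tsv(path), time_column = time_column,
                 event_column = event_column, time_unit = time_unit)
}

#' Read a BED track
#'
#' Minimal BED parser for annotation tracks (PAS, RBP- or miRNA-binding
#' intervals): at least 3 columns, 0-based half-open, optional name,
#' score and strand in columns 4-6.
#'
#' @param path path to the BED file (no header).
#' @return a `data.frame` with columns `chrom`, `start`, `end`, `name`,
#'   `score`, `strand`.
#' @export
parse_bed <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE, comment.char = "#")
  .assert(ncol(df) >= 3, "BED needs at least 3 columns")
  out <- data.frame(chrom = as.character(df[[1]]),
                    start = as.integer(df[[2]]),
                    end = as.integer(df[[3]]),
                    name = if (ncol(df) >= 4) as.character(df[[4]]) else ".",
                    score = if (ncol(df) >= 5) as.character(df[[5]]) else ".",
                    strand = if (ncol(df) >= 6) as.character(df[[6]]) else "*",
                    stringsAsFactors = FALSE)
  .assert(all(out$start < out$end), "BED intervals must satisfy start < end")
  out
}

#' Write a result table as TSV
#'
#' Tab-separated, header row, no quoting, `NA` for missing cells; an
#' empty table yields a header-only file.
#'
#' @param x a data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA",
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Write sites or UTR regions as a BED6 track
#'
#' Cleavage sites become 1-nt intervals (the stored 1-based coordinate is
#' converted to a 0-based half-open interval); UTR regions are written
#' as-is. Strand goes in column 6.
#'
#' @param x an [apa_sites()] or [utr_regions()] table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  if (inherits(x, "apa_sites")) {
    bed <- data.frame(chrom = x$chrom, start = x$cleavage_pos - 1L,
                      end = x$cleavage_pos,
                      name = ifelse(is.na(x$site_id), ".", x$site_id),
                      score = ".", strand = x$strand)
  } else if (inherits(x, "utr_regions")) {
    bed <- data.frame(chrom = x$chrom, start = x$start, end = x$end,
                      name = ifelse(is.na(x$transcript_id), ".", x$transcript_id),
                      score = ".", strand = x$strand)
  } else {
    stop("write_bed() expects apa_sites or utr_regions", call. = FALSE)
  }
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
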