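## Strand-aware 3'UTR construction, polyadenylation-signal motif scanning
## in upstream windows, track overlap, and query/ID-mapping utilities.

#' Build a 3'UTR region from its shared start and a cleavage site
#'
#' `utr_anchor` is the sense-strand 5' boundary of the 3'UTR that all of
#' the gene's isoforms share: on the plus strand the 0-based genomic
#' start of the UTR, on the minus strand its 0-based exclusive genomic
#' end. The UTR length is the strand-aware distance from the anchor to
#' the cleavage site (cleavage base included), so for two isoforms
#' sharing an anchor, `length_distal - length_proximal` equals the
#' genomic distance between the two cleavage sites.
#'
#' @param site one row of an [apa_sites()] table (or an equivalent
#'   one-row data.frame with `transcript_id`, `chrom`, `strand`,
#'   `cleavage_pos`).
#' @param utr_anchor sense-strand 5' boundary (see above).
#' @return a one-row [utr_regions()] table.
#' @export
build_utr <- function(site, utr_anchor) {
  .assert(nrow(site) == 1, "build_utr() takes a single site")
  pos <- site$cleavage_pos
  if (site$strand == "+") {
    .assert(utr_anchor < pos,
            "cleavage site %d is not downstream of the UTR start %d (+ strand)",
            pos, utr_anchor)
    utr_regions(site$transcript_id, site$chrom, "+",
                start = utr_anchor, end = pos)
  } else {
    .assert(utr_anchor >= pos,
            "cleavage site %d is not downstream of the UTR start %d (- strand)",
            pos, utr_anchor)
    utr_regions(site$transcript_id, site$chrom, "-",
                start = pos - 1L, end = utr_anchor)
  }
}

#' Scan for polyadenylation-signal motifs upstream of a cleavage site
#'
#' Scans a sense-strand sequence whose last base is the cleavage site for
#' all (including overlapping) occurrences of the given motifs whose
#' first base lies within `window` nt upstream of the cleavage site.
#' The offset of a hit is the distance in nt from the motif's first base
#' to the cleavage site (the canonical PAS AATAAA typically sits
#' ~10-40 nt upstream). Defaults cover the canonical AATAAA signal, its
#' most common variant ATTAAA, and the DNA-strand form TGTA of the UGUA
#' element bound by cleavage factor I.
#'
#' @param sequence sense-strand nucleotide string (A/C/G/T/N), already
#'   reverse-complemented for minus-strand features, ending at the
#'   cleavage site.
#' @param window scan window in nt upstream of the cleavage site
#'   (default 100).
#' @param motifs character vector of motif words.
#' @param site optional one-row site table; when given, hits also carry
#'   the 1-based genomic coordinate of the motif start.
#' @return data.frame with columns `motif`, `offset`, `genomic_pos`
#'   (NA without `site`), sorted by offset.
#' @export
scan_upstream_motifs <- function(sequence, window = 100,
                                 motifs = c("AATAAA", "ATTAAA", "TGTA"),
                                 site = NULL) {
  sequence <- toupper(as.character(sequence))
  .assert(grepl("^[ACGTN]*$", sequence),
          "sequence contains non-ACGTN characters")
  L <- nchar(sequence)
  if (L < window) {
    warning(sprintf("sequence length %d is shorter than the %d nt window",
                    L, window))
  }
  hits <- list()
  subj <- Biostrings::DNAString(sequence)
  for (m in motifs) {
    if (nchar(m) > L) next
    mt <- Biostrings::matchPattern(Biostrings::DNAString(toupper(m)), subj)
    starts <- BiocGenerics::start(mt)
    offsets <- L - starts + 1L          # first base of motif -> cleavage base
    keep <- offsets <= window
    if (any(keep)) {
      hits[[length(hits) + 1L]] <- data.frame(
        motif = toupper(m), offset = offsets[keep], stringsAsFactors = FALSE)
    }
  }
  out <- if (length(hits)) do.call(rbind, hits) else
    data.frame(motif = character(0), offset = integer(0))
  out$genomic_pos <- if (!is.null(site) && nrow(out)) {
    if (site$strand == "+") site$cleavage_pos - out$offset + 1L
    else site$cleavage_pos + out$offset - 1L
  } else rep(NA_integer_, nrow(out))
  out <- out[order(out$offset, out$motif), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract upstream windows from a genome FASTA and scan them
#'
#' Pulls the `window` nt ending at each site's cleavage position from the
#' reference sequences (reverse-complementing minus-strand features so
#' the scan runs on the sense strand) and applies
#' [scan_upstream_motifs()].
#'
#' @param sites an [apa_sites()] table.
#' @param fasta path to a FASTA whose names match `chrom`.
#' @inheritParams scan_upstream_motifs
#' @return data.frame with `site_id`, `motif`, `offset`, `genomic_pos`.
#' @export
scan_sites_fasta <- function(sites, fasta, window = 100,
                             motifs = c("AATAAA", "ATTAAA", "TGTA")) {
  genome <- Biostrings::readDNAStringSet(fasta)
  names(genome) <- sub("\\s.*$", "", names(genome))
  out <- list()
  for (i in seq_len(nrow(sites))) {
    s <- sites[i, ]
    .assert(s$chrom %in% names(genome), "chromosome '%s' not in FASTA", s$chrom)
    chrlen <- length(genome[[s$chrom]])
    if (s$strand == "+") {
      from <- max(1L, s$cleavage_pos - window + 1L)
      seq_ <- Biostrings::subseq(genome[[s$chrom]], from, min(s$cleavage_pos, chrlen))
    } else {
      to <- min(chrlen, s$cleavage_pos + window - 1L)
      seq_ <- Biostrings::reverseComplement(
        Biostrings::subseq(genome[[s$chrom]], s$cleavage_pos, to))
    }
    h <- scan_upstream_motifs(as.character(seq_), window = window,
                              motifs = motifs, site = s)
    if (nrow(h)) out[[length(out) + 1L]] <- cbind(site_id = s$site_id, h)
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(site_id = character(0), motif = character(0),
               offset = integer(0), genomic_pos = integer(0))
}

#' Overlap regions with an annotation track
#'
#' Reports, per query region, the names of track intervals (PAS, RBP- or
#' miRNA-binding annotations supplied as BED) that intersect it by at
#' least 1 nt. Both sides are 0-based half-open, so abutting intervals
#' (`[100,200)` vs `[200,210)`) do not overlap. With `stranded = TRUE`
#' strands must match (track entries with strand `*` match either).
#'
#' @param regions data.frame with `chrom`, `start`, `end` (0-based
#'   half-open) and optionally `strand`; [apa_sites()] tables are
#'   accepted and converted to 1-nt intervals.
#' @param track a BED-like data.frame from [parse_bed()].
#' @param stranded require strand agreement (default `FALSE`).
#' @return list, one character vector of overlapping track names per
#'   region row.
#' @export
overlap_tracks <- function(regions, track, stranded = FALSE) {
  if (inherits(regions, "apa_sites")) {
    regions <- data.frame(chrom = regions$chrom,
                          start = regions$cleavage_pos - 1L,
                          end = regions$cleavage_pos,
                          strand = regions$strand,
                          stringsAsFactors = FALSE)
  }
  n <- nrow(regions)
  out <- rep(list(character(0)), n)
  if (n == 0 || nrow(track) == 0) return(out)
  if (is.null(regions$strand)) regions$strand <- "*"
  for (ch in unique(regions$chrom)) {
    qi <- which(regions$chrom == ch)
    si <- which(track$chrom == ch)
    if (!length(si)) next
    q <- IRanges::IRanges(start = regions$start[qi] + 1L, end = regions$end[qi])
    s <- IRanges::IRanges(start = track$start[si] + 1L, end = track$end[si])
    ov <- IRanges::findOverlaps(q, s, minoverlap = 1L)
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    if (stranded) {
      ok <- track$strand[si][sh] == "*" | regions$strand[qi][qh] == "*" |
        track$strand[si][sh] == regions$strand[qi][qh]
      qh <- qh[ok]; sh <- sh[ok]
    }
    for (k in seq_along(qh)) {
      i <- qi[qh[k]]
      out[[i]] <- c(out[[i]], track$name[si[sh[k]]])
    }
  }
  out
}

#' Query a dataset by gene, transcript, list or genomic range
#'
#' Accepts a gene symbol, gene id or transcript id (exact,
#' case-insensitive), a character vector of such keys (the union is
#' returned in list order), or a genomic range `chrom:start-end` typed
#' with 1-based inclusive coordinates (a site matches when its cleavage
#' position lies inside). Unknown keys are reported in `unmatched`,
#' never silently dropped. An optional two-column id map (`from_id`,
#' `to_id`) translates external identifiers first.
#'
#' @param dataset an [apa_dataset()].
#' @param key query key(s) as above.
#' @param id_map optional data.frame with columns `from_id`, `to_id`.
#' @return list with `sites`, `utrs`, `usage` (matrix rows), `unmatched`.
#' @export
query_apa <- function(dataset, key, id_map = NULL) {
  .assert(inherits(dataset, "apa_dataset"), "dataset must be an apa_dataset")
  s <- dataset$sites
  pick <- integer(0)
  unmatched <- character(0)
  range_pat <- "^([^:]+):([0-9]+)-([0-9]+)$"
  for (k in key) {
    if (grepl(":", k, fixed = TRUE)) {
      m <- regmatches(k, regexec(range_pat, k))[[1]]
      .assert(length(m) == 4,
              "malformed range '%s'; expected chrom:start-end with 1-based coordinates", k)
      lo <- as.integer(m[3]); hi <- as.integer(m[4])
      .assert(lo <= hi, "range '%s' has start > end", k)
      hit <- which(s$chrom == m[2] & s$cleavage_pos >= lo & s$cleavage_pos <= hi)
    } else {
      kk <- k
      if (!is.null(id_map)) {
        mp <- match(tolower(kk), tolower(id_map$from_id))
        if (!is.na(mp)) kk <- id_map$to_id[mp]
      }
      klo <- tolower(kk)
      hit <- which(tolower(s$gene_symbol) == klo | tolower(s$gene_id) == klo |
                     tolower(s$transcript_id) == klo | tolower(s$site_id) == klo)
    }
    if (length(hit)) pick <- c(pick, hit) else unmatched <- c(unmatched, k)
  }
  pick <- pick[!duplicated(pick)]
  sites <- s[pick, , drop = FALSE]
  tx <- unique(sites$transcript_id)
  utrs <- dataset$utrs[dataset$utrs$transcript_id %in% tx, , drop = FALSE]
  ukeep <- rownames(dataset$usage$values) %in%
    unique(c(sites$site_id, sites$gene_id, sites$transcript_id))
  list(sites = sites, utrs = utrs,
       usage = dataset$usage$values[ukeep, , drop = FALSE],
       unmatched = unmatched)
}
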