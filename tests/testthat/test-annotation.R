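test_that("build_utr does strand-aware coordinate arithmetic", {
  sp <- apa_sites("s1", "G", transcript_id = "t1", chrom = "chr1",
                  strand = "+", cleavage_pos = 200)
  expect_equal(build_utr(sp, 100)$length, 100)
  expect_error(build_utr(sp, 300), "not downstream")

  ## minus-strand isoform pair sharing the sense-strand UTR start:
  ## proximal length 107 at 64834454 implies the anchor, and the distal
  ## site at 64833213 then measures 107 + (64834454 - 64833213) = 1348
  prox <- apa_sites("p", "JAK1", transcript_id = "tp", chrom = "chr1",
                    strand = "-", cleavage_pos = 64834454)
  dist <- apa_sites("d", "JAK1", transcript_id = "td", chrom = "chr1",
                    strand = "-", cleavage_pos = 64833213)
  anchor <- 64834454 + 107 - 1
  expect_equal(build_utr(prox, anchor)$length, 107)
  expect_equal(build_utr(dist, anchor)$length, 1348)
})

test_that("the distal-proximal length difference equals the inter-site distance", {
  set.seed(17)
  for (i in 1:50) {
    strand <- sample(c("+", "-"), 1)
    if (strand == "+") {
      anchor <- sample(1000:2000, 1)
      pos <- sort(anchor + sample(1:5000, 2))
    } else {
      anchor <- sample(10000:20000, 1)
      pos <- sort(anchor - sample(0:5000, 2))
    }
    mk <- function(id, p) apa_sites(id, "G", transcript_id = id,
                                    chrom = "chr1", strand = strand,
                                    cleavage_pos = p)
    if (strand == "+") { prox <- pos[1]; dist <- pos[2] }
    else { prox <- pos[2]; dist <- pos[1] }
    ld <- build_utr(mk("d", dist), anchor)$length
    lp <- build_utr(mk("p", prox), anchor)$length
    expect_equal(ld - lp, abs(dist - prox))
  }
})

test_that("motif scanning reports all in-window occurrences with exact offsets", {
  ## AATAAA with its first base 40 nt upstream of the cleavage site
  seq_ <- paste0(strrep("C", 60), "AATAAA", strrep("C", 34))
  hits <- scan_upstream_motifs(seq_, window = 100)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$motif, "AATAAA")
  expect_equal(hits$offset, 40)

  ## short sequences warn but still scan
  expect_warning(short <- scan_upstream_motifs(strrep("A", 5), window = 100),
                 "shorter than")
  expect_equal(nrow(short), 0)

  ## overlapping occurrences are all reported
  tail10 <- paste0(strrep("C", 90), "AATAAATAAA")
  hits2 <- scan_upstream_motifs(tail10, window = 100, motifs = "AATAAA")
  expect_equal(sort(hits2$offset), c(6, 10))
  expect_equal(nrow(scan_upstream_motifs(tail10, window = 100,
                                         motifs = "ATTAAA")), 0)

  expect_error(scan_upstream_motifs("ACGTX"), "non-ACGTN")

  ## genomic coordinates: plus strand counts back, minus strand forward
  sp <- apa_sites("s", "G", chrom = "chr1", strand = "+", cleavage_pos = 1000)
  h <- scan_upstream_motifs(seq_, window = 100, site = sp)
  expect_equal(h$genomic_pos, 1000 - 40 + 1)
  sm <- apa_sites("s", "G", chrom = "chr1", strand = "-", cleavage_pos = 1000)
  h2 <- scan_upstream_motifs(seq_, window = 100, site = sm)
  expect_equal(h2$genomic_pos, 1000 + 40 - 1)
})

test_that("motif scanning equals the exhaustive substring oracle", {
  set.seed(23)
  motifs <- c("AATAAA", "ATTAAA", "TGTA")
  for (i in 1:1000) {
    seq_ <- paste(sample(c("A", "T", "G"), 200, replace = TRUE), collapse = "")
    got <- scan_upstream_motifs(seq_, window = 100, motifs = motifs)
    want <- brute_motif_scan(seq_, window = 100, motifs = motifs)
    expect_equal(got[, c("motif", "offset")], want)
  }
})

test_that("FASTA scanning extracts sense-strand windows", {
  fa <- tempfile(fileext = ".fa")
  ## chr: 120 nt; put AATAAA at positions 41-46 (1-based)
  chrseq <- paste0(strrep("G", 40), "AATAAA", strrep("G", 74))
  writeLines(c(">chrT test", chrseq), fa)
  ## + strand cleavage at 80: motif first base 41 -> offset 80-41+1 = 40
  sp <- apa_sites("s", "G", chrom = "chrT", strand = "+", cleavage_pos = 80)
  h <- suppressWarnings(scan_sites_fasta(sp, fa, window = 100,
                                         motifs = "AATAAA"))
  expect_equal(h$offset, 40)
  expect_equal(h$genomic_pos, 41)
  ## - strand: reverse complement means TTTATT genomically downstream
  chrseq2 <- paste0(strrep("G", 50), "TTTATT", strrep("G", 64))
  writeLines(c(">chrT", chrseq2), fa)
  sm <- apa_sites("s", "G", chrom = "chrT", strand = "-", cleavage_pos = 20)
  h2 <- scan_sites_fasta(sm, fa, window = 100, motifs = "AATAAA")
  ## sense position of motif first base = genomic 56; offset = 56-20+1 = 37
  expect_equal(h2$offset, 37)
  expect_equal(h2$genomic_pos, 56)
})

test_that("track overlap uses half-open semantics and matches brute force", {
  regions <- data.frame(chrom = "chr1", start = 100, end = 200, strand = "+")
  track <- data.frame(chrom = "chr1", start = c(150, 200), end = c(160, 210),
                      name = c("in", "abut"), score = ".",
                      strand = c("+", "+"), stringsAsFactors = FALSE)
  ov <- overlap_tracks(regions, track)
  expect_equal(ov[[1]], "in")                 # [200,210) does not overlap

  set.seed(77)
  n <- 1000
  regions <- data.frame(
    chrom = sample(c("chr1", "chr2"), n, TRUE),
    start = s <- sample(0:5000, n, TRUE), end = s + sample(1:200, n, TRUE),
    strand = sample(c("+", "-"), n, TRUE), stringsAsFactors = FALSE)
  track <- data.frame(
    chrom = sample(c("chr1", "chr2"), n, TRUE),
    start = s2 <- sample(0:5000, n, TRUE), end = s2 + sample(1:200, n, TRUE),
    name = sprintf("f%04d", 1:n), score = ".",
    strand = sample(c("+", "-", "*"), n, TRUE), stringsAsFactors = FALSE)
  for (stranded in c(FALSE, TRUE)) {
    got <- overlap_tracks(regions, track, stranded = stranded)
    want <- brute_overlap(regions, track, stranded = stranded)
    expect_equal(lapply(got, sort), lapply(want, sort))
  }
})

test_that("query matches symbols, ids, lists and 1-based ranges", {
  ds <- parse_qapa(write_jak1_file())
  q <- query_apa(ds, "JAK1")
  expect_equal(nrow(q$sites), 2)
  expect_equal(nrow(q$utrs), 2)
  expect_length(q$unmatched, 0)

  ## case-insensitive; transcript and gene ids work too
  expect_equal(nrow(query_apa(ds, "jak1")$sites), 2)
  expect_equal(nrow(query_apa(ds, "JAK1_T1")$sites), 1)
  expect_equal(nrow(query_apa(ds, "ENSG_DEMO1")$sites), 2)

  ## range containment with 1-based inclusive coordinates
  expect_equal(nrow(query_apa(ds, "chr1:64833000-64835000")$sites), 2)
  expect_equal(nrow(query_apa(ds, "chr1:64833000-64834000")$sites), 1)
  expect_error(query_apa(ds, "chr1:10-"), "malformed range")

  ## lists preserve matches and report unknown keys
  q2 <- query_apa(ds, c("DEMO1", "NOPE"))
  expect_equal(nrow(q2$sites), 2)
  expect_equal(q2$unmatched, "NOPE")

  ## id mapping translates external identifiers
  q3 <- query_apa(ds, "ALIAS1",
                  id_map = data.frame(from_id = "ALIAS1", to_id = "JAK1"))
  expect_equal(nrow(q3$sites), 2)
})
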