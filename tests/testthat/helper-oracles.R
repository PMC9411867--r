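## Independent brute-force oracles used to cross-check the implementation.
## These deliberately avoid the code paths they verify.

## Exhaustive two-sided Mann-Whitney permutation p: enumerate every
## C(n1+n2, n1) assignment of the pooled values to group 1 and count
## rank-sum statistics at least as extreme (two-sided, around the mean).
mw_permutation_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  obs <- sum(r[seq_len(n1)])
  centre <- n1 * (length(pooled) + 1) / 2
  combos <- utils::combn(length(pooled), n1)
  stats_all <- apply(combos, 2, function(idx) sum(r[idx]))
  mean(abs(stats_all - centre) >= abs(obs - centre) - 1e-9)
}

## All-substring motif scan: every start position checked verbatim.
brute_motif_scan <- function(sequence, window, motifs) {
  L <- nchar(sequence)
  out <- list()
  for (m in motifs) {
    w <- nchar(m)
    for (s in seq_len(max(0L, L - w + 1L))) {
      if (substr(sequence, s, s + w - 1L) == m && (L - s + 1L) <= window) {
        out[[length(out) + 1L]] <- data.frame(motif = m, offset = L - s + 1L,
                                              stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out)) {
    df <- do.call(rbind, out)
    df <- df[order(df$offset, df$motif), , drop = FALSE]
    rownames(df) <- NULL
    df
  } else {
    data.frame(motif = character(0), offset = integer(0))
  }
}

## O(n*m) half-open interval overlap (with optional strand matching).
brute_overlap <- function(regions, track, stranded = FALSE) {
  lapply(seq_len(nrow(regions)), function(i) {
    hits <- character(0)
    for (j in seq_len(nrow(track))) {
      if (regions$chrom[i] != track$chrom[j]) next
      if (max(regions$start[i], track$start[j]) >=
          min(regions$end[i], track$end[j])) next
      if (stranded && track$strand[j] != "*" &&
          !is.null(regions$strand) && regions$strand[i] != "*" &&
          regions$strand[i] != track$strand[j]) next
      hits <- c(hits, track$name[j])
    }
    hits
  })
}

## Hand product-limit estimator over sorted unique event times.
hand_km <- function(time, event) {
  s <- 1
  out <- numeric(0)
  times <- sort(unique(time))
  for (t in times) {
    n_risk <- sum(time >= t)
    d <- sum(time == t & event == 1)
    s <- s * (1 - d / n_risk)
    out <- c(out, s)
  }
  data.frame(time = times, surv = out)
}

## Plain TSV reader independent of the package's parsers.
.read_tsv_oracle <- function(path) {
  utils::read.delim(path, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
}

## Writes the bundled worked-example fixture to a temp file.
write_jak1_file <- function() {
  f <- tempfile(fileext = ".tsv")
  write_results_tsv(jak1_fixture(), f)
  f
}
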