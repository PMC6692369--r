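# Shared fixtures and independent oracles.
# Oracles deliberately avoid the code paths they check: the Fisher oracle
# enumerates hypergeometric tables directly, the SAM oracle string-parses
# CIGARs, and the KS oracle evaluates both ECDFs on the pooled support.

# A 4-exon single-transcript gene: three introns in a row (neighbour context).
toy_constitutive <- function(chrom = "chrT", strand = "+") {
  as_annotation(tibble::tibble(
    gene_id = "gc", transcript_id = "gc.t1", chrom = chrom,
    start = c(100, 500, 900, 1300), end = c(200, 600, 1000, 1400),
    strand = strand
  ))
}

# A cassette-exon gene: inclusion (3 exons) + skipping (2 exons) transcripts.
# Introns: inc1 = [200,400), inc2 = [500,700), skip = [200,700).
toy_cassette <- function(chrom = "chrC", strand = "+") {
  as_annotation(dplyr::bind_rows(
    tibble::tibble(gene_id = "gx", transcript_id = "gx.inc", chrom = chrom,
                   start = c(100, 400, 700), end = c(200, 500, 800),
                   strand = strand),
    tibble::tibble(gene_id = "gx", transcript_id = "gx.skip", chrom = chrom,
                   start = c(100, 700), end = c(200, 800), strand = strand)
  ))
}

# Write a SAM file from raw record fields (qname/flag/chrom/pos/cigar).
write_toy_sam <- function(records, chrom_lengths, path = tempfile(fileext = ".sam")) {
  write_sam(tibble::as_tibble(records), path, chrom_lengths)
  path
}

aln_tbl <- function(chrom, pos, cigar, flag = 0L) {
  tibble::tibble(
    qname = sprintf("r%03d", seq_along(pos)),
    flag = rep_len(flag, length(pos)),
    chrom = rep_len(chrom, length(pos)),
    pos = as.integer(pos),
    cigar = cigar
  )
}

# Exhaustive two-sided Fisher oracle: hypergeometric mass over all tables
# with the observed margins, probability-mass ordering with the conventional
# (1 + 1e-7) relative tolerance.
fisher_oracle <- function(a, b, c, d) {
  m <- a + b        # row margin handled via hypergeometric parametrisation:
  n <- c + d        # column 1 total a + c drawn from m "successes"
  k <- a + c
  if (m == 0 || n == 0 || k == 0 || (b + d) == 0) {
    return(1)
  }
  lo <- max(0, k - n)
  hi <- min(k, m)
  x <- lo:hi
  p <- stats::dhyper(x, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(p[p <= p_obs * (1 + 1e-7)])
}

# Brute-force junction counter: string-parses CIGARs, walks the reference,
# applies the overhang rule by summing M between N gaps.
sam_gap_oracle <- function(alignments) {
  out <- list()
  for (i in seq_len(nrow(alignments))) {
    cig <- alignments$cigar[i]
    lens <- as.integer(regmatches(cig, gregexpr("[0-9]+", cig))[[1]])
    ops <- regmatches(cig, gregexpr("[A-Z]", cig))[[1]]
    refpos <- alignments$pos[i] - 1L
    chunk_m <- 0L
    chunks <- integer(0)
    gap_start <- integer(0)
    gap_end <- integer(0)
    for (j in seq_along(ops)) {
      op <- ops[j]
      if (op == "M") {
        chunk_m <- chunk_m + lens[j]
        refpos <- refpos + lens[j]
      } else if (op == "D") {
        refpos <- refpos + lens[j]
      } else if (op == "N") {
        chunks <- c(chunks, chunk_m)
        chunk_m <- 0L
        gap_start <- c(gap_start, refpos)
        refpos <- refpos + lens[j]
        gap_end <- c(gap_end, refpos)
      }
    }
    chunks <- c(chunks, chunk_m)
    if (length(gap_start) > 0) {
      out[[length(out) + 1]] <- tibble::tibble(
        chrom = alignments$chrom[i],
        start = gap_start, end = gap_end,
        overhang = pmin(chunks[-length(chunks)], chunks[-1])
      )
    }
  }
  dplyr::bind_rows(out)
}

# Brute-force two-sample KS statistic on the pooled support.
ks_D_oracle <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(abs(vapply(pts, function(t) mean(x <= t) - mean(y <= t), numeric(1))))
}
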