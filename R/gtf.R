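#' Read a gene annotation from GTF
#'
#' Imports exon features from a GTF file (via rtracklayer) and builds the
#' package's `annotation` object.  GTF coordinates are 1-based inclusive and
#' are converted to the internal 0-based half-open convention on read.
#' Feature types other than `exon` are ignored.
#'
#' @param path Path to a GTF file.
#' @return An `annotation` object (see [as_annotation()]).
#' @export
read_gtf <- function(path) {
  lines <- readr::read_lines(path)
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  nfield <- stringr::str_count(lines[body], stringr::fixed("\t")) + 1L
  if (any(nfield < 9L)) {
    stop("malformed GTF line ", body[which(nfield < 9L)[1]],
         ": expected 9 tab-separated fields")
  }
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == "exon"]
  if (length(gr) == 0) {
    stop("no exon features found in ", path)
  }
  tx <- as.character(gr$transcript_id)
  gid <- as.character(gr$gene_id)
  if (anyNA(tx) || anyNA(gid)) {
    stop("exon feature without transcript_id/gene_id attribute (record ",
         which(is.na(tx) | is.na(gid))[1], ")")
  }
  exons <- tibble::tibble(
    gene_id = gid,
    transcript_id = tx,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    strand = as.character(BiocGenerics::strand(gr))
  )
  as_annotation(exons)
}

#' Write an annotation to GTF
#'
#' Exports the exon table as GTF `exon` features with `gene_id` and
#' `transcript_id` attributes, converting internal 0-based half-open
#' coordinates back to GTF's 1-based inclusive convention.
#'
#' @param annotation An `annotation` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(annotation, path) {
  ex <- annotation$exons
  gr <- GenomicRanges::GRanges(
    seqnames = ex$chrom,
    ranges = IRanges::IRanges(start = ex$start + 1L, end = ex$end),
    strand = ex$strand,
    source = "juncture",
    type = "exon",
    gene_id = ex$gene_id,
    transcript_id = ex$transcript_id
  )
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Export derived introns as BED6
#'
#' Writes one BED record per derived intron (0-based half-open, as BED
#' requires), with the intron id in the name column and the intron strand in
#' column 6.
#'
#' @param annotation An `annotation` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_intron_bed <- function(annotation, path) {
  intr <- annotation$introns
  bed <- tibble::tibble(
    chrom = intr$chrom,
    start = intr$start,
    end = intr$end,
    name = intr$intron_id,
    score = 0L,
    strand = intr$strand
  )
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}
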