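# GFF3 export of genome annotations (via rtracklayer). Wrap-around
# features are split into two GFF rows sharing one ID, since GFF3 has no
# native representation for features spanning a circular origin.

#' Export genome annotations to GFF3
#'
#' CDS features carry `product_class` and the genetic code; stem-loop
#' features carry the deviation score and the matched nonanucleotide as a
#' note. Coordinates are converted to 1-based inclusive.
#'
#' @param x `SequenceCollection`, list of `CircularGenome`, or a single
#'   `CircularGenome`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_gff3 <- function(x, path) {
  recs <- if (inherits(x, "SequenceCollection")) x$records
          else if (inherits(x, "CircularGenome")) list(x) else x
  rows <- list()
  for (g in recs) {
    n <- g$length
    for (f in g$features) {
      if (inherits(f, "GeneAnnotation")) {
        for (si in seq_along(f$segments)) {
          s <- f$segments[[si]]
          segs <- split_wrap_segment(s, n)
          for (ss in segs) {
            rows[[length(rows) + 1L]] <- data.frame(
              seqnames = g$id, start = ss[1] + 1L, end = ss[2],
              strand = f$strand, type = "CDS", score = NA_real_,
              phase = 0L, ID = f$id, product_class = f$product_class,
              transl_table = if (f$genetic_code == "ciliate") "6" else "1",
              note = NA_character_, stringsAsFactors = FALSE)
          }
        }
      } else if (inherits(f, "StemLoopAnnotation")) {
        s <- list(start = f$hairpin$start, end = f$hairpin$end)
        for (ss in split_wrap_segment(s, n)) {
          rows[[length(rows) + 1L]] <- data.frame(
            seqnames = g$id, start = ss[1] + 1L, end = ss[2],
            strand = f$motif$strand, type = "stem_loop",
            score = as.numeric(f$score), phase = NA_integer_,
            ID = sprintf("%s_stemloop_%d", g$id, f$motif$position),
            product_class = NA_character_, transl_table = NA_character_,
            note = sprintf("nonanucleotide=%s", f$motif$matched_seq),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows)) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = df$seqnames,
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    strand = df$strand)
  S4Vectors::mcols(gr) <- df[, c("type", "score", "phase", "ID",
                                 "product_class", "transl_table", "note")]
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

# A 0-based half-open segment -> list of c(start0, end0) pieces that do
# not wrap (end0 as 1-exclusive/0-based, i.e. GFF end = end0).
split_wrap_segment <- function(s, n) {
  if (s$end > s$start) list(c(s$start, s$end))
  else list(c(s$start, n), c(0L, s$end))
}
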