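# Feature annotation records attached to CircularGenome objects.
# Coordinates: 0-based half-open on the forward strand; a segment with
# end <= start wraps across the origin. Segment order is transcription
# order (5'->3' on the feature's strand).

#' Construct a gene annotation
#'
#' @param id feature identifier
#' @param genome_id id of the genome the feature lies on
#' @param segments list of `list(start, end)` segments (0-based half-open,
#'   wrap allowed), in transcription order
#' @param strand `"+"` or `"-"`
#' @param frame 0, 1 or 2 (frame of the first coding base on `strand`)
#' @param genetic_code `"standard"` or `"ciliate"`
#' @param spliced logical; `TRUE` when the CDS is a join of several exons
#' @param product_class one of `"capsid"`, `"rep"`, `"putative_orf"`,
#'   `"unknown"`
#' @param protein translated product (may be `NA`)
#' @param best_hit `NULL` or list `(ref_id, bit_score, pident)`
#' @param flags character vector of quality flags (e.g. `"ambiguous"` when
#'   the feature sequence contains N, `"unresolved"` when no splice solution
#'   was found)
#' @return an object of class `GeneAnnotation`
#' @export
gene_annotation <- function(id, genome_id, segments, strand = "+", frame = 0L,
                            genetic_code = c("standard", "ciliate"),
                            spliced = FALSE,
                            product_class = c("unknown", "capsid", "rep",
                                              "putative_orf"),
                            protein = NA_character_, best_hit = NULL,
                            flags = character()) {
  genetic_code <- match.arg(genetic_code)
  product_class <- match.arg(product_class)
  stopifnot(strand %in% c("+", "-"), is.list(segments), length(segments) >= 1L)
  segments <- lapply(segments, function(s)
    list(start = as.integer(s$start %||% s[[1]]),
         end = as.integer(s$end %||% s[[2]])))
  structure(
    list(id = as.character(id), genome_id = as.character(genome_id),
         segments = segments, strand = strand, frame = as.integer(frame),
         genetic_code = genetic_code, spliced = isTRUE(spliced),
         product_class = product_class, protein = protein,
         best_hit = best_hit, flags = flags),
    class = "GeneAnnotation"
  )
}

#' @export
print.GeneAnnotation <- function(x, ...) {
  segs <- paste(vapply(x$segments, function(s)
    sprintf("%d..%d", s$start, s$end), character(1)), collapse = ",")
  cat(sprintf("<GeneAnnotation> %s [%s] strand %s %s%s code=%s\n",
              x$id, segs, x$strand, x$product_class,
              if (x$spliced) " (spliced)" else "", x$genetic_code))
  invisible(x)
}

# Length in nucleotides of a feature segment on a circle of size n.
segment_length <- function(s, n) {
  len <- (s$end - s$start) %% n
  if (len == 0L) n else len
}

# Nucleotide length of a (possibly spliced, possibly wrapping) gene.
gene_length <- function(gene, n) {
  sum(vapply(gene$segments, segment_length, integer(1), n = n))
}

# Extract the coding sequence of a gene from its genome (transcription
# order, reverse-complemented for minus-strand features).
gene_dna <- function(gene, genome) {
  n <- genome$length
  parts <- vapply(gene$segments, function(s)
    circ_substr(genome$seq, s$start, segment_length(s, n)), character(1))
  dna <- paste(parts, collapse = "")
  if (gene$strand == "-") dna <- revcomp(dna)
  dna
}

#' Construct a stem-loop (putative ori) annotation
#'
#' @param motif list with `pattern`, `position` (0-based start of the
#'   matched nonanucleotide on the forward strand reading frame of the
#'   motif's own strand), `strand`, `matched_seq`
#' @param hairpin list with `stem_len`, `loop_len`, `start`, `end`
#'   (genomic, 0-based half-open, forward strand), `pairs` (two-column
#'   matrix of paired window indices) and `backend`
#' @param score non-negative integer deviation score
#' @param accepted logical
#' @param rejection_reason one of `"none"`, `"score_gt_threshold"`,
#'   `"duplicate_first_base"`, `"motif_too_close_to_stem_end"`,
#'   `"geometry"`
#' @return an object of class `StemLoopAnnotation`
#' @export
stemloop_annotation <- function(motif, hairpin, score, accepted,
                                rejection_reason = c("none",
                                                     "score_gt_threshold",
                                                     "duplicate_first_base",
                                                     "motif_too_close_to_stem_end",
                                                     "geometry")) {
  rejection_reason <- match.arg(rejection_reason)
  if (accepted && rejection_reason != "none")
    stop("accepted annotation cannot carry a rejection reason", call. = FALSE)
  structure(
    list(motif = motif, hairpin = hairpin, score = as.integer(score),
         accepted = isTRUE(accepted), rejection_reason = rejection_reason),
    class = "StemLoopAnnotation"
  )
}

#' @export
print.StemLoopAnnotation <- function(x, ...) {
  cat(sprintf(
    "<StemLoop> %s@%d(%s) stem %d loop %d score %d %s\n",
    x$motif$matched_seq, x$motif$position, x$motif$strand,
    x$hairpin$stem_len, x$hairpin$loop_len, x$score,
    if (x$accepted) "accepted" else paste0("rejected:", x$rejection_reason)))
  invisible(x)
}
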