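# Stem-loop / origin-of-replication detection.
#
# CRESS-DNA viruses initiate rolling-circle replication at a conserved
# nonanucleotide presented in the loop of a DNA hairpin. Detection proceeds
# in three steps: (1) scan both strands of the circular genome for
# degenerate IUPAC nonanucleotide motifs, (2) fold a window of sequence
# around each hit and extract the best hairpin, (3) score the hairpin by
# its deviation from the ideal geometry (11 bp stem, 11 nt loop) and apply
# the acceptance and exclusion rules.

#' Conserved CRESS-DNA nonanucleotide motif patterns
#'
#' The degenerate 9-mers described for CRESS-DNA virus origins of
#' replication, in IUPAC notation.
#' @return character vector of IUPAC patterns
#' @export
default_nonanucleotide_patterns <- function() {
  c("NANTANTAN", "NAKWRTTAC", "TAWWDHWAN", "TRAKATTRC")
}

check_iupac <- function(pattern) {
  bad <- setdiff(split_chars(toupper(pattern)), names(IUPAC_MAP))
  if (length(bad))
    stop("non-IUPAC character(s) in pattern '", pattern, "': ",
         paste(bad, collapse = ","), call. = FALSE)
  toupper(pattern)
}

#' Does a sequence match an IUPAC pattern position by position?
#'
#' @param seq,pattern equal-length strings; `pattern` may use IUPAC
#'   degeneracy codes
#' @return logical
#' @export
iupac_matches <- function(seq, pattern) {
  pattern <- check_iupac(pattern)
  if (nchar(seq) != nchar(pattern)) return(FALSE)
  s <- split_chars(toupper(seq)); p <- split_chars(pattern)
  all(mapply(function(a, b) a %in% IUPAC_MAP[[b]], s, p))
}

#' Scan a circular genome for degenerate nonanucleotide motifs
#'
#' Matches are collected on both strands, scanning across the origin of
#' the circle. `position` is the forward-strand coordinate (0-based) of the
#' motif's own 5' base: for plus-strand hits the leftmost base of the
#' matched region, for minus-strand hits the rightmost. `matched_seq` is
#' read 5'->3' on the hit's strand. Hits are ordered by (position, strand).
#'
#' @param genome `CircularGenome` (or DNA string, treated as circular)
#' @param patterns IUPAC 9-mer patterns
#' @return list of motif hits, each `list(pattern, position, strand,
#'   matched_seq)`
#' @export
scan_nonanucleotides <- function(genome,
                                 patterns = default_nonanucleotide_patterns()) {
  seq <- if (inherits(genome, "CircularGenome")) genome$seq else toupper(genome)
  patterns <- vapply(patterns, check_iupac, character(1), USE.NAMES = FALSE)
  n <- nchar(seq)
  hits <- list()
  scan_one <- function(subject_seq, strand) {
    ext <- paste0(subject_seq, substr(subject_seq, 1L, min(8L, n)))
    subj <- Biostrings::DNAString(ext)
    for (pat in patterns) {
      if (nchar(pat) > nchar(ext)) next
      m <- Biostrings::matchPattern(Biostrings::DNAString(pat), subj,
                                    fixed = FALSE)
      st <- Biostrings::start(m)
      st <- st[st <= n]
      for (s in st) {
        opos <- s - 1L                       # 0-based on this strand
        pos <- if (strand == "+") opos else (n - 1L - opos) %% n
        hits[[length(hits) + 1L]] <<- list(
          pattern = pat, position = pos, strand = strand,
          matched_seq = circ_substr(subject_seq, opos, nchar(pat)))
      }
    }
  }
  scan_one(seq, "+")
  scan_one(revcomp(seq), "-")
  if (!length(hits)) return(list())
  ord <- order(vapply(hits, function(h) h$position, numeric(1)),
               vapply(hits, function(h) h$strand, character(1)))
  hits[ord]
}

# --- folding ---------------------------------------------------------------

can_pair <- function(a, b, wobble = TRUE) {
  (a == "A" && b == "T") || (a == "T" && b == "A") ||
    (a == "G" && b == "C") || (a == "C" && b == "G") ||
    (wobble && ((a == "G" && b == "T") || (a == "T" && b == "G")))
}

#' Maximum base-pairing nested fold of a DNA window
#'
#' Dynamic program over Watson-Crick pairs with G.T wobble allowed and a
#' minimum hairpin loop of `min_loop` unpaired bases. Returns all base
#' pairs of one maximum-pairing nested structure; the traceback is
#' deterministic (when the 3' base of a subinterval can pair optimally it
#' does, with the 5'-most partner, which favors long contiguous helices).
#'
#' @param window DNA string
#' @param min_loop minimum number of unpaired bases enclosed by a pair
#' @param wobble allow G.T pairs
#' @return integer matrix with columns `i`, `j` (1-based window indices,
#'   `i < j`); zero rows when no pair can form
#' @export
nussinov_fold <- function(window, min_loop = 3L, wobble = TRUE) {
  s <- split_chars(toupper(window))
  n <- length(s)
  empty <- matrix(integer(0), ncol = 2, dimnames = list(NULL, c("i", "j")))
  if (n < min_loop + 2L) return(empty)
  M <- matrix(0L, n, n)
  for (span in seq.int(min_loop + 1L, n - 1L)) {
    for (i in seq_len(n - span)) {
      j <- i + span
      best <- M[i, j - 1L]
      for (k in seq.int(i, j - min_loop - 1L)) {
        if (can_pair(s[k], s[j], wobble)) {
          v <- 1L + M[k + 1L, j - 1L] + (if (k > i) M[i, k - 1L] else 0L)
          if (v > best) best <- v
        }
      }
      M[i, j] <- best
    }
  }
  if (M[1L, n] == 0L) return(empty)
  # deterministic traceback
  pairs <- empty
  stack <- list(c(1L, n))
  while (length(stack)) {
    iv <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- iv[1]; j <- iv[2]
    if (j - i < min_loop + 1L) next
    if (M[i, j] == M[i, j - 1L]) {
      # j may still pair optimally; prefer pairing when it ties
      paired <- FALSE
      for (k in seq.int(i, j - min_loop - 1L)) {
        if (can_pair(s[k], s[j], wobble)) {
          v <- 1L + M[k + 1L, j - 1L] + (if (k > i) M[i, k - 1L] else 0L)
          if (v == M[i, j]) {
            pairs <- rbind(pairs, c(k, j))
            if (k > i) stack[[length(stack) + 1L]] <- c(i, k - 1L)
            stack[[length(stack) + 1L]] <- c(k + 1L, j - 1L)
            paired <- TRUE
            break
          }
        }
      }
      if (!paired) stack[[length(stack) + 1L]] <- c(i, j - 1L)
    } else {
      for (k in seq.int(i, j - min_loop - 1L)) {
        if (can_pair(s[k], s[j], wobble)) {
          v <- 1L + M[k + 1L, j - 1L] + (if (k > i) M[i, k - 1L] else 0L)
          if (v == M[i, j]) {
            pairs <- rbind(pairs, c(k, j))
            if (k > i) stack[[length(stack) + 1L]] <- c(i, k - 1L)
            stack[[length(stack) + 1L]] <- c(k + 1L, j - 1L)
            break
          }
        }
      }
    }
  }
  colnames(pairs) <- c("i", "j")
  pairs[order(pairs[, 1L]), , drop = FALSE]
}

# Enumerate all maximal contiguous helices of a window: outer pair (a,b),
# pairs (a+d, b-d) for d = 0..k-1, enclosed loop >= min_loop. Positions in
# `forbidden` may not pair (used to keep the nonanucleotide, the
# single-stranded nicking site, out of the stem).
enumerate_helices <- function(window, min_loop = 3L, wobble = TRUE,
                              forbidden = integer(0)) {
  s <- split_chars(toupper(window))
  n <- length(s)
  ok <- function(a, b) {
    !(a %in% forbidden) && !(b %in% forbidden) && can_pair(s[a], s[b], wobble)
  }
  out <- list()
  for (a in seq_len(n - min_loop - 1L)) {
    for (b in seq.int(a + min_loop + 1L, n)) {
      if (!ok(a, b)) next
      if (a > 1L && b < n && ok(a - 1L, b + 1L)) next  # not maximal outward
      k <- 1L
      while (b - a - 2L * k - 1L >= min_loop && ok(a + k, b - k))
        k <- k + 1L
      out[[length(out) + 1L]] <- list(outer_i = a, outer_j = b,
                                      inner_i = a + k - 1L,
                                      inner_j = b - k + 1L, stem_len = k)
    }
  }
  out
}

# Chooses the hairpin helix for a motif-anchored window. Preference
# order: helices whose enclosed loop contains `center`; then helices
# meeting the geometry filter; then the lowest deviation score (the
# quantity the annotation is judged by); then longer stems; then loop
# midpoint closest to `center`; then 5'-most.
choose_hairpin_helix <- function(helices, center, min_stem = 5L,
                                 min_loop = 7L) {
  if (!length(helices)) return(NULL)
  contains <- vapply(helices, function(h)
    h$inner_i < center && center < h$inner_j, logical(1))
  cand <- if (any(contains)) helices[contains] else helices
  stem <- vapply(cand, function(h) h$stem_len, integer(1))
  loop <- vapply(cand, function(h) h$inner_j - h$inner_i - 1L, integer(1))
  loopmid <- vapply(cand, function(h) (h$inner_i + h$inner_j) / 2, numeric(1))
  starts <- vapply(cand, function(h) h$outer_i, integer(1))
  geom_ok <- stem >= min_stem & loop >= min_loop
  ord <- order(-geom_ok, score_stemloop(stem, loop), -stem,
               abs(loopmid - center), starts)
  cand[[ord[1L]]]
}

#' Fold the window around a motif hit and extract the best hairpin
#'
#' Extracts the sequence `flank` bases on either side of the 9-mer hit (on
#' the hit's strand, wrapping across the circular origin) and returns the
#' hairpin helix that cradles the motif. Candidate hairpins are all
#' maximal contiguous helices of the window; the nine motif bases are
#' constrained unpaired (the nonanucleotide is the single-stranded nicking
#' site, so it may not be buried in a stem). Helices whose enclosed loop
#' contains the motif midpoint are preferred, then longer contiguous
#' stems, then the more centered loop. When `with_structure = TRUE` the
#' full maximum-pairing nested structure of the window (computed with the
#' selected backend, unconstrained) is attached as `structure_pairs`.
#'
#' @param genome `CircularGenome`
#' @param hit a motif hit from [scan_nonanucleotides()]
#' @param flank bases of context on either side of the motif (15-20;
#'   default 20)
#' @param backend `"nussinov_dna"` or a function `(window) -> pairs
#'   matrix` implementing an alternative folding engine
#' @param motif_unpaired keep the motif bases out of the stem?
#' @param with_structure also compute and attach the full maximum-pairing
#'   structure of the window
#' @param min_stem,min_loop geometry preferred during hairpin selection
#'   (candidates meeting it rank first; the hard filter is applied by
#'   [find_stemloops()])
#' @return a hairpin record (`stem_len`, `loop_len`, `start`, `end`,
#'   `pairs`, `backend`, plus window bookkeeping), or `NULL` when no
#'   helix can form
#' @export
fold_window <- function(genome, hit, flank = 20L, backend = "nussinov_dna",
                        motif_unpaired = TRUE, with_structure = FALSE,
                        min_stem = 5L, min_loop = 7L) {
  if (!inherits(genome, "CircularGenome"))
    stop("fold_window requires a CircularGenome; windows on linear records ",
         "may extend past the sequence end", call. = FALSE)
  flank <- as.integer(flank)
  if (flank < 15L || flank > 20L)
    stop("flank must be between 15 and 20", call. = FALSE)
  n <- genome$length
  mlen <- nchar(hit$matched_seq)
  wlen <- mlen + 2L * flank
  if (wlen > n) stop("window larger than genome", call. = FALSE)
  oriented <- if (hit$strand == "+") genome$seq else revcomp(genome$seq)
  opos <- if (hit$strand == "+") hit$position else (n - 1L - hit$position) %% n
  wstart <- (opos - flank) %% n
  window <- circ_substr(oriented, wstart, wlen)
  # keep the motif single stranded from its third base through its 3' end
  # (the nick site lies in the 3' half); the first two bases may
  # participate in the ascending stem arm, as they do in origins whose
  # loop is shorter than the nonanucleotide
  forbidden <- if (motif_unpaired) seq.int(flank + 3L, flank + mlen)
               else integer(0)
  helices <- enumerate_helices(window, forbidden = forbidden)
  backend_name <- if (is.function(backend)) "custom" else backend
  center <- flank + (mlen + 1L) / 2        # motif midpoint, 1-based
  h <- choose_hairpin_helix(helices, center, min_stem, min_loop)
  if (is.null(h)) return(NULL)
  loop_len <- h$inner_j - h$inner_i - 1L
  # map window indices back to forward-strand genomic coordinates
  w2g <- function(widx0) {
    p <- (wstart + widx0) %% n
    if (hit$strand == "+") p else (n - 1L - p) %% n
  }
  g1 <- w2g(h$outer_i - 1L); g2 <- w2g(h$outer_j - 1L)
  start <- min(g1, g2); end <- max(g1, g2) + 1L
  span_fwd <- (end - start) %% n
  if (span_fwd != (h$outer_j - h$outer_i + 1L) %% n) {  # wraps the origin
    start <- max(g1, g2); end <- min(g1, g2) + 1L
  }
  out <- list(stem_len = h$stem_len, loop_len = loop_len,
              apex_dist = abs((h$inner_i + h$inner_j) / 2 - center),
              start = start, end = end,
              pairs = cbind(i = seq.int(h$outer_i, h$inner_i),
                            j = seq.int(h$outer_j, h$inner_j)),
              backend = backend_name,
              window_start = wstart, window_len = wlen,
              helix = h, motif_offset = flank)
  if (with_structure) {
    out$structure_pairs <- if (is.function(backend)) backend(window)
                           else nussinov_fold(window)
  }
  out
}

#' Deviation score of a stem-loop
#'
#' One point for each base of deviation from the ideal geometry of an 11 bp
#' stem and an 11 nt loop: `|stem_len - 11| + |loop_len - 11|`.
#'
#' @param stem_len stem length in base pairs
#' @param loop_len loop length in bases
#' @return integer score (0 is ideal)
#' @export
score_stemloop <- function(stem_len, loop_len) {
  stopifnot(stem_len >= 0, loop_len >= 0)
  abs(as.integer(stem_len) - 11L) + abs(as.integer(loop_len) - 11L)
}

#' Find and score stem-loop origin candidates on a circular genome
#'
#' Runs the full annotation procedure: degenerate nonanucleotide scan on
#' both strands, window folding, geometry filter (stem at least
#' `min_stem` bp, loop at least `min_loop` nt), deviation scoring with
#' acceptance at `max_score` or below, then exclusion rules:
#' candidates whose nonanucleotide lies within `proximity` bases of the
#' hairpin's first or last nucleotide are rejected, and among candidates
#' whose hairpins share the same first base only the lowest-scoring one is
#' kept (ties broken by smaller loop deviation, then plus strand, then
#' lower start). All candidates are returned, each carrying its
#' `accepted` flag and `rejection_reason`.
#'
#' @param genome `CircularGenome`
#' @param patterns IUPAC 9-mers to scan for
#' @param flank folding context on either side of the motif
#' @param max_score maximum accepted deviation score (default 15)
#' @param min_stem minimum stem length in bp (default 5, i.e. stems longer
#'   than 4 bp)
#' @param min_loop minimum loop length in nt (default 7)
#' @param proximity exclusion distance between the nonanucleotide and the
#'   hairpin ends (default 4)
#' @param backend folding backend (see [fold_window()])
#' @return list of `StemLoopAnnotation`
#' @export
find_stemloops <- function(genome,
                           patterns = default_nonanucleotide_patterns(),
                           flank = 20L, max_score = 15L, min_stem = 5L,
                           min_loop = 7L, proximity = 4L,
                           backend = "nussinov_dna") {
  hits <- scan_nonanucleotides(genome, patterns)
  anns <- list()
  for (hit in hits) {
    hp <- fold_window(genome, hit, flank = flank, backend = backend,
                      min_stem = min_stem, min_loop = min_loop)
    if (is.null(hp)) {
      anns[[length(anns) + 1L]] <- stemloop_annotation(
        motif = hit,
        hairpin = list(stem_len = 0L, loop_len = 0L, start = hit$position,
                       end = hit$position, pairs = NULL,
                       backend = if (is.function(backend)) "custom" else backend),
        score = score_stemloop(0L, 0L), accepted = FALSE,
        rejection_reason = "geometry")
      next
    }
    sc <- score_stemloop(hp$stem_len, hp$loop_len)
    if (hp$stem_len < min_stem || hp$loop_len < min_loop) {
      reason <- "geometry"
    } else if (sc > max_score) {
      reason <- "score_gt_threshold"
    } else {
      # proximity of either motif end to either hairpin terminal nucleotide,
      # in window coordinates (1-based)
      m1 <- hp$motif_offset + 1L
      m2 <- hp$motif_offset + nchar(hit$matched_seq)
      h <- hp$helix
      d <- min(abs(c(m1, m2) - h$outer_i), abs(c(m1, m2) - h$outer_j))
      reason <- if (d <= proximity) "motif_too_close_to_stem_end" else "none"
    }
    anns[[length(anns) + 1L]] <- stemloop_annotation(
      motif = hit, hairpin = hp[c("stem_len", "loop_len", "apex_dist",
                                  "start", "end", "pairs", "backend")],
      score = sc, accepted = identical(reason, "none"),
      rejection_reason = reason)
  }
  dedup_same_first_base(anns)
}

# Among accepted annotations whose hairpins share the same first
# nucleotide (5' end of the hairpin read on its own strand), keep the
# lowest score (ties: smaller |loop - 11|, then '+' strand, then lower
# motif start); the others are demoted to rejected duplicates.
dedup_same_first_base <- function(anns) {
  acc <- which(vapply(anns, function(a) a$accepted, logical(1)))
  if (length(acc) < 2L) return(anns)
  first_base <- vapply(anns[acc], function(a) {
    if (a$motif$strand == "+") paste0("p", a$hairpin$start)
    else paste0("m", a$hairpin$end - 1L)
  }, character(1))
  for (fb in unique(first_base[duplicated(first_base)])) {
    grp <- acc[first_base == fb]
    key <- order(
      vapply(anns[grp], function(a) a$score, integer(1)),
      vapply(anns[grp], function(a) abs(a$hairpin$loop_len - 11L), integer(1)),
      vapply(anns[grp], function(a) a$hairpin$apex_dist %||% 0, numeric(1)),
      vapply(anns[grp], function(a) if (a$motif$strand == "+") 0L else 1L,
             integer(1)),
      vapply(anns[grp], function(a) a$motif$position, numeric(1)))
    for (idx in grp[key[-1L]]) {
      anns[[idx]]$accepted <- FALSE
      anns[[idx]]$rejection_reason <- "duplicate_first_base"
    }
  }
  anns
}

#' Base frequencies of accepted nonanucleotides
#'
#' Per-position base composition of the matched nonanucleotide sequences of
#' accepted stem-loop annotations, as a 4 x 9 column-stochastic matrix
#' (rows A, C, G, T; one column per motif position).
#'
#' @param annotations list of `StemLoopAnnotation` (only accepted ones are
#'   used)
#' @return 4 x 9 numeric matrix; each column sums to 1
#' @export
nonanucleotide_frequencies <- function(annotations) {
  seqs <- vapply(Filter(function(a) a$accepted, annotations),
                 function(a) a$motif$matched_seq, character(1))
  if (!length(seqs))
    stop("no accepted stem-loop annotations", call. = FALSE)
  stopifnot(all(nchar(seqs) == 9L))
  m <- matrix(0, nrow = 4L, ncol = 9L,
              dimnames = list(DNA_BASES, paste0("pos", 1:9)))
  for (s in seqs) {
    ch <- split_chars(s)
    for (p in 1:9) if (ch[p] %in% DNA_BASES) m[ch[p], p] <- m[ch[p], p] + 1
  }
  sweep(m, 2L, colSums(m), "/")
}
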