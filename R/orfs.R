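# ORF calling on circular genomes under standard and ciliate genetic
# codes, orientation classification, and splice-candidate rescue for rep
# genes whose transcripts appear to require intron removal.

GENETIC_CODE_IDS <- c(standard = "1", ciliate = "6")

genetic_code_table <- function(code = c("standard", "ciliate")) {
  code <- match.arg(code)
  Biostrings::getGeneticCode(GENETIC_CODE_IDS[[code]])
}

#' Translate a DNA string
#'
#' Under the standard code TAA/TAG/TGA are stops (`*`); under the ciliate
#' code (translation table 6) TAA and TAG encode glutamine and only TGA
#' remains a stop. Codons containing ambiguous bases translate to `X`.
#'
#' @param dna DNA string, length divisible by 3
#' @param code `"standard"` or `"ciliate"`
#' @return amino-acid string
#' @export
translate_dna <- function(dna, code = c("standard", "ciliate")) {
  code <- match.arg(code)
  dna <- toupper(dna)
  n <- nchar(dna)
  if (n %% 3L != 0L)
    stop("sequence length not divisible by 3", call. = FALSE)
  if (n == 0L) return("")
  tab <- genetic_code_table(code)
  codons <- substring(dna, seq(1L, n, 3L), seq(3L, n, 3L))
  aa <- unname(tab[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Find open reading frames on a circular genome
#'
#' Maximal ATG-to-stop ORFs on all six frames, scanning across the origin
#' (an ORF may wrap around the sequence end). An ORF runs from the first
#' ATG after the preceding stop codon to its stop codon, inclusive.
#' ORFs of nucleotide length greater than `min_len` (the stop codon
#' counts) and at most the genome length are reported, ordered by
#' (start, strand, length).
#'
#' @param genome `CircularGenome`
#' @param min_len report ORFs strictly longer than this many nucleotides
#'   (default 300)
#' @param code genetic code for translation
#' @return list of `GeneAnnotation` (product class `"unknown"`)
#' @export
find_orfs <- function(genome, min_len = 300L, code = c("standard", "ciliate")) {
  code <- match.arg(code)
  stopifnot(inherits(genome, "CircularGenome"))
  n <- genome$length
  tab <- genetic_code_table(code)
  stops <- names(tab)[tab == "*"]
  out <- list()
  for (strand in c("+", "-")) {
    S <- if (strand == "+") genome$seq else revcomp(genome$seq)
    ext <- paste0(S, S)
    for (f in 0:2) {
      cs <- seq.int(f + 1L, 2L * n - 2L, by = 3L)   # 1-based codon starts
      codons <- substring(ext, cs, cs + 2L)
      cur <- NA_integer_
      for (ci in seq_along(codons)) {
        cdn <- codons[ci]
        if (is.na(cur)) {
          if (cdn == "ATG") cur <- cs[ci]
        } else if (cdn %in% stops) {
          len <- cs[ci] + 3L - cur
          a0 <- cur - 1L                              # 0-based oriented start
          if (len > min_len && len <= n && a0 < n) {
            if (strand == "+") {
              st <- a0 %% n; en <- (a0 + len) %% n
            } else {
              st <- (n - a0 - len) %% n; en <- (n - a0) %% n
            }
            if (en == 0L) en <- n
            prot <- translate_dna(substr(ext, cur, cur + len - 1L), code)
            gid <- sprintf("%s_orf_%s%d", genome$id, if (strand == "+") "p" else "m",
                           length(out) + 1L)
            out[[length(out) + 1L]] <- gene_annotation(
              id = gid, genome_id = genome$id,
              segments = list(list(start = st, end = en)),
              strand = strand, frame = a0 %% 3L, genetic_code = code,
              product_class = "unknown",
              protein = sub("\\*$", "", prot),
              flags = if (grepl("N", substr(ext, cur, cur + len - 1L),
                               fixed = TRUE)) "ambiguous" else character())
          }
          cur <- NA_integer_
        }
      }
    }
  }
  ord <- order(vapply(out, function(g) g$segments[[1]]$start, numeric(1)),
               vapply(out, function(g) g$strand, character(1)),
               vapply(out, function(g) gene_length(g, n), numeric(1)))
  out[ord]
}

#' Relative orientation of the capsid and rep genes
#'
#' @param capsid,rep `GeneAnnotation` records on the same genome (`rep`
#'   may be `NULL`)
#' @return `"unisense"` when both genes lie on the same strand,
#'   `"ambisense"` otherwise, `"not_applicable"` when `rep` is missing
#' @export
classify_orientation <- function(capsid, rep) {
  if (is.null(rep) || is.null(capsid)) return("not_applicable")
  if (capsid$strand == rep$strand) "unisense" else "ambisense"
}

# --- splice-candidate rescue ----------------------------------------------

# Positions (0-based) of a 2-mer in a string.
dimer_positions <- function(s, dimer) {
  hit <- gregexpr(dimer, s, fixed = TRUE)[[1]]
  if (hit[1] == -1L) integer(0) else as.integer(hit) - 1L
}

# Search for the minimal GT..AG intron whose excision yields a stop-free
# ATG..stop ORF that spans the splice junction and whose translation
# matches all `required_motifs` regexes. `dna` is an oriented (5'->3')
# region string. Returns NULL or a list describing the solution in region
# coordinates (0-based).
find_spliced_orf <- function(dna, donor = "GT", acceptor = "AG",
                             min_intron = 40L, max_intron = 2000L,
                             code = "standard",
                             required_motifs = character(),
                             min_orf_aa = 100L, max_eval = 20000L) {
  n <- nchar(dna)
  dpos <- dimer_positions(dna, donor)
  apos <- dimer_positions(dna, acceptor)
  if (!length(dpos) || !length(apos)) return(NULL)
  grid <- expand.grid(d = dpos, a = apos)
  grid$len <- grid$a + 2L - grid$d
  grid <- grid[grid$len >= min_intron & grid$len <= max_intron, , drop = FALSE]
  if (!nrow(grid)) return(NULL)
  grid <- grid[order(grid$len, grid$d), , drop = FALSE]
  if (nrow(grid) > max_eval) grid <- grid[seq_len(max_eval), , drop = FALSE]
  for (r in seq_len(nrow(grid))) {
    d <- grid$d[r]; a2 <- grid$a[r] + 2L
    if (d < 1L || a2 >= n) next
    spliced <- paste0(substr(dna, 1L, d), substr(dna, a2 + 1L, n))
    orf <- best_spanning_orf(spliced, junction = d, code = code,
                             required_motifs = required_motifs,
                             min_orf_aa = min_orf_aa)
    if (!is.null(orf)) {
      return(list(donor = d, acceptor_end = a2, intron_len = grid$len[r],
                  orf_start = orf$start, orf_end_spliced = orf$end,
                  protein = orf$protein))
    }
  }
  NULL
}

# Longest ATG..stop ORF in `s` that covers position `junction` (0-based,
# in spliced coordinates) and whose translation matches all regexes.
best_spanning_orf <- function(s, junction, code = "standard",
                              required_motifs = character(),
                              min_orf_aa = 0L) {
  n <- nchar(s)
  tab <- genetic_code_table(code)
  stops <- names(tab)[tab == "*"]
  best <- NULL
  for (f in 0:2) {
    cs <- seq.int(f + 1L, n - 2L, by = 3L)
    codons <- substring(s, cs, cs + 2L)
    cur <- NA_integer_
    for (ci in seq_along(codons)) {
      cdn <- codons[ci]
      if (is.na(cur)) {
        if (cdn == "ATG") cur <- cs[ci]
      } else if (cdn %in% stops) {
        start0 <- cur - 1L; end0 <- cs[ci] + 2L   # 0-based half-open
        if (start0 < junction && end0 > junction &&
            end0 - start0 >= 3L * (min_orf_aa + 1L)) {
          prot <- sub("\\*$", "", translate_dna(substr(s, cur, end0), code))
          if (all(vapply(required_motifs, function(m) grepl(m, prot),
                         logical(1)))) {
            len <- end0 - start0
            if (is.null(best) || len > best$len)
              best <- list(start = start0, end = end0, len = len,
                           protein = prot)
          }
        }
        cur <- NA_integer_
      }
    }
  }
  best
}

#' Rescue rep genes that appear to require intron splicing
#'
#' Some rep coding regions cannot be read in a single frame: they contain
#' in-frame stop codons, or the endonuclease and helicase motifs fall in
#' different frames. For each candidate region this searches donor/acceptor
#' site pairs (canonical `GT..AG` by default) whose excision yields a
#' stop-free ORF spanning the junction and containing both domains, and
#' returns the minimal-intron solution as a spliced two-exon annotation.
#' Regions that can be read in a single frame are returned unchanged
#' (`spliced = FALSE`); regions with no splice solution are flagged
#' `"unresolved"` with product class `"unknown"`.
#'
#' @param genome `CircularGenome`
#' @param regions list of `list(start, end, strand)` candidate rep regions
#'   (genomic, 0-based half-open, wrap allowed)
#' @param donor,acceptor splice-site dinucleotides (default `GT`/`AG`)
#' @param min_intron,max_intron intron length bounds in nt
#' @param code genetic code
#' @param required_motifs protein regexes that the rescued ORF must
#'   contain (default: an HUH-type endonuclease motif II and a Walker A
#'   motif)
#' @param min_orf_aa smallest rescued product accepted, in residues
#'   (default 100; cruciviral Reps run 200+ residues, and short chance
#'   excisions can otherwise satisfy the motif regexes spuriously)
#' @return list of `GeneAnnotation`
#' @export
detect_splice_candidates <- function(genome, regions, donor = "GT",
                                     acceptor = "AG", min_intron = 40L,
                                     max_intron = 2000L,
                                     code = c("standard", "ciliate"),
                                     required_motifs = c("H.[HQ]",
                                                         "G.{4}GK[TS]"),
                                     min_orf_aa = 100L) {
  code <- match.arg(code)
  stopifnot(inherits(genome, "CircularGenome"))
  n <- genome$length
  out <- list()
  for (ri in seq_along(regions)) {
    reg <- regions[[ri]]
    strand <- reg$strand %||% "+"
    rlen <- segment_length(list(start = reg$start, end = reg$end), n)
    fwd <- circ_substr(genome$seq, reg$start, rlen)
    dna <- if (strand == "-") revcomp(fwd) else fwd
    # try a single-exon reading first
    # single-exon reading: any ORF containing both motifs
    single <- best_spanning_orf_any(dna, code, required_motifs, min_orf_aa)
    to_genomic <- function(p) {          # region-oriented 0-based -> genomic
      if (strand == "+") (reg$start + p) %% n
      else (reg$start + (rlen - p)) %% n
    }
    if (!is.null(single)) {
      s0 <- to_genomic(if (strand == "+") single$start else single$end)
      e0 <- to_genomic(if (strand == "+") single$end else single$start)
      out[[length(out) + 1L]] <- gene_annotation(
        id = sprintf("%s_rep%d", genome$id, ri), genome_id = genome$id,
        segments = list(list(start = s0, end = e0)), strand = strand,
        genetic_code = code, spliced = FALSE, product_class = "rep",
        protein = single$protein)
      next
    }
    sol <- find_spliced_orf(dna, donor, acceptor, min_intron, max_intron,
                            code, required_motifs, min_orf_aa = min_orf_aa)
    if (is.null(sol)) {
      out[[length(out) + 1L]] <- gene_annotation(
        id = sprintf("%s_rep%d", genome$id, ri), genome_id = genome$id,
        segments = list(list(start = reg$start, end = reg$end)),
        strand = strand, genetic_code = code, spliced = FALSE,
        product_class = "unknown", flags = "unresolved")
      next
    }
    # exon 1: [orf_start, donor); exon 2: [acceptor_end, orf_end in region)
    e1 <- c(sol$orf_start, sol$donor)
    e2 <- c(sol$acceptor_end,
            sol$orf_end_spliced + (sol$acceptor_end - sol$donor))
    seg <- function(a, b) {
      if (strand == "+") list(start = to_genomic(a), end = to_genomic(b))
      else list(start = to_genomic(b), end = to_genomic(a))
    }
    out[[length(out) + 1L]] <- gene_annotation(
      id = sprintf("%s_rep%d", genome$id, ri), genome_id = genome$id,
      segments = list(seg(e1[1], e1[2]), seg(e2[1], e2[2])),
      strand = strand, genetic_code = code, spliced = TRUE,
      product_class = "rep", protein = sol$protein)
  }
  out
}

# Longest ATG..stop ORF anywhere in s whose translation matches all
# regexes (used when single-exon reading need not span a junction).
best_spanning_orf_any <- function(s, code, required_motifs,
                                  min_orf_aa = 0L) {
  n <- nchar(s)
  tab <- genetic_code_table(code)
  stops <- names(tab)[tab == "*"]
  best <- NULL
  for (f in 0:2) {
    cs <- seq.int(f + 1L, n - 2L, by = 3L)
    codons <- substring(s, cs, cs + 2L)
    cur <- NA_integer_
    for (ci in seq_along(codons)) {
      cdn <- codons[ci]
      if (is.na(cur)) {
        if (cdn == "ATG") cur <- cs[ci]
      } else if (cdn %in% stops) {
        prot <- sub("\\*$", "", translate_dna(substr(s, cur, cs[ci] + 2L), code))
        if (nchar(prot) >= min_orf_aa &&
            all(vapply(required_motifs, function(m) grepl(m, prot),
                       logical(1)))) {
          len <- cs[ci] + 3L - cur
          if (is.null(best) || len > best$len)
            best <- list(start = cur - 1L, end = cs[ci] + 2L, len = len,
                         protein = prot)
        }
        cur <- NA_integer_
      }
    }
  }
  best
}
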