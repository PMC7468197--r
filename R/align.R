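# Protein alignment, bit scores and E-values.
#
# Local and global alignments are computed with an affine-gap dynamic
# program (BLAST-style gap cost: a gap of length L costs open + L*extend).
# Raw scores are converted to bit scores with the Karlin-Altschul
# transformation using the gapped BLOSUM62 parameters, so results are
# reproducible without an external search engine.

#' Karlin-Altschul parameters used for bit scores and E-values
#'
#' Gapped BLOSUM62 defaults: lambda = 0.267, K = 0.041.
#' @return list with `lambda` and `K`
#' @export
karlin_altschul_params <- function() list(lambda = 0.267, K = 0.041)

#' Convert a raw alignment score to a bit score
#' @param raw raw alignment score
#' @param params list with `lambda`, `K`
#' @return bit score
#' @export
bit_score <- function(raw, params = karlin_altschul_params()) {
  (params$lambda * raw - log(params$K)) / log(2)
}

#' E-value of a raw score over a search space
#' @param raw raw alignment score
#' @param m,n lengths of the two sequences (search space `m * n`)
#' @param params list with `lambda`, `K`
#' @return expected number of chance alignments with score >= `raw`
#' @export
evalue_score <- function(raw, m, n, params = karlin_altschul_params()) {
  params$K * m * n * exp(-params$lambda * raw)
}

load_sub_matrix <- function(matrix_name) {
  known <- c("BLOSUM45", "BLOSUM50", "BLOSUM62", "BLOSUM80", "BLOSUM100",
             "PAM30", "PAM40", "PAM70", "PAM120", "PAM250")
  if (!matrix_name %in% known)
    stop("unknown substitution matrix: ", matrix_name, call. = FALSE)
  env <- new.env()
  utils::data(list = matrix_name, package = "Biostrings", envir = env)
  get(matrix_name, envir = env)
}

# Identity and length over aligned columns of a pairwiseAlignment.
alignment_identity <- function(al, exclude_terminal_gaps = FALSE) {
  p <- split_chars(as.character(Biostrings::alignedPattern(al)))
  s <- split_chars(as.character(Biostrings::alignedSubject(al)))
  keep <- rep(TRUE, length(p))
  if (exclude_terminal_gaps) {
    gapcol <- p == "-" | s == "-"
    inner <- which(!gapcol)
    if (length(inner)) {
      keep[seq_along(keep) < inner[1]] <- FALSE
      keep[seq_along(keep) > inner[length(inner)]] <- FALSE
    }
  }
  p <- p[keep]; s <- s[keep]
  list(n_id = sum(p == s & p != "-"), len = length(p))
}

#' Optimal local protein alignment with bit score and E-value
#'
#' Smith-Waterman local alignment under an affine gap model (a gap of
#' length L costs `gap_open + L * gap_extend`). The raw score is converted
#' to a bit score via the Karlin-Altschul transformation with the gapped
#' BLOSUM62 parameters; the E-value uses search space `m * n`.
#'
#' @param query,ref amino-acid strings (non-empty)
#' @param matrix substitution matrix name (default `"BLOSUM62"`)
#' @param gap_open,gap_extend affine gap penalties (defaults 11, 1)
#' @param query_id,ref_id ids recorded in the hit
#' @return an `AlignmentHit`: list with `query_id`, `ref_id`, `raw`,
#'   `bits`, `evalue`, `pident`, `aln_len`
#' @export
smith_waterman <- function(query, ref, matrix = "BLOSUM62", gap_open = 11,
                           gap_extend = 1, query_id = "query",
                           ref_id = "ref") {
  if (!nchar(query) || !nchar(ref))
    stop("empty sequence in alignment", call. = FALSE)
  sub <- load_sub_matrix(matrix)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(ref),
    type = "local", substitutionMatrix = sub,
    gapOpening = gap_open, gapExtension = gap_extend)
  raw <- as.numeric(Biostrings::score(al))
  idy <- alignment_identity(al)
  params <- karlin_altschul_params()
  structure(
    list(query_id = query_id, ref_id = ref_id, raw = raw,
         bits = bit_score(raw, params),
         evalue = evalue_score(raw, nchar(query), nchar(ref), params),
         pident = if (idy$len) 100 * idy$n_id / idy$len else 0,
         aln_len = idy$len),
    class = "AlignmentHit")
}

#' @export
print.AlignmentHit <- function(x, ...) {
  cat(sprintf("<AlignmentHit> %s vs %s: raw %.0f, bits %.1f, E %.2g, %.1f%% id over %d\n",
              x$query_id, x$ref_id, x$raw, x$bits, x$evalue, x$pident,
              x$aln_len))
  invisible(x)
}

#' Six-frame translated peptides of a circular contig
#'
#' Translates all six frames across the origin and splits at stop codons.
#'
#' @param genome `CircularGenome`
#' @param min_aa shortest peptide kept (default 20)
#' @return character vector of peptides
#' @export
six_frame_peptides <- function(genome, min_aa = 20L) {
  n <- genome$length
  peps <- character()
  for (strand in c("+", "-")) {
    S <- if (strand == "+") genome$seq else revcomp(genome$seq)
    ext <- paste0(S, S)
    for (f in 0:2) {
      len <- ((2L * n - f) %/% 3L) * 3L
      prot <- translate_dna(substr(ext, f + 1L, f + len), "standard")
      parts <- strsplit(prot, "*", fixed = TRUE)[[1]]
      peps <- c(peps, parts[nchar(parts) >= min_aa])
    }
  }
  unique(peps)
}

#' Screen contigs for capsid-like coding capacity
#'
#' Six-frame translated search of each contig against a capsid reference
#' protein set; a contig is retained when its best local-alignment bit
#' score reaches `bit_threshold`. This is the discovery filter that
#' selects candidate crucivirus genomes from assembled circular contigs.
#'
#' @param contigs `SequenceCollection` or list of `CircularGenome`
#' @param capsid_refs named character vector (or `AAStringSet`) of capsid
#'   reference proteins
#' @param bit_threshold minimum best bit score to retain a contig
#'   (default 50)
#' @param min_aa shortest translated peptide scanned
#' @return data frame with one row per retained contig (`id`, `ref_id`,
#'   `raw`, `bits`, `evalue`, `pident`), sorted by decreasing bit score
#' @export
screen_capsid_candidates <- function(contigs, capsid_refs, bit_threshold = 50,
                                     min_aa = 20L) {
  recs <- if (inherits(contigs, "SequenceCollection")) contigs$records else contigs
  nm <- names(capsid_refs)
  refs <- as.character(capsid_refs)
  names(refs) <- nm
  if (!length(refs)) stop("capsid reference set is empty", call. = FALSE)
  if (is.null(names(refs))) names(refs) <- paste0("ref", seq_along(refs))
  sub <- load_sub_matrix("BLOSUM62")
  rows <- list()
  for (g in recs) {
    peps <- six_frame_peptides(g, min_aa = min_aa)
    best <- NULL
    if (length(peps)) {
      pepset <- Biostrings::AAStringSet(peps)
      for (ri in seq_along(refs)) {
        sc <- Biostrings::pairwiseAlignment(
          pepset, Biostrings::AAString(refs[[ri]]), type = "local",
          substitutionMatrix = sub, gapOpening = 11, gapExtension = 1,
          scoreOnly = TRUE)
        top <- which.max(sc)
        if (is.null(best) || sc[top] > best$raw) {
          best <- smith_waterman(peps[top], refs[[ri]], query_id = g$id,
                                 ref_id = names(refs)[ri])
        }
      }
    }
    if (!is.null(best) && best$bits >= bit_threshold) {
      rows[[length(rows) + 1L]] <- data.frame(
        id = g$id, ref_id = best$ref_id, raw = best$raw, bits = best$bits,
        evalue = best$evalue, pident = best$pident,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(id = character(), ref_id = character(), raw = numeric(),
                      bits = numeric(), evalue = numeric(),
                      pident = numeric(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out[order(-out$bits), , drop = FALSE]
}
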