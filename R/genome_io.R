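#' Construct a circular genome record
#'
#' A `CircularGenome` holds a resolved circular nucleotide sequence together
#' with its provenance (source contig, number of terminally redundant bases
#' trimmed) and its feature annotations (gene and stem-loop calls).
#' Coordinates of all features are 0-based, half-open, anchored on the
#' forward strand; a feature segment whose end is less than or equal to its
#' start wraps across the sequence origin.
#'
#' @param id record identifier
#' @param seq DNA sequence (uppercased; `U` is mapped to `T`); only
#'   `A,C,G,T,N` allowed
#' @param redundancy_trimmed number of bases removed from the 3' end of the
#'   source contig when circularity was resolved
#' @param source `"assembled_contig"` or `"finished_record"`
#' @param features list of feature annotations (may be empty)
#' @return an object of class `CircularGenome`
#' @export
circular_genome <- function(id, seq, redundancy_trimmed = 0L,
                            source = c("assembled_contig", "finished_record"),
                            features = list()) {
  source <- match.arg(source)
  stopifnot_scalar_dna(seq)
  seq <- toupper(seq)
  seq <- gsub("U", "T", seq, fixed = TRUE)
  if (nchar(seq) < 1L) stop("empty sequence for '", id, "'", call. = FALSE)
  if (grepl("[^ACGTN]", seq))
    stop("sequence of '", id, "' contains characters outside {A,C,G,T,N,U}",
         call. = FALSE)
  structure(
    list(id = as.character(id), seq = seq, length = nchar(seq),
         redundancy_trimmed = as.integer(redundancy_trimmed),
         source = source, features = features),
    class = "CircularGenome"
  )
}

#' @export
print.CircularGenome <- function(x, ...) {
  cat(sprintf("<CircularGenome> %s: %d bp, GC %.1f%%, %d feature(s), trimmed %d bp\n",
              x$id, x$length, gc_content(x), length(x$features),
              x$redundancy_trimmed))
  invisible(x)
}

#' @export
length.CircularGenome <- function(x) x$length

#' Construct a sequence collection
#'
#' An ordered set of genome/contig records with unique ids.
#'
#' @param records list of `CircularGenome` objects
#' @param format_origin `"fasta"` or `"genbank"`
#' @return an object of class `SequenceCollection`
#' @export
sequence_collection <- function(records, format_origin = c("fasta", "genbank")) {
  format_origin <- match.arg(format_origin)
  ids <- vapply(records, function(r) r$id, character(1))
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate sequence id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  names(records) <- ids
  structure(list(records = records, format_origin = format_origin),
            class = "SequenceCollection")
}

#' @export
print.SequenceCollection <- function(x, ...) {
  cat(sprintf("<SequenceCollection> %d record(s) [%s]\n",
              length(x$records), x$format_origin))
  invisible(x)
}

#' @export
length.SequenceCollection <- function(x) length(x$records)

#' Read sequences from a FASTA file
#'
#' Sequences are uppercased and `U` is mapped to `T`. Each record becomes a
#' `CircularGenome` with no features and `redundancy_trimmed = 0`.
#'
#' @param path FASTA file
#' @param source provenance tag stored on each record
#' @return a `SequenceCollection`
#' @export
read_fasta <- function(path, source = "assembled_contig") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  records <- lapply(seq_along(set), function(i) {
    circular_genome(ids[i], as.character(set[[i]]), source = source)
  })
  sequence_collection(records, "fasta")
}

#' Write a collection (or list of genomes) to FASTA
#'
#' @param x `SequenceCollection` or list of `CircularGenome`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_fasta <- function(x, path) {
  recs <- if (inherits(x, "SequenceCollection")) x$records else x
  seqs <- Biostrings::DNAStringSet(vapply(recs, function(r) r$seq, character(1)))
  names(seqs) <- vapply(recs, function(r) r$id, character(1))
  Biostrings::writeXStringSet(seqs, path, width = 70)
  invisible(path)
}

#' Detect terminal redundancy and resolve a circular genome
#'
#' De novo assemblers emit circular replicons as linear contigs whose 3' end
#' repeats their 5' start. The longest exact suffix of the contig that
#' equals its prefix is searched from `floor(n/2)` down to `min_overlap`;
#' when found, the suffix is trimmed and the contig is declared circular.
#'
#' @param contig DNA string (or `CircularGenome`, whose sequence is used)
#' @param min_overlap smallest overlap accepted as evidence of circularity
#'   (default 10)
#' @param id id for the resolved genome
#' @return list with `overlap_len` (integer, 0 when none found) and
#'   `genome` (a `CircularGenome`, or `NULL` when no redundancy was found)
#' @export
detect_terminal_redundancy <- function(contig, min_overlap = 10L,
                                       id = "contig") {
  if (inherits(contig, "CircularGenome")) {
    id <- contig$id
    contig <- contig$seq
  }
  stopifnot_scalar_dna(contig, "contig")
  min_overlap <- as.integer(min_overlap)
  if (min_overlap < 10L) stop("min_overlap must be >= 10", call. = FALSE)
  n <- nchar(contig)
  if (n < 2L * min_overlap) {
    warning("contig shorter than 2*min_overlap; cannot assess circularity")
    return(list(overlap_len = 0L, genome = NULL))
  }
  for (k in seq.int(n %/% 2L, min_overlap)) {
    if (substr(contig, n - k + 1L, n) == substr(contig, 1L, k)) {
      g <- circular_genome(id, substr(contig, 1L, n - k),
                           redundancy_trimmed = k, source = "assembled_contig")
      return(list(overlap_len = k, genome = g))
    }
  }
  list(overlap_len = 0L, genome = NULL)
}

#' GC content of a genome
#'
#' Percentage of G+C over unambiguous bases; `N` is excluded from the
#' denominator.
#'
#' @param genome `CircularGenome` or DNA string
#' @return percent G+C
#' @export
gc_content <- function(genome) {
  seq <- if (inherits(genome, "CircularGenome")) genome$seq else toupper(genome)
  counts <- table(factor(split_chars(seq), levels = c(DNA_BASES, "N")))
  denom <- sum(counts[DNA_BASES])
  if (denom == 0L)
    stop("GC content undefined: sequence has no unambiguous bases",
         call. = FALSE)
  100 * sum(counts[c("G", "C")]) / denom
}

# Booth's least-rotation algorithm; returns 0-based offset of the
# lexicographically least rotation.
least_rotation_offset <- function(seq) {
  s <- split_chars(paste0(seq, seq))
  n <- nchar(seq)
  f <- rep.int(-1L, 2L * n)
  k <- 0L
  for (j in seq.int(2L, 2L * n)) {
    sj <- s[j]
    i <- f[j - k - 1L]
    while (i != -1L && sj != s[k + i + 2L]) {
      if (sj < s[k + i + 2L]) k <- j - i - 2L
      i <- f[i + 1L]
    }
    if (sj != s[k + i + 2L]) {
      if (sj < s[k + 1L]) k <- j - 1L
      f[j - k] <- -1L
    } else {
      f[j - k] <- i + 1L
    }
  }
  k
}

#' Canonical rotation of a circular genome
#'
#' Rotates the sequence to its lexicographically least rotation on the
#' forward strand and shifts all feature coordinates accordingly. Applying
#' the function twice gives the same result as applying it once, which
#' makes circular sequence comparisons deterministic.
#'
#' @param genome a `CircularGenome`
#' @return the rotated `CircularGenome`
#' @export
canonical_rotation <- function(genome) {
  stopifnot(inherits(genome, "CircularGenome"))
  k <- least_rotation_offset(genome$seq)
  rotate_genome(genome, k)
}

#' Rotate a circular genome to a new origin
#'
#' @param genome a `CircularGenome`
#' @param k 0-based position that becomes the new first base
#' @return rotated `CircularGenome` with all feature coordinates shifted
#' @export
rotate_genome <- function(genome, k) {
  n <- genome$length
  k <- ((as.integer(k) %% n) + n) %% n
  if (k == 0L) return(genome)
  g <- genome
  g$seq <- rotate_string(genome$seq, k)
  shift <- function(pos) ((pos - k) %% n + n) %% n
  g$features <- lapply(genome$features, function(f) shift_feature(f, shift))
  g
}

# Applies a coordinate map to a feature annotation.
shift_feature <- function(f, shift) {
  if (inherits(f, "GeneAnnotation")) {
    f$segments <- lapply(f$segments, function(s) {
      s$start <- shift(s$start); s$end <- shift(s$end); s
    })
  } else if (inherits(f, "StemLoopAnnotation")) {
    f$motif$position <- shift(f$motif$position)
    f$hairpin$start <- shift(f$hairpin$start)
    f$hairpin$end <- shift(f$hairpin$end)
  }
  f
}
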