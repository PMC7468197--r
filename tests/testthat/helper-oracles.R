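# Independent oracles used by the test suite. These deliberately use
# different algorithms (or different implementations) than the package
# code they check.

AAS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
BASES <- c("A", "C", "G", "T")

rand_dna <- function(n) paste(sample(BASES, n, TRUE), collapse = "")
rand_prot <- function(n) paste(sample(AAS, n, TRUE), collapse = "")

# Longest proper suffix of x that is also a prefix, checked naively.
bf_longest_prefix_suffix <- function(x, min_len) {
  n <- nchar(x)
  for (k in seq.int(n %/% 2, min_len)) {
    if (substr(x, n - k + 1, n) == substr(x, 1, k)) return(k)
  }
  0L
}

# Maximum number of nested base pairs (Watson-Crick + G.T wobble,
# min_loop unpaired bases inside every pair), by top-down memoized
# interval recursion on "last base unpaired or paired with k".
bf_max_pairs <- function(s, min_loop = 3L) {
  ch <- strsplit(toupper(s), "")[[1]]
  n <- length(ch)
  pairable <- function(a, b) {
    p <- paste0(ch[a], ch[b])
    p %in% c("AT", "TA", "GC", "CG", "GT", "TG")
  }
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (j - i < min_loop + 1L) return(0L)
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    best <- rec(i, j - 1L)
    for (k in i:(j - min_loop - 1L)) {
      if (pairable(k, j)) {
        v <- 1L + rec(k + 1L, j - 1L) + (if (k > i) rec(i, k - 1L) else 0L)
        if (v > best) best <- v
      }
    }
    memo[[key]] <- best
    best
  }
  if (n < min_loop + 2L) return(0L)
  rec(1L, n)
}

# Validity of a nested pairing for a window.
valid_nested_pairing <- function(s, pairs, min_loop = 3L) {
  if (!nrow(pairs)) return(TRUE)
  ch <- strsplit(toupper(s), "")[[1]]
  idx <- c(pairs[, 1], pairs[, 2])
  if (any(duplicated(idx))) return(FALSE)          # each base pairs once
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    if (j - i - 1 < min_loop) return(FALSE)
    p <- paste0(ch[i], ch[j])
    if (!p %in% c("AT", "TA", "GC", "CG", "GT", "TG")) return(FALSE)
    # nesting: no crossing pairs
    for (r2 in seq_len(nrow(pairs))) {
      i2 <- pairs[r2, 1]; j2 <- pairs[r2, 2]
      if (i2 > i && i2 < j && j2 > j) return(FALSE)
      if (i2 < i && j2 > i && j2 < j) return(FALSE)
    }
  }
  TRUE
}

# Textbook affine-gap Smith-Waterman (three-state DP, gap of length L
# costs open + L * ext), score only.
bf_smith_waterman <- function(q, r, sub, open = 11, ext = 1) {
  qq <- strsplit(q, "")[[1]]; rr <- strsplit(r, "")[[1]]
  n <- length(qq); m <- length(rr)
  M <- matrix(-Inf, n + 1, m + 1)
  Ix <- matrix(-Inf, n + 1, m + 1)
  Iy <- matrix(-Inf, n + 1, m + 1)
  M[1, ] <- 0; M[, 1] <- 0
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- sub[qq[i - 1], rr[j - 1]]
      M[i, j] <- max(0, M[i - 1, j - 1], Ix[i - 1, j - 1],
                     Iy[i - 1, j - 1]) + s
      Ix[i, j] <- max(M[i - 1, j] - open - ext, Ix[i - 1, j] - ext)
      Iy[i, j] <- max(M[i, j - 1] - open - ext, Iy[i, j - 1] - ext)
      if (M[i, j] > best) best <- M[i, j]
    }
  }
  best
}

blosum62 <- local({
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  env$BLOSUM62
})

# A genome with a single planted hairpin in a pairing-inert (poly-A)
# background: the detected geometry is forced by construction.
polyA_hairpin_genome <- function(stem = "GCGCGCGCGCG", loop_pad = 1L,
                                 motif = "TAGTATTAC", lead = 400L,
                                 total = 1200L) {
  loop <- paste0(strrep("A", loop_pad), motif, strrep("A", loop_pad))
  hp <- paste0(stem, loop,
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString(stem))))
  seq <- paste0(strrep("A", lead), hp,
                strrep("A", total - lead - nchar(hp)))
  list(genome = circular_genome("hp", seq),
       motif_pos = lead + nchar(stem) + loop_pad,
       hairpin_start = lead, stem_len = nchar(stem),
       loop_len = nchar(loop))
}

# Cache for expensive shared fixtures (built once per test run).
.fixtures <- new.env(parent = emptyenv())
get_fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}
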