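# Internal sequence utilities. Sequences are plain uppercase character
# scalars over {A,C,G,T,N}; Biostrings objects are used at the boundaries
# (file formats, alignment) and converted as needed.

DNA_BASES <- c("A", "C", "G", "T")

IUPAC_MAP <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Rotate a sequence string
#'
#' Returns the rotation of `x` beginning at 0-based offset `k`.
#' @param x character scalar
#' @param k 0-based offset in `[0, nchar(x))`
#' @return rotated character scalar
#' @keywords internal
rotate_string <- function(x, k) {
  n <- nchar(x)
  k <- ((k %% n) + n) %% n
  if (k == 0L) return(x)
  paste0(substr(x, k + 1L, n), substr(x, 1L, k))
}

# substring on a circle, 0-based start, length len (may wrap)
circ_substr <- function(seq, start, len) {
  n <- nchar(seq)
  start <- ((start %% n) + n) %% n
  if (start + len <= n) {
    substr(seq, start + 1L, start + len)
  } else {
    paste0(substr(seq, start + 1L, n), substr(seq, 1L, start + len - n))
  }
}

random_dna <- function(n, gc = 50) {
  p <- c(A = (100 - gc) / 200, C = gc / 200, G = gc / 200, T = (100 - gc) / 200)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p[DNA_BASES]), collapse = "")
}

split_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_dna <- function(x, what = "sequence") {
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop(what, " must be a single character string", call. = FALSE)
  invisible(x)
}
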