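# Conserved-motif profiling of crucivirus proteins.
#
# Rep carries an N-terminal HUH-endonuclease domain (motifs I, II, III)
# and a C-terminal superfamily-3 helicase domain (Walker A, Walker B,
# motif C, Arg finger). Motif patterns are data, not code: they ship as a
# default table of regexes with expected regions and can be replaced
# wholesale. Capsid proteins are partitioned into the tombusvirus-like
# R (RNA-binding), S (shell) and P (protruding) domains.

HYDROPHOBIC_AA <- c("A", "V", "L", "I", "M", "F", "W", "C")

#' Default Rep motif pattern table
#'
#' One row per conserved motif: a regular expression and the region of the
#' protein in which it is expected (`n_half` for the endonuclease domain,
#' `c_half` for the helicase domain, `downstream_motif_c` for the Arg
#' finger). The patterns are consensus-style defaults and are editable
#' without code change; the geminivirus-like GRS pattern is disabled by
#' default and marked low confidence.
#'
#' @return data frame with columns `motif`, `regex`, `region`, `enabled`,
#'   `low_confidence`
#' @export
default_rep_motif_patterns <- function() {
  data.frame(
    motif = c("motif_I", "motif_II", "motif_III", "walker_A", "walker_B",
              "motif_C", "arg_finger", "grs"),
    regex = c("[FWL]T[LIV]NN", "H.[HQ]", "Y.{2,3}K", "G.{4}GK[TS]",
              "[AVLIMFWC]{2}D[DE]", "[AVLIMFWC].TSN", "R", "[FY].{2}K.{4,12}W"),
    region = c("n_half", "n_half", "n_half", "c_half", "c_half", "c_half",
               "downstream_motif_c", "n_half"),
    enabled = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
    low_confidence = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE)
}

#' Read a motif pattern table from TSV
#'
#' Columns as in [default_rep_motif_patterns()].
#' @param path TSV file
#' @return data frame of motif patterns
#' @export
read_motif_patterns <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("motif", "regex", "region")
  if (!all(need %in% names(df)))
    stop("motif pattern file must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  if (is.null(df$enabled)) df$enabled <- TRUE
  if (is.null(df$low_confidence)) df$low_confidence <- FALSE
  df
}

search_region <- function(protein, region, n_half_frac = 0.6,
                          motif_c_end = NA_integer_, downstream_span = 40L) {
  L <- nchar(protein)
  switch(region,
         n_half = c(1L, ceiling(L * n_half_frac)),
         c_half = c(floor(L * (1 - n_half_frac)) + 1L, L),
         downstream_motif_c = {
           if (is.na(motif_c_end)) return(NULL)
           c(motif_c_end + 1L, min(L, motif_c_end + downstream_span))
         },
         c(1L, L))
}

#' Profile the conserved motifs of a Rep protein
#'
#' Each motif is searched with its regular expression inside its expected
#' region: endonuclease motifs in the N-terminal portion, helicase motifs
#' in the C-terminal portion, and the Arg finger downstream of motif C.
#' The motif II trigram (His + 2 residues) is extracted and classified
#' with [classify_motif2()]. Absence of a motif is recorded, not an error.
#'
#' @param rep amino-acid string (length >= 50)
#' @param motif_defs pattern table (see [default_rep_motif_patterns()])
#' @param n_half_frac fraction of the protein searched as the N-terminal
#'   region (the C-terminal region is the symmetric complement)
#' @return a `RepMotifProfile`: per-motif `(present, position, seq)`,
#'   `motif2_trigram`, `motif2_class`, `grs_present`,
#'   `helicase_motifs_all_absent`
#' @export
find_rep_motifs <- function(rep, motif_defs = default_rep_motif_patterns(),
                            n_half_frac = 0.6) {
  if (nchar(rep) < 50L)
    stop("Rep protein shorter than 50 residues", call. = FALSE)
  rep <- toupper(rep)
  defs <- motif_defs[motif_defs$enabled, , drop = FALSE]
  motifs <- list()
  motif_c_end <- NA_integer_
  # search motif C before the arg finger so the downstream window is known
  ord <- order(defs$region == "downstream_motif_c")
  for (r in seq_len(nrow(defs))[ord]) {
    name <- defs$motif[r]
    span <- search_region(rep, defs$region[r], n_half_frac, motif_c_end)
    rec <- list(present = FALSE, position = NA_integer_, seq = NA_character_)
    if (!is.null(span) && span[1] <= span[2]) {
      sub <- substr(rep, span[1], span[2])
      m <- regexpr(defs$regex[r], sub, perl = TRUE)
      if (m[1] != -1L) {
        pos <- span[1] + as.integer(m[1]) - 1L
        rec <- list(present = TRUE, position = pos,
                    seq = substr(rep, pos, pos + attr(m, "match.length") - 1L))
        if (name == "motif_C") motif_c_end <- pos + attr(m, "match.length") - 1L
      }
    }
    motifs[[name]] <- rec
  }
  trigram <- if (isTRUE(motifs$motif_II$present))
    substr(rep, motifs$motif_II$position, motifs$motif_II$position + 2L)
  else NA_character_
  core <- c("walker_A", "walker_B", "motif_C", "arg_finger")
  heli_absent <- !any(vapply(core, function(m)
    isTRUE(motifs[[m]]$present), logical(1)))
  structure(
    list(motifs = motifs,
         motif2_trigram = trigram,
         motif2_class = classify_motif2(trigram),
         grs_present = isTRUE(motifs$grs$present),
         helicase_motifs_all_absent = heli_absent),
    class = "RepMotifProfile")
}

#' @export
print.RepMotifProfile <- function(x, ...) {
  pres <- names(Filter(function(m) isTRUE(m$present), x$motifs))
  cat(sprintf("<RepMotifProfile> motif II %s (%s); present: %s\n",
              x$motif2_trigram %||% "-", x$motif2_class,
              if (length(pres)) paste(pres, collapse = ",") else "none"))
  invisible(x)
}

#' Classify a motif II trigram
#'
#' The canonical HUH motif holds two histidines separated by a bulky
#' hydrophobic residue; common variants replace the second histidine with
#' glutamine (HUQ), or additionally replace the hydrophobic residue (e.g.
#' HYQ). Classes: `HUH` (H, hydrophobic, H), `HUQ` (H, hydrophobic, Q),
#' `HYQ` (exactly H-Y-Q), `other_alt` (any other H-initial trigram),
#' `absent` (no motif II hit / trigram not starting with H).
#'
#' @param trigram three residues starting at the motif II histidine, or
#'   `NA`
#' @param hydrophobic residues counted as hydrophobic (configurable)
#' @return character class
#' @export
classify_motif2 <- function(trigram, hydrophobic = HYDROPHOBIC_AA) {
  if (is.null(trigram) || is.na(trigram)) return("absent")
  trigram <- toupper(trigram)
  if (nchar(trigram) != 3L || substr(trigram, 1, 1) != "H") return("absent")
  a2 <- substr(trigram, 2, 2); a3 <- substr(trigram, 3, 3)
  if (trigram == "HYQ") return("HYQ")
  if (a2 %in% hydrophobic && a3 == "H") return("HUH")
  if (a2 %in% hydrophobic && a3 == "Q") return("HUQ")
  "other_alt"
}

#' Call CruV versus CruCGE
#'
#' A circular capsid-encoding genome is a crucivirus (CruV) when it
#' carries a Rep with at least one detectable conserved motif; it is a
#' crucivirus-like circular genetic element (CruCGE) when it has no Rep
#' CDS at all, or a Rep-homologous region in which none of the seven
#' conserved motifs can be detected.
#'
#' @param profile `RepMotifProfile` or `NULL` when no Rep CDS was found
#' @param has_rep_homology logical; was a Rep CDS/homologous region found?
#' @return `"CruV"` or `"CruCGE"`
#' @export
call_cruv_or_crucge <- function(profile, has_rep_homology) {
  if (!isTRUE(has_rep_homology) || is.null(profile)) return("CruCGE")
  seven <- c("motif_I", "motif_II", "motif_III", "walker_A", "walker_B",
             "motif_C", "arg_finger")
  n_present <- sum(vapply(seven, function(m)
    isTRUE(profile$motifs[[m]]$present), logical(1)))
  if (n_present == 0L) "CruCGE" else "CruV"
}

# --- capsid domain partition ----------------------------------------------

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Build a gapless S-domain log-odds profile from reference segments
#'
#' @param segments character vector of equal-length S-domain sequences
#' @param pseudocount added to each residue count
#' @return matrix (20 residues x width) of log-odds scores against a
#'   uniform background
#' @export
build_sdomain_profile <- function(segments, pseudocount = 0.5) {
  stopifnot(length(segments) >= 1L)
  w <- unique(nchar(segments))
  if (length(w) != 1L)
    stop("S-domain reference segments must have equal length", call. = FALSE)
  counts <- matrix(pseudocount, nrow = length(AA20), ncol = w,
                   dimnames = list(AA20, NULL))
  for (s in segments) {
    ch <- split_chars(toupper(s))
    for (p in seq_len(w)) if (ch[p] %in% AA20)
      counts[ch[p], p] <- counts[ch[p], p] + 1
  }
  freq <- sweep(counts, 2L, colSums(counts), "/")
  log(freq / (1 / length(AA20)))
}

profile_scan <- function(protein, profile) {
  w <- ncol(profile)
  L <- nchar(protein)
  if (L < w) return(NULL)
  ch <- split_chars(toupper(protein))
  idx <- match(ch, AA20)
  scores <- vapply(seq_len(L - w + 1L), function(s) {
    cols <- seq.int(s, s + w - 1L)
    vals <- profile[cbind(idx[cols], seq_len(w))]
    sum(vals, na.rm = TRUE)
  }, numeric(1))
  list(start = which.max(scores), score = max(scores), all = scores)
}

#' Partition a capsid protein into R, S and P domains
#'
#' The shell (S) domain is located as the best-scoring gapless window
#' against a position-specific log-odds profile built from reference
#' S-domains; the RNA-binding (R) domain is the prefix and the protruding
#' (P) domain the suffix, so the three domains tile the protein. Within
#' the R-domain, the glycine-rich tract is the maximal window of at least
#' `gly_min_len` residues with >= 50% glycine, and `basic_fraction_r` is
#' the fraction of K/R/H residues.
#'
#' @param capsid amino-acid string (length >= 60)
#' @param s_profile log-odds matrix from [build_sdomain_profile()]
#' @param score_floor minimum profile score per column to accept an
#'   S-domain placement (default 0: better than background on average)
#' @param gly_min_len minimum glycine-tract length (default 8)
#' @return a `CapsidDomains` list: `r_domain`, `s_domain`, `p_domain`
#'   (1-based inclusive `c(start, end)`; an empty domain has end < start),
#'   `gly_tract`, `ca_motif_positions`, `basic_fraction_r`, `flags`
#' @export
partition_capsid <- function(capsid, s_profile, score_floor = 0,
                             gly_min_len = 8L) {
  L <- nchar(capsid)
  if (L < 60L) stop("capsid protein shorter than 60 residues", call. = FALSE)
  hit <- profile_scan(capsid, s_profile)
  w <- ncol(s_profile)
  flags <- character()
  if (is.null(hit) || hit$score < score_floor * w) {
    warning("no S-domain placement above the score floor")
    flags <- "no_s_domain"
    s_dom <- c(1L, 0L)
    r_dom <- c(1L, L)
    p_dom <- c(L + 1L, L)
  } else {
    s_dom <- c(hit$start, hit$start + w - 1L)
    r_dom <- c(1L, s_dom[1] - 1L)
    p_dom <- c(s_dom[2] + 1L, L)
  }
  r_seq <- if (r_dom[2] >= r_dom[1]) substr(capsid, r_dom[1], r_dom[2]) else ""
  s_seq <- if (s_dom[2] >= s_dom[1]) substr(capsid, s_dom[1], s_dom[2]) else ""
  gly <- max_gly_tract(r_seq, gly_min_len)
  if (!is.null(gly)) gly <- gly + r_dom[1] - 1L
  basic <- if (nchar(r_seq))
    mean(split_chars(r_seq) %in% c("K", "R", "H")) else 0
  ca <- find_ca_motif(s_seq)
  if (length(ca)) ca <- ca + s_dom[1] - 1L
  structure(
    list(r_domain = r_dom, s_domain = s_dom, p_domain = p_dom,
         gly_tract = gly, ca_motif_positions = ca,
         basic_fraction_r = basic, flags = flags),
    class = "CapsidDomains")
}

#' @export
print.CapsidDomains <- function(x, ...) {
  fmt <- function(d) if (d[2] >= d[1]) sprintf("%d-%d", d[1], d[2]) else "-"
  cat(sprintf("<CapsidDomains> R %s | S %s | P %s; Gly tract %s; basic R %.2f\n",
              fmt(x$r_domain), fmt(x$s_domain), fmt(x$p_domain),
              if (is.null(x$gly_tract)) "-" else
                sprintf("%d-%d", x$gly_tract[1], x$gly_tract[2]),
              x$basic_fraction_r))
  invisible(x)
}

# Maximal window of length >= min_len with >= 50% glycine; returns
# c(start, end) (1-based) or NULL. Maximality: the longest qualifying
# window, ties broken by the earliest start.
max_gly_tract <- function(seq, min_len = 8L) {
  L <- nchar(seq)
  if (L < min_len) return(NULL)
  g <- split_chars(seq) == "G"
  cs <- c(0L, cumsum(g))
  best <- NULL
  for (len in seq.int(L, min_len)) {
    for (s in seq_len(L - len + 1L)) {
      if ((cs[s + len] - cs[s]) / len >= 0.5) {
        best <- c(s, s + len - 1L)
        break
      }
    }
    if (!is.null(best)) break
  }
  best
}

#' Find calcium-binding DxDxxD motifs
#'
#' All (overlapping) matches of the pattern D-x-D-x-x-D.
#'
#' @param segment amino-acid string (typically the S-domain)
#' @return integer vector of 1-based match start positions (may be empty)
#' @export
find_ca_motif <- function(segment) {
  if (!nchar(segment)) return(integer(0))
  m <- gregexpr("(?=D.D..D)", segment, perl = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m)
}

# --- isoelectric point -----------------------------------------------------

# EMBOSS pKa values
PKA_POS <- c(Nterm = 8.6, K = 10.8, R = 12.5, H = 6.5)
PKA_NEG <- c(Cterm = 3.6, D = 3.9, E = 4.1, C = 8.5, Y = 10.1)

peptide_net_charge <- function(counts, pH) {
  pos <- sum(counts[names(PKA_POS)] / (1 + 10^(pH - PKA_POS)))
  neg <- sum(counts[names(PKA_NEG)] / (1 + 10^(PKA_NEG - pH)))
  pos - neg
}

#' Isoelectric point of a peptide
#'
#' Bisection on the Henderson-Hasselbalch net-charge function with the
#' EMBOSS pKa table; free N and C termini are included.
#'
#' @param peptide amino-acid string
#' @return pH at which the net charge is zero
#' @export
isoelectric_point <- function(peptide) {
  ch <- split_chars(toupper(peptide))
  counts <- c(Nterm = 1, Cterm = 1,
              vapply(c("K", "R", "H", "D", "E", "C", "Y"),
                     function(a) sum(ch == a), numeric(1)))
  lo <- 0; hi <- 14
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (peptide_net_charge(counts, mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Sliding-window isoelectric-point profile
#'
#' The pI of a window centered on each residue; windows are truncated at
#' the protein ends.
#'
#' @param protein amino-acid string
#' @param window odd window size >= 5 (default 21)
#' @return numeric vector of per-position pI values
#' @export
isoelectric_profile <- function(protein, window = 21L) {
  window <- as.integer(window)
  if (window %% 2L == 0L || window < 5L)
    stop("window must be odd and >= 5", call. = FALSE)
  L <- nchar(protein)
  half <- window %/% 2L
  vapply(seq_len(L), function(i) {
    isoelectric_point(substr(protein, max(1L, i - half), min(L, i + half)))
  }, numeric(1))
}
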