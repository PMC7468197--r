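# Synthetic crucivirus-like genome generator.
#
# Generates circular genomes with fully known ground truth: a planted
# nonanucleotide atop a hairpin of chosen stem/loop geometry, capsid- and
# Rep-like CDSs derived from a bundled synthetic reference protein library
# (so homology screening and classification are exercised realistically),
# chosen motif-II variant and helicase motifs, optional intron in rep, and
# optional use of the ciliate genetic code. Every planted element's
# coordinates are recorded in a truth record sufficient to score the
# recall and precision of every detector in the package.

# Residues used for random protein scaffolds. H, Y and W are excluded so
# that the endonuclease motif patterns (which all require H or Y) cannot
# arise in background sequence by chance; planted motifs are the only
# source of those residues.
SCAFFOLD_AA <- c("A", "C", "D", "E", "F", "G", "I", "K", "L", "M", "N",
                 "P", "Q", "R", "S", "T", "V")
# Residues used for point substitutions; additionally excludes D, K, C,
# M and F so that substitutions cannot complete a Walker/motif pattern.
MUTATION_AA <- c("A", "S", "T", "V", "L", "I", "N", "Q", "E", "R", "G", "P")

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  force(code)
}

random_protein <- function(n, alphabet = SCAFFOLD_AA) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Substitute residues at `rate`, never touching `protect` positions;
# replacements come from a restricted alphabet that cannot complete a
# conserved-motif pattern.
mutate_protein <- function(protein, rate, protect = integer(0),
                           alphabet = MUTATION_AA) {
  ch <- split_chars(protein)
  hit <- which(runif(length(ch)) < rate)
  hit <- setdiff(hit, protect)
  for (i in hit) {
    repl <- setdiff(alphabet, ch[i])
    ch[i] <- sample(repl, 1L)
  }
  paste(ch, collapse = "")
}

overwrite_at <- function(protein, pos, insert) {
  paste0(substr(protein, 1L, pos - 1L), insert,
         substr(protein, pos + nchar(insert), nchar(protein)))
}

# Breaks every match of `regex` in protein positions [from, to] by
# substituting the middle residue, skipping protected positions.
break_matches <- function(protein, regex, from, to, protect = integer(0),
                          repl = "P") {
  repeat {
    sub <- substr(protein, from, to)
    m <- regexpr(regex, sub, perl = TRUE)
    if (m[1] == -1L) break
    pos <- from + as.integer(m[1]) - 1L + attr(m, "match.length") %/% 2L
    while (pos %in% protect) pos <- pos + 1L
    protein <- overwrite_at(protein, pos, repl)
  }
  protein
}

# Fixed amino-acid offsets (1-based) of the planted Rep motifs.
REP_MOTIF_OFFSETS <- c(motif_I = 10L, motif_II = 38L, motif_III = 75L,
                       walker_A = 135L, walker_B = 165L, motif_C = 185L,
                       arg_finger = 195L)
REP_LEN <- 230L
SDOM_LEN <- 120L

#' Synthetic reference protein library
#'
#' A deterministic, synthetic stand-in for a curated library of crucivirus
#' capsid and Rep homologues: three capsid references (R-domain with basic
#' tract and Gly-rich stretch, shared S-domain core, P-domain tail) and
#' two Rep references carrying all seven conserved motifs at fixed
#' positions. The same library seeds the genome generator, so planted CDSs
#' are genuine (mutated) homologues of these references.
#'
#' @return list with `capsid` and `rep` (named character vectors),
#'   `s_core` (the shared S-domain core), `s_segments` (per-reference
#'   S-domain sequences) and `layout` (domain coordinates within the
#'   capsid references)
#' @export
synthetic_reference_proteins <- function() {
  with_seed(20200901L, {
    s_core <- random_protein(SDOM_LEN)
    # the S core must not contain a chance Ca-binding motif
    s_core <- break_matches(s_core, "D.D..D", 1L, SDOM_LEN, repl = "N")
    r_basic_len <- 25L; gly_len <- 14L; p_len <- 80L
    capsid <- character(); s_segments <- character()
    for (k in 1:3) {
      r_basic <- paste(sample(c("K", "R", "H", "S", "T", "A"), r_basic_len,
                              replace = TRUE, prob = c(3, 3, 1, 1, 1, 1)),
                       collapse = "")
      gly <- split_chars(random_protein(gly_len))
      gly[sample(gly_len, 12L)] <- "G"
      sdom <- mutate_protein(s_core, 0.10)
      p_tail <- random_protein(p_len)
      capsid[paste0("capsid_ref", k)] <-
        paste0("M", r_basic, paste(gly, collapse = ""), sdom, p_tail)
      s_segments[paste0("capsid_ref", k)] <- sdom
    }
    rep <- character()
    for (k in 1:2) {
      p <- random_protein(REP_LEN)
      p <- overwrite_at(p, REP_MOTIF_OFFSETS[["motif_I"]], "FTLNN")
      p <- overwrite_at(p, REP_MOTIF_OFFSETS[["motif_II"]], "HVH")
      p <- overwrite_at(p, REP_MOTIF_OFFSETS[["motif_III"]], "YLDK")
      p <- overwrite_at(p, REP_MOTIF_OFFSETS[["walker_A"]], "GPSGTGKT")
      p <- overwrite_at(p, REP_MOTIF_OFFSETS[["walker_B"]], "VLDD")
      p <- overwrite_at(p, REP_MOTIF_OFFSETS[["motif_C"]], "LITSN")
      p <- overwrite_at(p, REP_MOTIF_OFFSETS[["arg_finger"]], "R")
      p <- clean_spurious_rep_motifs(p)
      rep[paste0("rep_ref", k)] <- paste0("M", p)
    }
    layout <- list(r_domain = c(1L, 1L + r_basic_len + gly_len),
                   s_domain = c(2L + r_basic_len + gly_len,
                                1L + r_basic_len + gly_len + SDOM_LEN),
                   gly_tract = c(2L + r_basic_len,
                                 1L + r_basic_len + gly_len))
    list(capsid = capsid, rep = rep, s_core = s_core,
         s_segments = s_segments, layout = layout)
  })
}

# Removes chance motif-pattern matches from a Rep scaffold so that the
# planted instances are the first match inside their search regions.
clean_spurious_rep_motifs <- function(p) {
  L <- nchar(p)
  offs <- REP_MOTIF_OFFSETS
  protect <- unlist(lapply(seq_along(offs), function(i) {
    w <- c(5L, 3L, 4L, 8L, 4L, 5L, 1L)[i]
    seq.int(offs[i], offs[i] + w - 1L)
  }))
  defs <- default_rep_motif_patterns()
  # Walker/motif C patterns anywhere except the planted site
  for (mm in c("walker_A", "walker_B", "motif_C")) {
    rx <- defs$regex[defs$motif == mm]
    repeat {
      m <- gregexpr(rx, p, perl = TRUE)[[1]]
      if (m[1] == -1L) break
      spurious <- setdiff(as.integer(m), offs[[mm]])
      if (!length(spurious)) break
      pos <- spurious[1] + 1L
      while (pos %in% protect) pos <- pos + 1L
      p <- overwrite_at(p, pos, "P")
    }
  }
  p
}

#' Specification of one synthetic genome
#'
#' @param length genome length in bases
#' @param gc target GC percent (the generator compensates the background
#'   composition for the planted coding inserts so the realized genome GC
#'   tracks the target)
#' @param nonanucleotide the 9-mer planted in the hairpin loop
#' @param stem_len,loop_len hairpin geometry (stem >= 1 bp, loop >= 3 nt;
#'   when the loop is shorter than 9 the motif's 5' end extends into the
#'   ascending stem arm)
#' @param ori_strand strand of the planted stem-loop
#' @param orientation `"unisense"` (capsid and rep on the same strand) or
#'   `"ambisense"`
#' @param rep_present plant a rep CDS at all?
#' @param motif2_class motif II trigram class to plant: `"HUH"`, `"HUQ"`,
#'   `"HYQ"`, an explicit H-initial trigram, or `"absent"`
#' @param include_walker plant the four helicase motifs?
#' @param include_endo plant endonuclease motifs I and III?
#' @param include_intron split the rep frame with a GT..AG intron?
#' @param include_ca_motif plant a DxDxxD Ca-binding motif in the capsid
#'   S-domain?
#' @param genetic_code `"standard"` or `"ciliate"` (ciliate genomes encode
#'   some glutamines as TAA/TAG)
#' @param capsid_mut,rep_mut substitution rates applied to the reference
#'   proteins
#' @param capsid_ref,rep_ref which reference to derive the CDSs from
#' @param seed RNG seed for this genome
#' @return an object of class `SyntheticSpec`
#' @export
synthetic_spec <- function(length = 3000L, gc = 42.9,
                           nonanucleotide = "TAGTATTAC",
                           stem_len = 11L, loop_len = 11L, ori_strand = "+",
                           orientation = c("unisense", "ambisense"),
                           rep_present = TRUE,
                           motif2_class = "HUQ",
                           include_walker = TRUE, include_endo = TRUE,
                           include_intron = FALSE, include_ca_motif = FALSE,
                           genetic_code = c("standard", "ciliate"),
                           capsid_mut = 0.15, rep_mut = 0.15,
                           capsid_ref = 1L, rep_ref = 1L, seed = 1L) {
  orientation <- match.arg(orientation)
  genetic_code <- match.arg(genetic_code)
  if (nchar(nonanucleotide) != 9L)
    stop("nonanucleotide must be 9 bases", call. = FALSE)
  if (stem_len < 1L || loop_len < 3L)
    stop("stem_len must be >= 1 and loop_len >= 3", call. = FALSE)
  structure(
    list(length = as.integer(length), gc = gc,
         nonanucleotide = toupper(nonanucleotide),
         stem_len = as.integer(stem_len), loop_len = as.integer(loop_len),
         ori_strand = ori_strand, orientation = orientation,
         rep_present = isTRUE(rep_present), motif2_class = motif2_class,
         include_walker = isTRUE(include_walker),
         include_endo = isTRUE(include_endo),
         include_intron = isTRUE(include_intron),
         include_ca_motif = isTRUE(include_ca_motif),
         genetic_code = genetic_code,
         capsid_mut = capsid_mut, rep_mut = rep_mut,
         capsid_ref = as.integer(capsid_ref), rep_ref = as.integer(rep_ref),
         seed = as.integer(seed)),
    class = "SyntheticSpec")
}

# Reverse-translate a protein; synonymous codons are weighted toward the
# target GC. Under the ciliate code, glutamine is encoded as TAA/TAG with
# probability q_taa_frac.
reverse_translate <- function(protein, gc = 50,
                              code = c("standard", "ciliate"),
                              q_taa_frac = 0.5) {
  code <- match.arg(code)
  tab <- genetic_code_table(code)
  by_aa <- split(names(tab), tab)
  pb <- c(A = (100 - gc) / 200, C = gc / 200, G = gc / 200,
          T = (100 - gc) / 200)
  codon_w <- function(codons) {
    vapply(codons, function(cd) prod(pb[split_chars(cd)]), numeric(1))
  }
  ch <- split_chars(protein)
  codons <- vapply(ch, function(aa) {
    opts <- by_aa[[aa]]
    if (is.null(opts)) stop("cannot encode residue ", aa, call. = FALSE)
    if (code == "ciliate" && aa == "Q") {
      alt <- intersect(opts, c("TAA", "TAG"))
      std <- setdiff(opts, c("TAA", "TAG"))
      if (length(alt) && runif(1) < q_taa_frac) opts <- alt else opts <- std
    } else if (code == "standard") {
      # nothing: stop codons are never in by_aa for coding residues
    }
    w <- codon_w(opts)
    sample(opts, 1L, prob = w)
  }, character(1))
  paste(codons, collapse = "")
}

# Builds the hairpin insert and returns the motif offset within it.
build_hairpin <- function(spec) {
  s <- spec$stem_len; l <- spec$loop_len; m <- spec$nonanucleotide
  o <- max(0L, 9L - l)                    # motif overhang into the 5' arm
  if (o >= s) stop("stem too short for the motif overhang", call. = FALSE)
  left <- paste0(random_dna(s - o, spec$gc), substr(m, 1L, o))
  if (l <= 9L) {
    loop <- substr(m, o + 1L, 9L)
  } else {
    lead <- (l - 9L) %/% 2L
    loop <- paste0(random_dna(lead, spec$gc), m,
                   random_dna(l - 9L - lead, spec$gc))
  }
  right <- revcomp(left)
  motif_offset <- if (l <= 9L) s - o else s + (l - 9L) %/% 2L
  list(seq = paste0(left, loop, right), motif_offset = motif_offset)
}

motif2_trigram_for_class <- function(cls) {
  switch(cls,
         HUH = "HVH", HUQ = "HLQ", HYQ = "HYQ", absent = NA_character_,
         { if (nchar(cls) == 3L && substr(cls, 1, 1) == "H") toupper(cls)
           else stop("motif2_class must be HUH/HUQ/HYQ/absent or an ",
                     "H-initial trigram", call. = FALSE) })
}

# Construct the planted Rep protein for a spec, plus the truth positions
# of its motifs (1-based aa offsets; +1 for the leading Met of the refs).
build_rep_protein <- function(spec, refs) {
  ref <- refs$rep[[spec$rep_ref]]
  offs <- REP_MOTIF_OFFSETS + 1L          # leading M of the reference
  protect <- unlist(lapply(seq_along(offs), function(i) {
    w <- c(5L, 3L, 4L, 8L, 4L, 5L, 1L)[i]
    seq.int(offs[i], offs[i] + w - 1L)
  }))
  p <- mutate_protein(ref, spec$rep_mut, protect = c(1L, protect))
  truth <- as.list(offs)
  tri <- motif2_trigram_for_class(spec$motif2_class)
  if (is.na(tri)) {
    p <- overwrite_at(p, offs[["motif_II"]], "QTS")  # no H: motif II absent
    truth$motif_II <- NA_integer_
  } else {
    p <- overwrite_at(p, offs[["motif_II"]], tri)
  }
  if (!spec$include_endo) {
    p <- overwrite_at(p, offs[["motif_I"]], "ATLGS")
    p <- overwrite_at(p, offs[["motif_III"]], "SLDR")
    truth$motif_I <- NA_integer_; truth$motif_III <- NA_integer_
  }
  if (!spec$include_walker) {
    p <- overwrite_at(p, offs[["walker_A"]], "GPSGTGRT")   # K->R kills it
    p <- overwrite_at(p, offs[["walker_B"]], "VLND")
    p <- overwrite_at(p, offs[["motif_C"]], "LITQN")
    p <- break_matches(p, "G.{4}GK[TS]", 1L, nchar(p))
    p <- break_matches(p, "[AVLIMFWC]{2}D[DE]",
                       floor(nchar(p) * 0.4) + 1L, nchar(p), repl = "N")
    p <- break_matches(p, "[AVLIMFWC].TSN",
                       floor(nchar(p) * 0.4) + 1L, nchar(p), repl = "Q")
    truth$walker_A <- NA_integer_; truth$walker_B <- NA_integer_
    truth$motif_C <- NA_integer_; truth$arg_finger <- NA_integer_
  }
  list(protein = p, motif_positions = truth, trigram = tri)
}

build_capsid_protein <- function(spec, refs) {
  ref <- refs$capsid[[spec$capsid_ref]]
  lay <- refs$layout
  sdom <- c(lay$s_domain[1], lay$s_domain[2])
  p <- mutate_protein(ref, spec$capsid_mut, protect = 1L)
  ca_pos <- NA_integer_
  if (spec$include_ca_motif) {
    ca_pos <- sdom[1] + 40L
    p <- overwrite_at(p, ca_pos, "DTDGGD")
  }
  list(protein = p, s_domain = sdom, gly_tract = lay$gly_tract,
       ca_position = ca_pos)
}

#' Generate one synthetic crucivirus-like genome with ground truth
#'
#' Deterministic for a given spec (the spec carries its own seed). The
#' genome consists of i.i.d. background sequence at a compensated GC, a
#' planted hairpin with the nonanucleotide at its loop, and capsid/rep
#' CDSs derived from the synthetic reference library. Each CDS is
#' preceded by an in-frame stop codon so its maximal ORF starts exactly at
#' the planted ATG.
#'
#' @param spec a `SyntheticSpec`
#' @return list with `genome` (a `CircularGenome`) and `truth` (a list of
#'   planted-element coordinates and classes)
#' @export
generate_genome <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  with_seed(spec$seed, generate_genome_impl(spec))
}

generate_genome_impl <- function(spec) {
  refs <- synthetic_reference_proteins()
  code <- spec$genetic_code
  cap <- build_capsid_protein(spec, refs)
  cap_dna <- paste0(
    reverse_translate(cap$protein, spec$gc, code), "TGA")
  rep_info <- NULL; rep_dna <- NULL
  if (spec$rep_present) {
    rep_info <- build_rep_protein(spec, refs)
    rep_dna <- paste0(reverse_translate(rep_info$protein, spec$gc, code),
                      "TGA")
  }
  intron <- NULL; intron_at <- NA_integer_
  if (spec$rep_present && spec$include_intron) {
    # GT..AG intron; the G-free interior cannot create competing
    # donor/acceptor sites, and the in-frame TGA right after the donor
    # stops read-through translation under both genetic codes
    ilen <- 90L
    interior <- paste(sample(c("A", "C", "T"), ilen - 8L, replace = TRUE),
                      collapse = "")
    intron <- paste0("GTATGA", interior, "AG")
    intron_at <- 3L * 115L                 # codon boundary between domains
    rep_dna <- paste0(substr(rep_dna, 1L, intron_at), intron,
                      substr(rep_dna, intron_at + 1L, nchar(rep_dna)))
  }
  hp <- build_hairpin(spec)
  # the pad is a stop codon in both the standard and the ciliate code, so
  # the maximal ORF starts at the planted ATG under either code
  cap_block <- paste0("TGA", cap_dna)
  rep_block <- if (is.null(rep_dna)) "" else {
    if (spec$orientation == "unisense") paste0("TGA", rep_dna)
    else revcomp(paste0("TGA", rep_dna))
  }
  hp_block <- if (spec$ori_strand == "+") hp$seq else revcomp(hp$seq)
  ins_len <- nchar(cap_block) + nchar(rep_block) + nchar(hp_block)
  bg_total <- spec$length - ins_len
  if (bg_total < 120L)
    stop("genome length too small for the planted elements (need >= ",
         ins_len + 120L, " bases)", call. = FALSE)
  # compensate background GC for the composition of the inserts
  ins_gc_n <- sum(vapply(c(cap_block, rep_block, hp_block), function(x)
    sum(split_chars(x) %in% c("G", "C")), numeric(1)))
  bg_gc <- (spec$gc / 100 * spec$length - ins_gc_n) / bg_total * 100
  bg_gc <- min(95, max(5, bg_gc))
  cuts <- sort(sample.int(bg_total - 4L * 30L + 1L, 3L) - 1L)
  bg_len <- diff(c(0L, cuts, bg_total - 4L * 30L)) + 30L
  bg <- vapply(bg_len, random_dna, character(1), gc = bg_gc)

  seqs <- c(bg[1], cap_block, bg[2], rep_block, bg[3], hp_block, bg[4])
  genome_seq <- paste(seqs, collapse = "")
  offs <- cumsum(c(0L, nchar(seqs)))      # start offset of each part
  cap_start <- offs[2] + 3L
  cap_end <- offs[2] + nchar(cap_block)
  rep_truth <- NULL
  if (spec$rep_present) {
    lenR <- nchar(rep_dna)
    if (spec$orientation == "unisense") {
      rep_start <- offs[4] + 3L
      rep_end <- offs[4] + 3L + lenR
      rep_strand <- "+"
      exons <- if (spec$include_intron)
        list(c(rep_start, rep_start + intron_at),
             c(rep_start + intron_at + nchar(intron), rep_end))
      else list(c(rep_start, rep_end))
    } else {
      rep_start <- offs[4]
      rep_end <- offs[4] + lenR
      rep_strand <- "-"
      exons <- if (spec$include_intron)
        list(c(rep_end - intron_at, rep_end),
             c(rep_start, rep_end - intron_at - nchar(intron)))
      else list(c(rep_start, rep_end))
    }
    rep_truth <- list(start = rep_start, end = rep_end, strand = rep_strand,
                      exons = exons, intron_len = if (is.null(intron)) 0L
                      else nchar(intron),
                      protein = rep_info$protein,
                      motif_positions = rep_info$motif_positions,
                      motif2_trigram = rep_info$trigram,
                      motif2_class = spec$motif2_class,
                      ref = names(refs$rep)[spec$rep_ref])
  }
  hp_off <- offs[6]
  hp_len <- nchar(hp_block)
  ori_pos <- if (spec$ori_strand == "+") hp_off + hp$motif_offset
             else hp_off + hp_len - hp$motif_offset - 1L
  genome <- circular_genome(sprintf("synth_seed%d", spec$seed), genome_seq,
                            source = "assembled_contig")
  truth <- list(
    id = genome$id, spec = spec, length = spec$length,
    ori = list(position = ori_pos, strand = spec$ori_strand,
               stem_len = spec$stem_len, loop_len = spec$loop_len,
               hairpin_start = hp_off, hairpin_end = hp_off + hp_len,
               nonanucleotide = spec$nonanucleotide),
    capsid = list(start = cap_start, end = cap_end, strand = "+",
                  protein = cap$protein, s_domain = cap$s_domain,
                  gly_tract = cap$gly_tract, ca_position = cap$ca_position,
                  ref = names(refs$capsid)[spec$capsid_ref]),
    rep = rep_truth,
    orientation = if (spec$rep_present) spec$orientation else "not_applicable",
    genetic_code = spec$genetic_code)
  list(genome = genome, truth = truth)
}

#' Default sampler of synthetic genome specs
#'
#' Draws one `SyntheticSpec` from distributions emulating the reported
#' properties of the crucivirus data set: lengths uniform on 2,474-7,947
#' bases, GC normal around 42.9% (sd 4.9), hairpin stems of 5-14 bp and
#' loops of 7-15 nt, a menu of CRESS-type nonanucleotides dominated by
#' TAGTATTAC, 2% of genomes without a rep CDS, an ambisense:unisense ratio
#' of 58:40, motif-II classes at HUQ 70% / HYQ 12% / HUH 4.8% / other
#' 13.2%, helicase motifs absent in ~3% of reps, an intron in ~8%, a
#' Ca-binding motif in ~15% of capsids, and the ciliate code in ~1%.
#'
#' @param seed seed recorded in the spec (the caller seeds the RNG)
#' @return a `SyntheticSpec`
#' @export
sample_synthetic_spec <- function(seed = 1L) {
  nona <- sample(c("TAGTATTAC", "TAATATTAC", "CAGTATTAC", "TAATATTAT",
                   "TAGTATTAG"), 1L, prob = c(0.45, 0.2, 0.1, 0.15, 0.1))
  rep_present <- runif(1) < 0.98
  orientation <- if (runif(1) < 0.58 / 0.98) "ambisense" else "unisense"
  m2 <- sample(c("HUQ", "HYQ", "HUH", "HSQ"), 1L,
               prob = c(0.700, 0.120, 0.048, 0.132))
  synthetic_spec(
    length = sample(2474:7947, 1L),
    gc = min(65, max(25, rnorm(1, 42.9, 4.9))),
    nonanucleotide = nona,
    stem_len = sample(5:14, 1L), loop_len = sample(7:15, 1L),
    ori_strand = sample(c("+", "-"), 1L),
    orientation = orientation, rep_present = rep_present,
    motif2_class = m2,
    include_walker = runif(1) < 0.97,
    include_intron = runif(1) < 0.078,
    include_ca_motif = runif(1) < 0.148,
    genetic_code = if (runif(1) < 0.011) "ciliate" else "standard",
    capsid_ref = sample(3L, 1L), rep_ref = sample(2L, 1L),
    seed = seed)
}

#' Generate a dataset of synthetic genomes with a truth table
#'
#' Each genome gets its own RNG stream seeded from `(seed, index)`, so
#' datasets are reproducible regardless of generation order.
#'
#' @param n number of genomes
#' @param spec_sampler function `(seed) -> SyntheticSpec`
#' @param seed master seed
#' @return list with `collection` (a `SequenceCollection`), `truths`
#'   (list of per-genome truth records) and `truth_table` (data frame)
#' @export
generate_dataset <- function(n, spec_sampler = sample_synthetic_spec,
                             seed = 1L) {
  stopifnot(n >= 1L)
  genomes <- vector("list", n)
  truths <- vector("list", n)
  for (i in seq_len(n)) {
    gseed <- (as.integer(seed) + 7919L * i) %% 2147483587L + 1L
    spec <- with_seed(gseed, spec_sampler(seed = gseed))
    res <- generate_genome(spec)
    res$genome$id <- sprintf("synth%03d_%d", i, gseed)
    res$truth$id <- res$genome$id
    genomes[[i]] <- res$genome
    truths[[i]] <- res$truth
  }
  list(collection = sequence_collection(genomes, "fasta"),
       truths = truths,
       truth_table = truth_table(truths))
}

#' Flatten truth records into a data frame
#' @param truths list of truth records from [generate_genome()]
#' @return data frame, one row per genome
#' @export
truth_table <- function(truths) {
  do.call(rbind, lapply(truths, function(t) {
    data.frame(
      id = t$id, length = t$length,
      ori_position = t$ori$position, ori_strand = t$ori$strand,
      stem_len = t$ori$stem_len, loop_len = t$ori$loop_len,
      nonanucleotide = t$ori$nonanucleotide,
      capsid_start = t$capsid$start, capsid_end = t$capsid$end,
      capsid_strand = t$capsid$strand,
      rep_present = !is.null(t$rep),
      rep_start = if (is.null(t$rep)) NA_integer_ else t$rep$start,
      rep_end = if (is.null(t$rep)) NA_integer_ else t$rep$end,
      rep_strand = if (is.null(t$rep)) NA_character_ else t$rep$strand,
      spliced = if (is.null(t$rep)) FALSE else t$rep$intron_len > 0L,
      motif2_class = if (is.null(t$rep)) NA_character_ else t$rep$motif2_class,
      orientation = t$orientation,
      genetic_code = t$genetic_code,
      stringsAsFactors = FALSE)
  }))
}

#' Linearize a circular genome with terminal redundancy
#'
#' Emulates assembler output: the genome rotated to `start` with its first
#' `k` bases appended at the end. The inverse of
#' [detect_terminal_redundancy()].
#'
#' @param genome `CircularGenome`
#' @param start 0-based rotation origin
#' @param k redundancy length, `10 <= k < length/2`
#' @return contig string of length `length + k`
#' @export
linearize_with_redundancy <- function(genome, start = 0L, k = 50L) {
  n <- genome$length
  start <- as.integer(start); k <- as.integer(k)
  if (start < 0L || start >= n) stop("start out of range", call. = FALSE)
  if (k < 10L || k >= n / 2) stop("k must be in [10, length/2)", call. = FALSE)
  rot <- rotate_string(genome$seq, start)
  paste0(rot, substr(rot, 1L, k))
}
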