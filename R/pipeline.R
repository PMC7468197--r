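# End-to-end discovery pipeline: circularize -> capsid screen -> gene
# annotation (standard code, with ciliate-code and splice rescue for
# failures) -> stem-loop detection -> motif profiling -> CruV/CruCGE call
# -> sequential naming -> summary report.

#' Default pipeline configuration
#'
#' All detector parameters in one serializable list. `start_index = 81`
#' continues the historical crucivirus numbering; names are assigned in
#' ascending genome length (ties broken lexicographically by input id).
#'
#' @param ... named overrides of individual fields
#' @return a `PipelineConfig` list
#' @export
default_pipeline_config <- function(...) {
  cfg <- list(
    patterns = default_nonanucleotide_patterns(),
    flank = 20L, max_score = 15L, min_stem = 5L, min_loop = 7L,
    proximity = 4L, backend = "nussinov_dna",
    min_orf = 300L, bit_threshold = 50,
    class_min_pident = 25, class_min_cov = 0.5,
    rep_hint_bits = 40, splice_max_intron = 300L,
    motif_defs = default_rep_motif_patterns(),
    min_overlap = 10L, require_redundancy = FALSE,
    start_index = 81L,
    compute_pi = FALSE,
    genbank_date = "01-JAN-2020",
    seed = 1L)
  ov <- list(...)
  cfg[names(ov)] <- ov
  class(cfg) <- "PipelineConfig"
  cfg
}

# Best six-frame peptide hit of a genome against a reference set, with
# the genomic region of the peptide. Used to locate rep loci that did not
# yield a clean ORF.
six_frame_hit_region <- function(genome, refs, min_aa = 30L) {
  n <- genome$length
  sub <- load_sub_matrix("BLOSUM62")
  best <- NULL
  for (strand in c("+", "-")) {
    S <- if (strand == "+") genome$seq else revcomp(genome$seq)
    ext <- paste0(S, S)
    for (f in 0:2) {
      len <- ((2L * n - f) %/% 3L) * 3L
      prot <- translate_dna(substr(ext, f + 1L, f + len), "standard")
      stops <- c(0L, which(split_chars(prot) == "*"), nchar(prot) + 1L)
      for (si in seq_len(length(stops) - 1L)) {
        a <- stops[si] + 1L; b <- stops[si + 1L] - 1L
        if (b - a + 1L < min_aa) next
        ostart <- f + 3L * (a - 1L)            # oriented nt offset, 0-based
        if (ostart >= n) next                   # duplicate of a wrapped copy
        pep <- substr(prot, a, b)
        sc <- max(Biostrings::pairwiseAlignment(
          Biostrings::AAStringSet(as.character(refs)),
          Biostrings::AAString(pep),
          type = "local", substitutionMatrix = sub, gapOpening = 11,
          gapExtension = 1, scoreOnly = TRUE))
        bits <- bit_score(sc)
        if (is.null(best) || bits > best$bits) {
          olen <- 3L * (b - a + 1L)
          if (strand == "+") {
            st <- ostart %% n; en <- (ostart + olen) %% n
          } else {
            st <- (n - ostart - olen) %% n; en <- (n - ostart) %% n
          }
          if (en == 0L) en <- n
          best <- list(bits = bits, start = st, end = en, strand = strand)
        }
      }
    }
  }
  best
}

classify_orf <- function(orf, refs_capsid, refs_rep, min_pident, min_cov) {
  prot <- orf$protein
  if (is.na(prot) || nchar(prot) < 30L) return(orf)
  best <- NULL; best_class <- "unknown"
  for (set in list(list(refs = refs_capsid, class = "capsid"),
                   list(refs = refs_rep, class = "rep"))) {
    for (ri in seq_along(set$refs)) {
      hit <- smith_waterman(prot, set$refs[[ri]], query_id = orf$id,
                            ref_id = names(set$refs)[ri])
      if (is.null(best) || hit$bits > best$bits) {
        best <- hit
        best_class <- set$class
      }
    }
  }
  ref_len <- nchar(c(refs_capsid, refs_rep)[[best$ref_id]])
  if (best$pident >= min_pident && best$aln_len >= min_cov * ref_len) {
    orf$product_class <- best_class
    orf$best_hit <- list(ref_id = best$ref_id, bit_score = best$bits,
                         pident = best$pident)
  }
  orf
}

segments_overlap <- function(g1, g2, n) {
  cov <- function(g) {
    unlist(lapply(g$segments, function(s) {
      len <- segment_length(s, n)
      (s$start + seq_len(len) - 1L) %% n
    }))
  }
  length(intersect(cov(g1), cov(g2))) > 0L
}

#' Annotate a single circular genome
#'
#' Runs ORF calling (standard code first; ciliate code and splice rescue
#' when the standard code yields no complete capsid or rep), homology
#' classification against the reference library, stem-loop detection and
#' motif profiling, and calls CruV versus CruCGE.
#'
#' @param genome `CircularGenome`
#' @param refs list with `capsid` and `rep` named protein vectors and
#'   `s_segments` (reference S-domains for the capsid partition profile)
#' @param config `PipelineConfig`
#' @return the genome with `features` filled and an `analysis` element
#'   (classification, orientation, motif profile, capsid domains, type)
#' @export
annotate_genome <- function(genome, refs, config = default_pipeline_config()) {
  n <- genome$length
  orfs <- find_orfs(genome, min_len = config$min_orf, code = "standard")
  orfs <- lapply(orfs, classify_orf, refs_capsid = refs$capsid,
                 refs_rep = refs$rep, min_pident = config$class_min_pident,
                 min_cov = config$class_min_cov)
  have <- function(cls) any(vapply(orfs, function(o)
    o$product_class == cls, logical(1)))
  # a class call is complete when its protein covers most of its
  # reference; a CDS truncated at an in-frame stop is only a fragment
  complete <- function(cls) {
    any(vapply(orfs, function(o) {
      if (o$product_class != cls || is.na(o$protein)) return(FALSE)
      ref_len <- if (!is.null(o$best_hit))
        nchar(c(refs$capsid, refs$rep)[[o$best_hit$ref_id]])
      else nchar(o$protein)
      nchar(o$protein) >= 0.8 * ref_len
    }, logical(1)))
  }
  used_ciliate <- FALSE
  if (!complete("capsid") || !complete("rep")) {
    # ciliate-code rescue, only because the standard code left a class
    # missing or fragmentary
    orfs6 <- find_orfs(genome, min_len = config$min_orf, code = "ciliate")
    orfs6 <- lapply(orfs6, classify_orf, refs_capsid = refs$capsid,
                    refs_rep = refs$rep,
                    min_pident = config$class_min_pident,
                    min_cov = config$class_min_cov)
    for (o in orfs6) {
      if (o$product_class %in% c("capsid", "rep") &&
          !complete(o$product_class)) {
        orfs[[length(orfs) + 1L]] <- o
        used_ciliate <- TRUE
      }
    }
  }
  rep_homology <- have("rep")
  # splice rescue: no rep ORF at all, or only fragments of one (in-frame
  # stops, or endonuclease and helicase domains in different frames). A
  # full-length rep that merely lacks a motif (e.g. the helicase-less
  # class) is left alone.
  if (!complete("rep")) {
    hint <- six_frame_hit_region(genome, refs$rep)
    if (!is.null(hint) && hint$bits >= config$rep_hint_bits) {
      rep_homology <- TRUE
      margin <- 900L
      reg <- list(start = (hint$start - margin) %% n,
                  end = (hint$end + margin) %% n, strand = hint$strand)
      cand <- detect_splice_candidates(
        genome, list(reg), max_intron = config$splice_max_intron,
        min_orf_aa = ceiling(0.8 * min(nchar(refs$rep))))
      cand <- Filter(function(g) g$product_class == "rep" && g$spliced, cand)
      if (length(cand)) {
        # drop the partial single-domain call in favor of the spliced one
        orfs <- Filter(function(o) o$product_class != "rep", orfs)
        orfs[[length(orfs) + 1L]] <- cand[[1L]]
      }
    }
  }
  # putative ORFs: long ORFs without homology and without overlap with
  # classified capsid/rep genes
  assigned <- Filter(function(o) o$product_class %in% c("capsid", "rep"), orfs)
  orfs <- lapply(orfs, function(o) {
    if (o$product_class == "unknown") {
      overlaps <- any(vapply(assigned, segments_overlap, logical(1),
                             g2 = o, n = n))
      if (!overlaps && gene_length(o, n) >= 300L)
        o$product_class <- "putative_orf"
    }
    o
  })
  stemloops <- find_stemloops(genome, patterns = config$patterns,
                              flank = config$flank,
                              max_score = config$max_score,
                              min_stem = config$min_stem,
                              min_loop = config$min_loop,
                              proximity = config$proximity,
                              backend = config$backend)
  capsids <- Filter(function(o) o$product_class == "capsid", orfs)
  reps <- Filter(function(o) o$product_class == "rep", orfs)
  pick_longest <- function(xs) {
    if (!length(xs)) return(NULL)
    xs[[order(-vapply(xs, gene_length, numeric(1), n = n))[1L]]]
  }
  capsid <- pick_longest(capsids); rep <- pick_longest(reps)
  profile <- NULL
  if (!is.null(rep) && !is.na(rep$protein) && nchar(rep$protein) >= 50L)
    profile <- find_rep_motifs(rep$protein, motif_defs = config$motif_defs)
  domains <- NULL
  if (!is.null(capsid) && !is.na(capsid$protein) &&
      nchar(capsid$protein) >= 60L) {
    s_profile <- build_sdomain_profile(refs$s_segments)
    domains <- partition_capsid(capsid$protein, s_profile)
  }
  type <- call_cruv_or_crucge(profile, has_rep_homology = rep_homology)
  genome$features <- c(orfs, stemloops)
  genome$analysis <- list(
    capsid = capsid, rep = rep, orientation = classify_orientation(capsid, rep),
    rep_profile = profile, capsid_domains = domains, type = type,
    used_ciliate = used_ciliate,
    n_stemloops_accepted = sum(vapply(stemloops, function(a) a$accepted,
                                      logical(1))))
  genome
}

#' Run the full discovery pipeline
#'
#' Stages, in order: circular resolution of terminally redundant contigs,
#' capsid homology screen, gene annotation with rescue paths, stem-loop
#' detection, motif profiling, CruV/CruCGE call, sequential naming
#' beginning with the smallest genome, and summary. Fully deterministic
#' for a given input and configuration.
#'
#' @param contigs `SequenceCollection` (raw contigs or finished circular
#'   records)
#' @param refs reference library (see [annotate_genome()]; default: the
#'   bundled synthetic reference proteins)
#' @param config `PipelineConfig`
#' @param out_dir optional directory to write the per-genome table, GFF3,
#'   GenBank, summary JSON and manifest into
#' @return list with `genomes` (annotated), `table` (per-genome data
#'   frame), `report` (summary list), `manifest`
#' @export
run_discovery <- function(contigs, refs = synthetic_reference_proteins(),
                          config = default_pipeline_config(),
                          out_dir = NULL) {
  stopifnot(inherits(contigs, "SequenceCollection"))
  if (!length(refs$capsid)) stop("need at least one capsid reference",
                                 call. = FALSE)
  log_stage <- function(stage, n_in, n_out)
    message(sprintf("[%s] in=%d out=%d", stage, n_in, n_out))

  # 1. circularize
  genomes <- list()
  for (rec in contigs$records) {
    if (rec$source == "finished_record" || rec$redundancy_trimmed > 0L) {
      genomes[[length(genomes) + 1L]] <- rec
      next
    }
    res <- suppressWarnings(
      detect_terminal_redundancy(rec, min_overlap = config$min_overlap))
    if (!is.null(res$genome)) genomes[[length(genomes) + 1L]] <- res$genome
    else if (!config$require_redundancy)
      genomes[[length(genomes) + 1L]] <- rec
  }
  log_stage("circularize", length(contigs$records), length(genomes))

  # 2. capsid screen
  screen <- screen_capsid_candidates(genomes, refs$capsid,
                                     bit_threshold = config$bit_threshold)
  genomes <- Filter(function(g) g$id %in% screen$id, genomes)
  log_stage("capsid_screen", nrow(screen) + 0L, length(genomes))
  if (!length(genomes)) {
    return(list(genomes = list(),
                table = data.frame(), report = NULL,
                manifest = list(config = unclass(config), n_named = 0L)))
  }

  # 3-6. annotate
  genomes <- lapply(genomes, annotate_genome, refs = refs, config = config)
  log_stage("annotate", length(genomes), length(genomes))

  # 7. naming: ascending length, ties lexicographic by input id
  ord <- order(vapply(genomes, function(g) g$length, integer(1)),
               vapply(genomes, function(g) g$id, character(1)))
  genomes <- genomes[ord]
  idx <- config$start_index
  for (i in seq_along(genomes)) {
    prefix <- if (genomes[[i]]$analysis$type == "CruV") "CruV" else "CruCGE"
    genomes[[i]]$analysis$name <- sprintf("%s-%d", prefix, idx)
    idx <- idx + 1L
  }

  table <- per_genome_table(genomes)
  report <- summarize_genomes(genomes, compute_pi = config$compute_pi)
  manifest <- list(config = unclass(config),
                   n_input = length(contigs$records),
                   n_retained = length(genomes),
                   names = table$name)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(table, file.path(out_dir, "genomes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_gff3(genomes, file.path(out_dir, "annotations.gff3"))
    write_genbank(genomes, file.path(out_dir, "genomes.gbk"),
                  date = config$genbank_date)
    jsonlite::write_json(report, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(genomes = genomes, table = table, report = report, manifest = manifest)
}

per_genome_table <- function(genomes) {
  do.call(rbind, lapply(genomes, function(g) {
    a <- g$analysis
    acc <- Filter(function(f) inherits(f, "StemLoopAnnotation") && f$accepted,
                  g$features)
    best_sl <- if (length(acc))
      acc[[order(vapply(acc, function(x) x$score, integer(1)))[1L]]] else NULL
    data.frame(
      name = a$name %||% NA_character_, input_id = g$id,
      type = a$type, length = g$length, gc = round(gc_content(g), 2),
      n_orfs = sum(vapply(g$features, inherits, logical(1), "GeneAnnotation")),
      has_capsid = !is.null(a$capsid), has_rep = !is.null(a$rep),
      rep_spliced = !is.null(a$rep) && isTRUE(a$rep$spliced),
      orientation = a$orientation,
      n_stemloops = a$n_stemloops_accepted,
      nonanucleotide = if (is.null(best_sl)) NA_character_
                       else best_sl$motif$matched_seq,
      stemloop_score = if (is.null(best_sl)) NA_integer_ else best_sl$score,
      motif2_class = if (is.null(a$rep_profile)) NA_character_
                     else a$rep_profile$motif2_class,
      ciliate_code = a$used_ciliate,
      stringsAsFactors = FALSE)
  }))
}

#' Summary report over annotated genomes
#'
#' Recomputes every reported group-level quantity from the annotations:
#' genome composition, rep-coding and CruCGE counts, orientation
#' fractions, stem-loop and nonanucleotide tallies, motif-II class
#' counts, and (optionally) pairwise-identity statistics per protein
#' class.
#'
#' @param genomes list of annotated `CircularGenome` (from
#'   [annotate_genome()] / [run_discovery()])
#' @param compute_pi also compute capsid/rep pairwise-identity matrices
#'   (quadratic in the number of genomes)
#' @return a list with the summary fields
#' @export
summarize_genomes <- function(genomes, compute_pi = FALSE) {
  stopifnot(length(genomes) >= 1L)
  gc <- vapply(genomes, gc_content, numeric(1))
  len <- vapply(genomes, function(g) g$length, integer(1))
  a <- lapply(genomes, function(g) g$analysis)
  has_rep <- vapply(a, function(x) !is.null(x$rep), logical(1))
  type <- vapply(a, function(x) x$type, character(1))
  orient <- vapply(a, function(x) x$orientation, character(1))
  sl_acc <- lapply(genomes, function(g)
    Filter(function(f) inherits(f, "StemLoopAnnotation") && f$accepted,
           g$features))
  n_sl_genomes <- sum(vapply(sl_acc, length, integer(1)) > 0L)
  all_acc <- unlist(sl_acc, recursive = FALSE)
  pat_counts <- table(vapply(all_acc, function(x) x$motif$pattern,
                             character(1)))
  nona_counts <- table(vapply(all_acc, function(x) x$motif$matched_seq,
                              character(1)))
  m2 <- vapply(a, function(x)
    if (is.null(x$rep_profile)) NA_character_ else x$rep_profile$motif2_class,
    character(1))
  report <- list(
    n_genomes = length(genomes),
    gc_mean = mean(gc), gc_sd = stats::sd(gc),
    length_min = min(len), length_max = max(len),
    n_with_rep = sum(has_rep),
    n_crucge = sum(type == "CruCGE"),
    orientation_fractions = as.list(prop.table(table(
      factor(orient, levels = c("unisense", "ambisense", "not_applicable"))))),
    n_stemloop_annotated = n_sl_genomes,
    nonanucleotide_pattern_counts = as.list(pat_counts),
    nonanucleotide_counts = as.list(nona_counts),
    motif2_counts = as.list(table(m2[!is.na(m2)])))
  if (compute_pi) {
    caps <- vapply(a, function(x)
      if (is.null(x$capsid)) NA_character_ else x$capsid$protein, character(1))
    reps <- vapply(a, function(x)
      if (is.null(x$rep)) NA_character_ else x$rep$protein, character(1))
    ids <- vapply(genomes, function(g) g$id, character(1))
    pi_stats <- function(seqs) {
      seqs <- seqs[!is.na(seqs) & nchar(seqs) > 0]
      if (length(seqs) < 2L) return(NULL)
      matrix_stats(pairwise_identity_matrix(seqs))
    }
    names(caps) <- ids; names(reps) <- ids
    report$pi_capsid <- pi_stats(caps)
    report$pi_rep <- pi_stats(reps)
  }
  report
}
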