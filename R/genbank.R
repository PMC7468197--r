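# Minimal GenBank flat-file support: LOCUS (with topology), FEATURES with
# CDS/stem_loop entries (location strings with complement() and join(),
# including joins across the origin of circular records), /product,
# /transl_table and /note qualifiers, and the ORIGIN sequence block.

#' Default product-class keyword mapping
#'
#' Maps substrings of a `/product` qualifier (case-insensitive) to product
#' classes. First match wins, in the listed order.
#' @return named character vector: names are regular expressions, values
#'   are product classes
#' @export
default_product_map <- function() {
  c("capsid|coat protein" = "capsid",
    "replication[- ]associated|replication protein|\\brep\\b" = "rep",
    "putative orf|hypothetical" = "putative_orf")
}

# Parses one GenBank location string into (segments, strand) with 0-based
# half-open coordinates; origin-spanning joins are merged into single wrap
# segments. Returns NULL when the location grammar is not understood.
parse_gb_location <- function(loc, n) {
  loc <- gsub("[<>]", "", gsub("\\s", "", loc))
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) loc <- sub("^join\\((.*)\\)$", "\\1", loc)
  if (grepl("complement|join|order", loc)) return(NULL)  # nested forms unsupported
  parts <- strsplit(loc, ",", fixed = TRUE)[[1]]
  segs <- lapply(parts, function(p) {
    m <- regmatches(p, regexec("^(\\d+)\\.\\.(\\d+)$", p))[[1]]
    if (length(m) == 0L) {
      m1 <- regmatches(p, regexec("^(\\d+)$", p))[[1]]
      if (length(m1) == 0L) return(NULL)
      a <- as.integer(m1[2]); b <- a
    } else {
      a <- as.integer(m[2]); b <- as.integer(m[3])
    }
    if (a < 1L || b < a || b > n) return("out_of_range")
    list(start = a - 1L, end = b)  # 0-based half-open
  })
  if (any(vapply(segs, is.null, logical(1)))) return(NULL)
  if (any(vapply(segs, identical, logical(1), "out_of_range")))
    stop("feature location out of range: ", loc, call. = FALSE)
  # merge origin-spanning pairs: ...x..n followed by 1..y
  merged <- list()
  i <- 1L
  while (i <= length(segs)) {
    s <- segs[[i]]
    if (i < length(segs) && s$end == n && segs[[i + 1L]]$start == 0L) {
      s <- list(start = s$start, end = segs[[i + 1L]]$end)
      i <- i + 2L
    } else i <- i + 1L
    merged[[length(merged) + 1L]] <- s
  }
  if (strand == "-") merged <- rev(merged)  # transcription order
  list(segments = merged, strand = strand)
}

#' Read genomes and CDS annotations from a GenBank flat file
#'
#' Parses each record's sequence, topology and feature table. `CDS` and
#' `stem_loop` features are mapped into the package's annotation records;
#' joins across the origin of circular records become single wrap-around
#' segments. A `/transl_table` of 6 marks the feature as using the ciliate
#' genetic code. `/product` strings are mapped to a product class through
#' `product_map`.
#'
#' @param path GenBank flat file
#' @param product_map named vector of regex -> class (see
#'   [default_product_map()])
#' @return a `SequenceCollection` with `format_origin = "genbank"`
#' @export
read_genbank_features <- function(path, product_map = default_product_map()) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("empty GenBank file: ", path, call. = FALSE)
  ends <- which(trimws(lines) == "//")
  starts <- c(1L, head(ends, -1L) + 1L)
  records <- list()
  for (r in seq_along(ends)) {
    chunk <- lines[starts[r]:ends[r]]
    rec <- parse_gb_record(chunk, product_map)
    if (!is.null(rec)) records[[length(records) + 1L]] <- rec
  }
  if (!length(records)) stop("no records parsed from ", path, call. = FALSE)
  sequence_collection(records, "genbank")
}

parse_gb_record <- function(chunk, product_map) {
  locus_line <- grep("^LOCUS", chunk, value = TRUE)
  if (!length(locus_line)) return(NULL)
  toks <- strsplit(trimws(locus_line[1]), "\\s+")[[1]]
  id <- toks[2]
  # sequence
  oi <- grep("^ORIGIN", chunk)
  seq <- ""
  if (length(oi)) {
    seq_lines <- chunk[(oi[1] + 1L):length(chunk)]
    seq_lines <- seq_lines[!grepl("^//", seq_lines)]
    seq <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  }
  if (!nchar(seq)) return(NULL)
  n <- nchar(seq)
  genome <- circular_genome(id, seq, source = "finished_record")

  fi <- grep("^FEATURES", chunk)
  feats <- list()
  if (length(fi)) {
    fend <- if (length(oi)) oi[1] - 1L else length(chunk)
    flines <- chunk[(fi[1] + 1L):fend]
    feats <- parse_gb_features(flines, id, n, product_map)
  }
  genome$features <- feats
  genome
}

parse_gb_features <- function(flines, genome_id, n, product_map) {
  # group lines into features: a new feature starts with a key at col 6
  key_idx <- grep("^ {5}\\S", flines)
  feats <- list()
  counter <- 0L
  for (i in seq_along(key_idx)) {
    from <- key_idx[i]
    to <- if (i < length(key_idx)) key_idx[i + 1L] - 1L else length(flines)
    block <- flines[from:to]
    key <- sub("^\\s*(\\S+).*$", "\\1", block[1])
    if (!key %in% c("CDS", "stem_loop")) next
    # location may continue over lines until the first qualifier line
    qual_start <- grep("^\\s+/", block)
    loc_end <- if (length(qual_start)) qual_start[1] - 1L else length(block)
    loc <- paste(c(sub("^\\s*\\S+\\s*", "", block[1]),
                   trimws(block[seq_len(loc_end)][-1])), collapse = "")
    quals <- parse_gb_qualifiers(block[seq_along(block) > loc_end])
    parsed <- tryCatch(parse_gb_location(loc, n), error = function(e) stop(e))
    if (is.null(parsed)) {
      warning("skipping feature with unparseable location in ", genome_id,
              ": ", loc)
      next
    }
    counter <- counter + 1L
    if (key == "CDS") {
      code <- if (identical(quals[["transl_table"]], "6")) "ciliate" else "standard"
      cls <- "unknown"
      prod <- quals[["product"]]
      if (!is.null(prod)) {
        for (pat in names(product_map)) {
          if (grepl(pat, prod, ignore.case = TRUE)) {
            cls <- unname(product_map[[pat]]); break
          }
        }
      }
      feats[[length(feats) + 1L]] <- gene_annotation(
        id = quals[["locus_tag"]] %||% sprintf("%s_cds%d", genome_id, counter),
        genome_id = genome_id, segments = parsed$segments,
        strand = parsed$strand, genetic_code = code,
        spliced = length(parsed$segments) > 1L, product_class = cls,
        protein = quals[["translation"]] %||% NA_character_)
    } else {
      s <- parsed$segments[[1]]
      note <- quals[["note"]] %||% ""
      sc <- suppressWarnings(as.integer(quals[["score"]] %||% "0"))
      if (is.na(sc)) sc <- 0L
      feats[[length(feats) + 1L]] <- stemloop_annotation(
        motif = list(pattern = NA_character_, position = s$start,
                     strand = parsed$strand, matched_seq = note),
        hairpin = list(stem_len = NA_integer_, loop_len = NA_integer_,
                       start = s$start, end = s$end, pairs = NULL,
                       backend = "genbank"),
        score = sc,
        accepted = TRUE)
    }
  }
  feats
}

parse_gb_qualifiers <- function(lines) {
  if (!length(lines)) return(list())
  txt <- trimws(lines)
  starts <- grep("^/", txt)
  quals <- list()
  for (i in seq_along(starts)) {
    from <- starts[i]
    to <- if (i < length(starts)) starts[i + 1L] - 1L else length(txt)
    q <- paste(txt[from:to], collapse = " ")
    m <- regmatches(q, regexec("^/([A-Za-z_]+)(=(.*))?$", q))[[1]]
    if (length(m) == 0L) next
    val <- m[4]
    val <- gsub("^\"|\"$", "", val)
    quals[[m[2]]] <- if (identical(m[3], "")) TRUE else val
  }
  quals
}

# --- writing ---------------------------------------------------------------

format_gb_location <- function(segments, strand, n) {
  segs <- segments
  if (strand == "-") segs <- rev(segs)  # genomic order for serialization
  parts <- unlist(lapply(segs, function(s) {
    if (s$end > s$start && s$end <= n) {
      sprintf("%d..%d", s$start + 1L, s$end)
    } else {  # wraps the origin: split in two
      c(sprintf("%d..%d", s$start + 1L, n), sprintf("1..%d", s$end))
    }
  }))
  loc <- if (length(parts) > 1L)
    sprintf("join(%s)", paste(parts, collapse = ",")) else parts
  if (strand == "-") loc <- sprintf("complement(%s)", loc)
  loc
}

#' Write genomes with annotations to a GenBank flat file
#'
#' Records are written with LOCUS topology `circular`; wrap-around
#' features are serialized as `join()` across the origin.
#'
#' @param x `SequenceCollection` or list of `CircularGenome`
#' @param path output file
#' @param date LOCUS date string; a fixed value keeps outputs
#'   byte-reproducible
#' @return `path`, invisibly
#' @export
write_genbank <- function(x, path, date = "01-JAN-2020") {
  recs <- if (inherits(x, "SequenceCollection")) x$records else x
  con <- file(path, "w")
  on.exit(close(con))
  for (g in recs) write_gb_record(g, con, date)
  invisible(path)
}

write_gb_record <- function(g, con, date = "01-JAN-2020") {
  n <- g$length
  writeLines(sprintf("LOCUS       %-16s %d bp    DNA     circular VRL %s",
                     g$id, n, date), con)
  writeLines(sprintf("DEFINITION  %s.", g$id), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", n), con)
  for (f in g$features) {
    if (inherits(f, "GeneAnnotation")) {
      writeLines(sprintf("     CDS             %s",
                         format_gb_location(f$segments, f$strand, n)), con)
      writeLines(sprintf("                     /locus_tag=\"%s\"", f$id), con)
      prod <- switch(f$product_class,
                     capsid = "capsid protein",
                     rep = "replication-associated protein",
                     putative_orf = "putative ORF",
                     "hypothetical protein")
      writeLines(sprintf("                     /product=\"%s\"", prod), con)
      if (f$genetic_code == "ciliate")
        writeLines("                     /transl_table=6", con)
    } else if (inherits(f, "StemLoopAnnotation")) {
      h <- f$hairpin
      seg <- list(list(start = h$start, end = h$end))
      writeLines(sprintf("     stem_loop       %s",
                         format_gb_location(seg, f$motif$strand, n)), con)
      writeLines(sprintf("                     /note=\"%s\"",
                         f$motif$matched_seq), con)
      writeLines(sprintf("                     /score=%d", f$score), con)
    }
  }
  writeLines("ORIGIN", con)
  s <- tolower(g$seq)
  pos <- seq(1L, n, by = 60L)
  for (p in pos) {
    line <- substr(s, p, min(p + 59L, n))
    blocks <- substring(line, seq(1, nchar(line), 10), pmin(seq(10, nchar(line) + 9, 10), nchar(line)))
    writeLines(sprintf("%9d %s", p, paste(blocks, collapse = " ")), con)
  }
  writeLines("//", con)
}
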