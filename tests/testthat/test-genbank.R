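make_annotated_genome <- function() {
  set.seed(42)
  g <- circular_genome("gbk1", rand_dna(600))
  g$features <- list(
    gene_annotation("cap1", "gbk1", list(list(start = 30, end = 330)),
                    strand = "+", product_class = "capsid"),
    gene_annotation("rep1", "gbk1",
                    list(list(start = 350, end = 420),
                         list(start = 470, end = 560)),
                    strand = "+", spliced = TRUE, product_class = "rep",
                    genetic_code = "ciliate"),
    gene_annotation("orfm", "gbk1", list(list(start = 560, end = 40)),
                    strand = "-", product_class = "putative_orf"),
    stemloop_annotation(
      motif = list(pattern = "NANTANTAN", position = 450, strand = "+",
                   matched_seq = "TAGTATTAC"),
      hairpin = list(stem_len = 11L, loop_len = 11L, apex_dist = 0,
                     start = 440L, end = 473L, pairs = NULL,
                     backend = "nussinov_dna"),
      score = 0L, accepted = TRUE))
  g
}

test_that("GenBank write/read round-trips coordinates, strands and joins", {
  g <- make_annotated_genome()
  f <- withr::local_tempfile(fileext = ".gbk")
  write_genbank(list(g), f)
  back <- read_genbank_features(f)
  b <- back$records[[1]]
  expect_equal(b$seq, g$seq)
  genes_in <- Filter(function(x) inherits(x, "GeneAnnotation"), g$features)
  genes_out <- Filter(function(x) inherits(x, "GeneAnnotation"), b$features)
  expect_length(genes_out, length(genes_in))
  for (i in seq_along(genes_in)) {
    expect_equal(lapply(genes_out[[i]]$segments, unlist),
                 lapply(genes_in[[i]]$segments, unlist))
    expect_equal(genes_out[[i]]$strand, genes_in[[i]]$strand)
    expect_equal(genes_out[[i]]$spliced, genes_in[[i]]$spliced)
    expect_equal(genes_out[[i]]$genetic_code, genes_in[[i]]$genetic_code)
    expect_equal(genes_out[[i]]$product_class, genes_in[[i]]$product_class)
  }
  sl <- Filter(function(x) inherits(x, "StemLoopAnnotation"), b$features)
  expect_length(sl, 1L)
  expect_equal(sl[[1]]$hairpin$start, 440L)
  expect_equal(sl[[1]]$score, 0L)
})

test_that("GenBank parser handles strands, joins and transl_table", {
  gb <- c(
    "LOCUS       rec1             120 bp    DNA     circular VRL 01-JAN-2020",
    "FEATURES             Location/Qualifiers",
    "     source          1..120",
    "     CDS             complement(10..60)",
    "                     /product=\"replication-associated protein\"",
    "     CDS             join(5..40,61..90)",
    "                     /product=\"capsid protein\"",
    "                     /transl_table=6",
    "ORIGIN",
    paste0("        1 ", paste(rep("acgtacgtac", 6), collapse = " ")),
    paste0("       61 ", paste(rep("acgtacgtac", 6), collapse = " ")),
    "//")
  f <- withr::local_tempfile(fileext = ".gbk")
  writeLines(gb, f)
  col <- read_genbank_features(f)
  feats <- col$records[[1]]$features
  expect_length(feats, 2L)
  expect_equal(feats[[1]]$strand, "-")
  expect_equal(feats[[1]]$product_class, "rep")
  expect_true(feats[[2]]$spliced)
  expect_length(feats[[2]]$segments, 2L)
  expect_equal(feats[[2]]$genetic_code, "ciliate")
  expect_equal(feats[[2]]$product_class, "capsid")
})

test_that("GenBank parser rejects out-of-range and skips bad locations", {
  gb <- c(
    "LOCUS       rec2             40 bp    DNA     circular VRL 01-JAN-2020",
    "FEATURES             Location/Qualifiers",
    "     CDS             10..90",
    "ORIGIN",
    "        1 acgtacgtac acgtacgtac acgtacgtac acgtacgtac",
    "//")
  f <- withr::local_tempfile(fileext = ".gbk")
  writeLines(gb, f)
  expect_error(read_genbank_features(f), "out of range")

  gb2 <- sub("10\\.\\.90", "order(1..5,<<bad>>)", gb)
  f2 <- withr::local_tempfile(fileext = ".gbk")
  writeLines(gb2, f2)
  expect_warning(col <- read_genbank_features(f2), "unparseable")
  expect_length(col$records[[1]]$features, 0L)
})
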