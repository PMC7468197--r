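test_that("FASTA reading uppercases, maps U to T, and validates ids", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "acgt", ">b", "ACGU"), f)
  col <- read_fasta(f)
  expect_length(col, 2L)
  expect_equal(col$records$a$seq, "ACGT")
  expect_equal(col$records$b$seq, "ACGT")

  f2 <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGT", ">a", "TTTT"), f2)
  expect_error(read_fasta(f2), "a")

  f3 <- withr::local_tempfile(fileext = ".fasta")
  file.create(f3)
  expect_error(read_fasta(f3), "empty")
})

test_that("FASTA write/read round-trips sequences", {
  g <- circular_genome("x", strrep("ACGTT", 30))
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(list(g), f)
  back <- read_fasta(f)
  expect_equal(back$records$x$seq, g$seq)
})

test_that("terminal redundancy detection matches a brute-force oracle", {
  set.seed(101)
  for (rep in 1:25) {
    n <- sample(200:1500, 1)
    S <- rand_dna(n)
    k <- sample(10:(n %/% 2 - 1), 1)
    contig <- paste0(S, substr(S, 1, k))
    res <- detect_terminal_redundancy(contig)
    oracle <- bf_longest_prefix_suffix(contig, 10L)
    expect_equal(res$overlap_len, oracle)
    expect_equal(res$genome$length, nchar(contig) - oracle)
    # the resolved circle matches S up to rotation
    expect_true(grepl(res$genome$seq, paste0(S, S), fixed = TRUE))
  }
})

test_that("contigs without redundancy and short contigs yield none", {
  expect_equal(detect_terminal_redundancy("ACGTACGTTTACGTACG",
                                          min_overlap = 10)$overlap_len, 0L)
  set.seed(7)
  s <- rand_dna(400)
  res <- detect_terminal_redundancy(s)
  expect_equal(res$overlap_len, bf_longest_prefix_suffix(s, 10L))
  expect_warning(r <- detect_terminal_redundancy(rand_dna(15)), "shorter")
  expect_null(r$genome)
  expect_error(detect_terminal_redundancy("ACGT", min_overlap = 5), ">= 10")
})

test_that("gc_content handles N and degenerate inputs", {
  expect_equal(gc_content("ATGC"), 50)
  expect_equal(gc_content("GGGG"), 100)
  expect_equal(gc_content("ATNNAT"), 0)
  expect_error(gc_content("NNNN"), "undefined")
})

test_that("gc_content is rotation- and reverse-complement-invariant", {
  set.seed(5)
  for (i in 1:10) {
    s <- rand_dna(100)
    g <- circular_genome("g", s)
    expect_equal(gc_content(rotate_genome(g, sample(99, 1))), gc_content(g))
    expect_equal(gc_content(as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(s)))),
      gc_content(s))
  }
})

test_that("canonical rotation is the least rotation and is idempotent", {
  g <- circular_genome("g", "CGA")
  expect_equal(canonical_rotation(g)$seq, "ACG")
  # oracle: enumerate all rotations, take the minimum
  s <- "TTAGGA"
  rots <- vapply(0:5, function(k)
    canonical_rotation(circular_genome("r", rotate_string(s, k)))$seq,
    character(1))
  expect_equal(unique(rots), min(vapply(0:5, rotate_string, character(1),
                                        x = s)))
  set.seed(11)
  for (i in 1:10) {
    g <- circular_genome("g", rand_dna(60))
    c1 <- canonical_rotation(g)
    expect_identical(canonical_rotation(c1)$seq, c1$seq)
  }
})

test_that("rotation shifts feature coordinates consistently", {
  g <- circular_genome("g", strrep("ACGT", 50))
  g$features <- list(gene_annotation("f1", "g",
                                     list(list(start = 10, end = 40))))
  r <- rotate_genome(g, 25)
  s <- r$features[[1]]$segments[[1]]
  # the feature sequence is preserved under rotation
  expect_equal(circ_substr(r$seq, s$start, 30), circ_substr(g$seq, 10, 30))
})
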