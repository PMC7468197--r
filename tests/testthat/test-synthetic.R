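test_that("genome generation is deterministic for a given spec", {
  spec <- synthetic_spec(length = 3000, stem_len = 11, loop_len = 11,
                         nonanucleotide = "TAGTATTAC", seed = 1)
  r1 <- generate_genome(spec)
  r2 <- generate_genome(spec)
  expect_identical(r1$genome$seq, r2$genome$seq)
  expect_identical(r1$truth, r2$truth)
})

test_that("realized GC tracks the requested target", {
  devs <- vapply(1:50, function(i) {
    r <- generate_genome(synthetic_spec(length = 3000, gc = 60, seed = 4000 + i))
    gc_content(r$genome) - 60
  }, numeric(1))
  expect_lt(max(abs(devs)), 2)
})

test_that("planted elements honor the spec", {
  r <- generate_genome(synthetic_spec(length = 3200, motif2_class = "HUQ",
                                      seed = 5))
  tr <- r$truth
  # nonanucleotide sits at the recorded position on the recorded strand
  seen <- circ_substr(r$genome$seq, tr$ori$position, 9)
  expect_equal(seen, tr$ori$nonanucleotide)
  # motif II trigram of the planted Rep
  p2 <- tr$rep$motif_positions$motif_II
  expect_equal(substr(tr$rep$protein, p2, p2 + 2), "HLQ")
  expect_equal(classify_motif2(substr(tr$rep$protein, p2, p2 + 2)), "HUQ")
  # planted trigram "HUQ" class for an explicit trigram spec
  r2 <- generate_genome(synthetic_spec(length = 3200, motif2_class = "HCQ",
                                       seed = 6))
  p2b <- r2$truth$rep$motif_positions$motif_II
  expect_equal(substr(r2$truth$rep$protein, p2b, p2b), "H")
  # minus-strand ori: motif read on the minus strand matches
  r3 <- generate_genome(synthetic_spec(length = 3000, ori_strand = "-",
                                       seed = 7))
  region <- circ_substr(r3$genome$seq,
                        (r3$truth$ori$position - 8) %% r3$genome$length, 9)
  expect_equal(as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(region))), r3$truth$ori$nonanucleotide)
})

test_that("planted CDSs contain no spurious in-frame stops", {
  for (seed in 11:14) {
    r <- generate_genome(synthetic_spec(length = 3500, seed = seed))
    expect_false(grepl("[*]", r$truth$capsid$protein))
    expect_false(grepl("[*]", r$truth$rep$protein))
  }
})

test_that("datasets are reproducible with distinct per-genome streams", {
  d1 <- generate_dataset(5, seed = 9)
  d2 <- generate_dataset(5, seed = 9)
  expect_identical(vapply(d1$collection$records, function(g) g$seq,
                          character(1)),
                   vapply(d2$collection$records, function(g) g$seq,
                          character(1)))
  expect_length(unique(names(d1$collection$records)), 5L)
  d3 <- generate_dataset(5, seed = 10)
  expect_false(identical(d1$collection$records[[1]]$seq,
                         d3$collection$records[[1]]$seq))
  # a constrained sampler propagates to every truth row
  amb <- generate_dataset(4, seed = 2, spec_sampler = function(seed)
    synthetic_spec(length = 3000, orientation = "ambisense", seed = seed))
  expect_true(all(amb$truth_table$orientation == "ambisense"))
})

test_that("linearize/redetect round-trips the circular genome", {
  r <- generate_genome(synthetic_spec(length = 2800, seed = 20))
  g <- r$genome
  set.seed(33)
  for (i in 1:8) {
    s <- sample(0:(g$length - 1), 1)
    k <- sample(10:(g$length %/% 2 - 1), 1)
    contig <- linearize_with_redundancy(g, s, k)
    expect_equal(nchar(contig), g$length + k)
    res <- detect_terminal_redundancy(contig)
    expect_equal(res$genome$length, g$length)
    # recovered up to rotation
    expect_true(grepl(res$genome$seq, paste0(g$seq, g$seq), fixed = TRUE))
  }
  expect_error(linearize_with_redundancy(g, 0, 5), "k must be")
  expect_error(linearize_with_redundancy(g, g$length, 50), "start")
  # minimal redundancy is detected exactly when nothing longer matches
  contig <- linearize_with_redundancy(g, 0, 10)
  expect_equal(detect_terminal_redundancy(contig)$overlap_len,
               bf_longest_prefix_suffix(contig, 10L))
})

test_that("overlong planted content is rejected", {
  expect_error(generate_genome(synthetic_spec(length = 1400, seed = 1)),
               "too small")
})
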