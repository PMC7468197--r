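test_that("IUPAC matching follows positionwise degeneracy semantics", {
  expect_true(iupac_matches("TAGTATTAC", "NANTANTAN"))
  expect_true(iupac_matches("TAGTATTAC", "NAKWRTTAC"))
  expect_false(iupac_matches("TAGTATTAC", "TAWWDHWAN"))  # G fails W
  expect_true(iupac_matches("TAATATTAT", "TAWWDHWAN"))
  expect_error(iupac_matches("TAGTATTAC", "NANTAXTAN"), "non-IUPAC")
})

test_that("nonanucleotide scan finds hits on both strands and across the origin", {
  bg <- strrep("C", 60)
  g <- circular_genome("s", paste0(bg, "TAGTATTAC", bg))
  hits <- scan_nonanucleotides(g, "NANTANTAN")
  expect_true(any(vapply(hits, function(h)
    h$position == 60 && h$strand == "+", logical(1))))

  # minus strand: plant the reverse complement
  g2 <- circular_genome("s2", paste0(bg, revcomp("TAGTATTAC"), bg))
  hits2 <- scan_nonanucleotides(g2, "NANTANTAN")
  m <- Filter(function(h) h$strand == "-", hits2)
  expect_length(m, 1L)
  expect_equal(m[[1]]$matched_seq, "TAGTATTAC")
  # 5' end of the motif on the minus strand is the rightmost base
  expect_equal(m[[1]]$position, 60 + 8)

  # motif split across the sequence end: last 4 + first 5 bases
  g3 <- circular_genome("s3", paste0("TTAC", strrep("C", 50), "TAGTA"))
  hits3 <- scan_nonanucleotides(g3, "NANTANTAN")
  expect_true(any(vapply(hits3, function(h)
    h$position == 54 && h$strand == "+", logical(1))))
})

test_that("maximum-pairing fold matches forced examples", {
  p <- nussinov_fold("GGGGGAAAAAAACCCCC")
  expect_equal(nrow(p), 5L)
  expect_equal(nrow(nussinov_fold(strrep("A", 20))), 0L)
  # a perfect 11-bp inverted repeat around an 11-base loop
  stem <- "GCATGCCGGAT"
  win <- paste0(stem, strrep("A", 11), revcomp(stem))
  p2 <- nussinov_fold(win)
  expect_true(valid_nested_pairing(win, p2))
  expect_equal(nrow(p2), bf_max_pairs(win))
})

test_that("deviation scoring is the stated absolute-deviation formula", {
  expect_equal(score_stemloop(11, 11), 0L)
  expect_equal(score_stemloop(5, 7), 10L)
  expect_equal(score_stemloop(20, 20), 18L)
  expect_equal(score_stemloop(0, 11), 11L)
  expect_equal(score_stemloop(11, 0), 11L)
})

test_that("a planted ideal hairpin is annotated with score 0", {
  fx <- polyA_hairpin_genome(loop_pad = 1L)
  anns <- find_stemloops(fx$genome)
  # a hairpin is double-stranded: the minus-strand reading of the same
  # structure may carry its own accepted annotation; the planted register
  # must be the unique plus-strand one
  acc <- Filter(function(a) a$accepted && a$motif$strand == "+", anns)
  expect_length(acc, 1L)
  a <- acc[[1]]
  expect_equal(a$motif$position, fx$motif_pos)
  expect_equal(a$motif$strand, "+")
  expect_equal(a$hairpin$stem_len, 11L)
  expect_equal(a$hairpin$loop_len, 11L)
  expect_equal(a$score, 0L)
  expect_equal(a$hairpin$start, fx$hairpin_start)
})

test_that("hairpins failing the geometry filter are rejected", {
  fx <- polyA_hairpin_genome(stem = "GCGC", loop_pad = 1L)  # 4 bp stem
  anns <- find_stemloops(fx$genome)
  cand <- Filter(function(a) a$motif$position == fx$motif_pos, anns)
  expect_true(length(cand) >= 1L)
  expect_false(any(vapply(cand, function(a) a$accepted, logical(1))))
  expect_true(all(vapply(cand, function(a)
    a$rejection_reason == "geometry", logical(1))))
})

test_that("same-first-base duplicates keep only the best candidate", {
  fx <- polyA_hairpin_genome(loop_pad = 1L)
  # TAGTATTAC matches two of the default patterns; both hits share the
  # hairpin, so exactly one annotation survives the de-duplication
  anns <- find_stemloops(fx$genome,
                         patterns = c("NANTANTAN", "NAKWRTTAC"))
  at_pos <- Filter(function(a) a$motif$position == fx$motif_pos, anns)
  expect_length(at_pos, 2L)
  expect_equal(sum(vapply(at_pos, function(a) a$accepted, logical(1))), 1L)
  dup <- Filter(function(a) !a$accepted, at_pos)
  expect_equal(dup[[1]]$rejection_reason, "duplicate_first_base")
})

test_that("scores above the threshold are rejected with the right reason", {
  # stem 5, loop 21 -> score 16 > 15
  fx <- polyA_hairpin_genome(stem = "GCGCG", loop_pad = 6L)
  anns <- find_stemloops(fx$genome)
  cand <- Filter(function(a) a$motif$position == fx$motif_pos, anns)
  expect_true(all(vapply(cand, function(a)
    a$rejection_reason == "score_gt_threshold", logical(1))))
  # the same geometry passes with a raised threshold
  anns2 <- find_stemloops(fx$genome, max_score = 20)
  cand2 <- Filter(function(a) a$motif$position == fx$motif_pos && a$accepted,
                  anns2)
  expect_length(cand2, 1L)
  expect_equal(cand2[[1]]$score, 16L)
})

test_that("motifs too close to the hairpin ends are excluded", {
  # loop 9 with no padding and a 5-bp stem: the motif start sits 5 bases
  # from the hairpin end; with proximity 6 it must be excluded
  fx <- polyA_hairpin_genome(stem = "GCGCG", loop_pad = 0L)
  anns <- find_stemloops(fx$genome, proximity = 6L)
  cand <- Filter(function(a) a$motif$position == fx$motif_pos, anns)
  expect_true(all(vapply(cand, function(a)
    a$rejection_reason == "motif_too_close_to_stem_end", logical(1))))
})

test_that("stem-loop sets are invariant under genome rotation", {
  r <- generate_genome(synthetic_spec(length = 2800, seed = 51))
  g <- r$genome
  base <- find_stemloops(g)
  key <- function(anns, shift, n) sort(vapply(
    Filter(function(a) a$accepted, anns),
    function(a) sprintf("%d%s%d", (a$motif$position + shift) %% n,
                        a$motif$strand, a$score), character(1)))
  for (k in c(137L, 1123L)) {
    rot <- rotate_genome(g, k)
    expect_equal(key(find_stemloops(rot), k, g$length), key(base, 0L, g$length))
  }
})

test_that("nonanucleotide frequency matrices are column-stochastic", {
  mk <- function(seq9) stemloop_annotation(
    motif = list(pattern = "NANTANTAN", position = 0, strand = "+",
                 matched_seq = seq9),
    hairpin = list(stem_len = 11L, loop_len = 11L, apex_dist = 0,
                   start = 0L, end = 33L, pairs = NULL, backend = "x"),
    score = 0L, accepted = TRUE)
  m <- nonanucleotide_frequencies(rep(list(mk("TAGTATTAC")), 64))
  expect_equal(unname(m["T", 1]), 1)
  m2 <- nonanucleotide_frequencies(c(rep(list(mk("TAGTATTAC")), 5),
                                     rep(list(mk("AAGTATTAC")), 5)))
  expect_equal(unname(m2["T", 1]), 0.5)
  expect_equal(unname(m2["A", 1]), 0.5)
  expect_equal(unname(colSums(m2)), rep(1, 9))
  expect_error(nonanucleotide_frequencies(list()), "no accepted")
})
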