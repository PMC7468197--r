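test_that("translation follows the standard and ciliate codes", {
  expect_equal(translate_dna("ATGTAA", "standard"), "M*")
  expect_equal(translate_dna("ATGTAA", "ciliate"), "MQ")
  expect_equal(translate_dna("ATGTAG", "ciliate"), "MQ")
  expect_equal(translate_dna("ATGTGA", "ciliate"), "M*")
  expect_equal(translate_dna("ATGNNN", "standard"), "MX")
  expect_error(translate_dna("ATGT"), "divisible")
})

test_that("ORF calling recovers planted CDS coordinates exactly", {
  for (seed in c(61, 62)) {
    r <- generate_genome(synthetic_spec(length = 3400, seed = seed,
                                        orientation = "ambisense"))
    orfs <- find_orfs(r$genome, 300)
    tr <- r$truth
    cap <- Filter(function(o)
      o$strand == tr$capsid$strand &&
        o$segments[[1]]$start == tr$capsid$start &&
        o$segments[[1]]$end == tr$capsid$end, orfs)
    expect_length(cap, 1L)
    expect_identical(cap[[1]]$protein, tr$capsid$protein)
    rep <- Filter(function(o)
      o$strand == tr$rep$strand &&
        o$segments[[1]]$start == tr$rep$start &&
        o$segments[[1]]$end == tr$rep$end, orfs)
    expect_length(rep, 1L)
    expect_identical(rep[[1]]$protein, tr$rep$protein)
  }
})

test_that("ORFs spanning the circular origin are found with wrap segments", {
  r <- generate_genome(synthetic_spec(length = 3000, seed = 63))
  tr <- r$truth
  # rotate so the capsid CDS crosses the origin
  mid <- tr$capsid$start + 300L
  rot <- rotate_genome(r$genome, mid)
  orfs <- find_orfs(rot, 300)
  hit <- Filter(function(o) identical(o$protein, tr$capsid$protein), orfs)
  expect_length(hit, 1L)
  s <- hit[[1]]$segments[[1]]
  expect_true(s$end <= s$start)  # wraps
  expect_equal(gene_dna(hit[[1]], rot),
               circ_substr(r$genome$seq, tr$capsid$start,
                           tr$capsid$end - tr$capsid$start))
})

test_that("ORF sets are rotation-invariant modulo coordinate shift", {
  r <- generate_genome(synthetic_spec(length = 2800, seed = 64))
  g <- r$genome
  base <- find_orfs(g, 300)
  rot <- find_orfs(rotate_genome(g, 911L), 300)
  key <- function(os) sort(vapply(os, function(o)
    paste0(o$strand, o$protein), character(1)))
  expect_equal(key(rot), key(base))
})

test_that("genomes without ATG yield no ORFs", {
  g <- circular_genome("noatg", strrep("ACC", 200))
  expect_length(find_orfs(g, 30), 0L)
})

test_that("orientation classification is by strand equality", {
  cap <- gene_annotation("c", "g", list(list(0, 300)), strand = "+")
  repp <- gene_annotation("r", "g", list(list(400, 700)), strand = "+")
  repm <- gene_annotation("r", "g", list(list(400, 700)), strand = "-")
  capm <- gene_annotation("c", "g", list(list(0, 300)), strand = "-")
  expect_equal(classify_orientation(cap, repp), "unisense")
  expect_equal(classify_orientation(cap, repm), "ambisense")
  expect_equal(classify_orientation(capm, repm), "unisense")
  expect_equal(classify_orientation(cap, NULL), "not_applicable")
})

test_that("splice rescue recovers planted introns exactly", {
  for (orient in c("unisense", "ambisense")) {
    r <- generate_genome(synthetic_spec(length = 3600, include_intron = TRUE,
                                        orientation = orient, seed = 71))
    tr <- r$truth; g <- r$genome
    reg <- list(start = (tr$rep$start - 60) %% g$length,
                end = (tr$rep$end + 60) %% g$length,
                strand = tr$rep$strand)
    cand <- detect_splice_candidates(g, list(reg))
    expect_length(cand, 1L)
    a <- cand[[1]]
    expect_true(a$spliced)
    expect_equal(a$product_class, "rep")
    expect_identical(a$protein, tr$rep$protein)
    got <- lapply(a$segments, function(s) c(s$start, s$end))
    expect_equal(got, tr$rep$exons)
  }
})

test_that("clean single-frame regions are returned unspliced", {
  r <- generate_genome(synthetic_spec(length = 3200, seed = 72))
  tr <- r$truth
  reg <- list(start = (tr$rep$start - 30) %% r$genome$length,
              end = (tr$rep$end + 30) %% r$genome$length,
              strand = tr$rep$strand)
  cand <- detect_splice_candidates(r$genome, list(reg))
  expect_false(cand[[1]]$spliced)
  expect_identical(cand[[1]]$protein, tr$rep$protein)
})

test_that("the minimal of two valid introns is chosen", {
  # region built from G-free codons so donor/acceptor sites are planted:
  # exon1 (with an HVH motif), a 90-nt intron, a 150-nt optional
  # extension ending in AG (second acceptor), exon2 (Walker A), stop.
  aa_n <- function(k) strrep("AAT", k)                 # Asn filler, G-free
  exon1 <- paste0("ATG", aa_n(20), "CATGTACAT", aa_n(10))   # M..HVH..
  intron <- paste0("GT", strrep("CTT", 28), "CAAG")         # 90 nt, no inner AG
  ext <- paste0(aa_n(49), "AAG")                            # 150 nt, ends AG
  exon2 <- paste0(aa_n(5), "GGAAATAATAATAATGGAAAAACT", aa_n(10), "TGA")
  dna <- paste0(aa_n(4), exon1, intron, ext, exon2, aa_n(4))
  sol <- find_spliced_orf(dna, min_intron = 60, max_intron = 400,
                          required_motifs = c("H.[HQ]", "G.{4}GK[TS]"))
  expect_false(is.null(sol))
  expect_equal(sol$intron_len, 90L)
  expect_true(grepl("HVH", sol$protein))
  expect_true(grepl("G.{4}GK[TS]", sol$protein))
})
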