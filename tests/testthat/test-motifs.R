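test_that("all seven Rep motifs are found at their planted positions", {
  refs <- synthetic_reference_proteins()
  for (k in 1:2) {
    prof <- find_rep_motifs(refs$rep[[k]])
    offs <- REP_MOTIF_OFFSETS + 1L  # leading Met
    for (m in names(offs)) {
      expect_true(prof$motifs[[m]]$present, info = m)
      if (m != "arg_finger")
        expect_equal(prof$motifs[[m]]$position, unname(offs[[m]]), info = m)
    }
    expect_equal(prof$motif2_class, "HUH")
    expect_false(prof$helicase_motifs_all_absent)
    expect_false(prof$grs_present)
  }
})

test_that("motif absence is data, not an error", {
  prof <- find_rep_motifs(strrep("A", 120))
  expect_true(all(!vapply(prof$motifs, function(m) m$present, logical(1))))
  expect_true(prof$helicase_motifs_all_absent)
  expect_equal(prof$motif2_class, "absent")
  expect_error(find_rep_motifs("SHORT"), "shorter")
})

test_that("motif detection is position-independent", {
  core <- "LDFGPSRTGKTLW"  # carries a Walker A instantiation
  set.seed(91)
  seen <- vapply(c(0, 15, 40), function(off) {
    p <- paste0(strrep("S", 130 + off), core, strrep("S", 60))
    prof <- find_rep_motifs(p)
    prof$motifs$walker_A$seq
  }, character(1))
  expect_equal(unique(seen), "GPSRTGKT")
})

test_that("motif II trigrams classify into the documented classes", {
  expect_equal(classify_motif2("HLQ"), "HUQ")
  expect_equal(classify_motif2("HYQ"), "HYQ")
  expect_equal(classify_motif2("HVH"), "HUH")
  expect_equal(classify_motif2("HSQ"), "other_alt")
  expect_equal(classify_motif2("QVH"), "absent")
  expect_equal(classify_motif2(NA), "absent")
  # total on H-initial trigrams
  for (a2 in AAS) for (a3 in AAS) {
    cls <- classify_motif2(paste0("H", a2, a3))
    expect_true(cls %in% c("HUH", "HUQ", "HYQ", "other_alt"))
  }
})

test_that("CruV/CruCGE calls follow the motif evidence", {
  refs <- synthetic_reference_proteins()
  full <- find_rep_motifs(refs$rep[[1]])
  expect_equal(call_cruv_or_crucge(full, TRUE), "CruV")
  none <- find_rep_motifs(strrep("A", 120))
  expect_equal(call_cruv_or_crucge(none, TRUE), "CruCGE")
  expect_equal(call_cruv_or_crucge(NULL, FALSE), "CruCGE")
})

test_that("capsid partition recovers planted domain boundaries", {
  refs <- synthetic_reference_proteins()
  prof <- build_sdomain_profile(refs$s_segments)
  for (seed in 101:104) {
    r <- generate_genome(synthetic_spec(length = 3000, seed = seed,
                                        include_ca_motif = TRUE))
    tr <- r$truth$capsid
    d <- partition_capsid(tr$protein, prof)
    expect_lte(abs(d$s_domain[1] - tr$s_domain[1]), 5)
    expect_lte(abs(d$s_domain[2] - tr$s_domain[2]), 5)
    # tiling invariant
    r_len <- max(0, d$r_domain[2] - d$r_domain[1] + 1)
    s_len <- max(0, d$s_domain[2] - d$s_domain[1] + 1)
    p_len <- max(0, d$p_domain[2] - d$p_domain[1] + 1)
    expect_equal(r_len + s_len + p_len, nchar(tr$protein))
    # the maximal >=50%-G window overlaps the planted tract (it may
    # legitimately extend into G-poor neighbors while staying above 50%)
    expect_false(is.null(d$gly_tract))
    expect_lte(d$gly_tract[1], tr$gly_tract[2])
    expect_gte(d$gly_tract[2], tr$gly_tract[1])
    expect_gte(d$gly_tract[2] - d$gly_tract[1] + 1, 8)
    expect_gt(d$basic_fraction_r, 0.3)
    # planted Ca motif found inside the S-domain
    expect_true(tr$ca_position %in% d$ca_motif_positions)
  }
  expect_error(partition_capsid(strrep("A", 40), prof), "shorter")
})

test_that("Ca-binding motif search reports overlapping hits", {
  expect_equal(find_ca_motif("AADADAADAA"), 3L)
  expect_equal(find_ca_motif("WWWWWW"), integer(0))
  expect_equal(find_ca_motif("DDDDDDD"), c(1L, 2L))
  expect_equal(find_ca_motif(""), integer(0))
})

test_that("isoelectric points reflect residue chemistry", {
  expect_gt(isoelectric_point(strrep("K", 21)), 10)
  expect_lt(isoelectric_point(strrep("D", 21)), 4)
  gly <- isoelectric_point(strrep("G", 21))
  expect_gt(gly, 5); expect_lt(gly, 7)
  prof <- isoelectric_profile(paste0(strrep("K", 30), strrep("D", 30)),
                              window = 11)
  expect_length(prof, 60L)
  expect_gt(prof[5], 10)
  expect_lt(prof[55], 4)
  expect_error(isoelectric_profile("KKKK", window = 4), "odd")
})

test_that("the shipped motif pattern file matches the built-in defaults", {
  path <- system.file("extdata", "rep_motif_patterns.tsv",
                      package = "crucivir")
  expect_true(file.exists(path))
  df <- read_motif_patterns(path)
  expect_equal(df, default_rep_motif_patterns())
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines("foo\tbar", bad)
  expect_error(read_motif_patterns(bad), "columns")
})
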