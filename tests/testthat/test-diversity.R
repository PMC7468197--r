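fake_identity_matrix <- function(values, ids = rownames(values)) {
  structure(list(ids = ids, values = values, aligner = "test",
                 pi_definition = "test"), class = "IdentityMatrix")
}

test_that("pairwise identity follows the SDT-style definition", {
  m <- pairwise_identity_matrix(c(a = "MKLVW", b = "MKLVW"))
  expect_equal(unname(m$values["a", "b"]), 100)
  expect_equal(unname(diag(m$values)), c(100, 100))
  m2 <- pairwise_identity_matrix(c(a = "AAAA", b = "AATA"))
  expect_equal(unname(m2$values["a", "b"]), 75)
  expect_error(pairwise_identity_matrix(c(a = "AAAA", b = "")), "b")
  expect_error(pairwise_identity_matrix(c(a = "AAAA")), "two")
})

test_that("identity matrices are symmetric and permutation-equivariant", {
  set.seed(301)
  prots <- setNames(vapply(1:6, function(i) rand_prot(40), character(1)),
                    paste0("p", 1:6))
  m <- pairwise_identity_matrix(prots)
  expect_true(isSymmetric(m$values))
  perm <- sample(names(prots))
  m2 <- pairwise_identity_matrix(prots[perm])
  expect_equal(m2$values[names(prots), names(prots)], m$values)
})

test_that("matrix statistics summarize the upper triangle", {
  v <- matrix(c(100, 40, 40, 100), 2, dimnames = list(c("a", "b"),
                                                      c("a", "b")))
  st <- matrix_stats(fake_identity_matrix(v))
  expect_equal(st$mean, 40); expect_equal(st$sd, 0)
  v3 <- matrix(100, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  v3["a", "b"] <- v3["b", "a"] <- 10
  v3["a", "c"] <- v3["c", "a"] <- 20
  v3["b", "c"] <- v3["c", "b"] <- 30
  st3 <- matrix_stats(fake_identity_matrix(v3))
  expect_equal(st3$mean, 20)
  expect_equal(st3$n_pairs, 3L)
  expect_equal(st3$sd, sd(c(10, 20, 30)))
})

test_that("threshold clustering implements the stated rules", {
  ids <- paste0("s", 1:8)
  v <- matrix(80, 8, 8, dimnames = list(ids, ids)); diag(v) <- 100
  cs <- cluster_by_threshold(fake_identity_matrix(v), min_pi = 70,
                             max_pi = 100, min_size = 7)
  expect_length(cs$clusters, 1L)
  expect_length(cs$clusters[[1]], 8L)

  # two identical sequences collapse to one representative
  v2 <- v; v2["s1", "s2"] <- v2["s2", "s1"] <- 100
  cs2 <- cluster_by_threshold(fake_identity_matrix(v2), min_pi = 45,
                              max_pi = 98, min_size = 7)
  expect_length(cs2$clusters, 1L)
  expect_length(cs2$clusters[[1]], 7L)
  expect_false(all(c("s1", "s2") %in% cs2$clusters[[1]]))

  # single linkage: a chain forms one component
  ids3 <- c("a", "b", "c")
  v3 <- matrix(40, 3, 3, dimnames = list(ids3, ids3)); diag(v3) <- 100
  v3["a", "b"] <- v3["b", "a"] <- 75
  v3["b", "c"] <- v3["c", "b"] <- 75
  cs3 <- cluster_by_threshold(fake_identity_matrix(v3), min_pi = 70,
                              max_pi = 100, min_size = 3)
  expect_equal(cs3$clusters[[1]], c("a", "b", "c"))
  # clique mode does not admit the chain
  cs3q <- cluster_by_threshold(fake_identity_matrix(v3), min_pi = 70,
                               max_pi = 100, min_size = 3, mode = "clique")
  expect_length(cs3q$clusters, 0L)

  # order invariance
  perm <- c(5, 3, 8, 1, 2, 7, 4, 6)
  csp <- cluster_by_threshold(
    fake_identity_matrix(v[perm, perm]), min_pi = 70, max_pi = 100,
    min_size = 7)
  expect_equal(csp$clusters, cs$clusters)
})

test_that("planted sequence families are recovered exactly", {
  set.seed(310)
  k <- 4
  fams <- unlist(lapply(1:k, function(f) {
    anc <- rand_prot(120)
    vapply(1:8, function(j) {
      ch <- strsplit(anc, "")[[1]]
      idx <- sample(120, 8)
      ch[idx] <- vapply(idx, function(i) sample(setdiff(AAS, ch[i]), 1),
                        character(1))
      paste(ch, collapse = "")
    }, character(1))
  }))
  names(fams) <- sprintf("f%d_%d", rep(1:k, each = 8), 1:8)
  m <- pairwise_identity_matrix(fams)
  cs <- cluster_by_threshold(m, min_pi = 70, max_pi = 100, min_size = 7)
  expect_length(cs$clusters, k)
  for (cl in cs$clusters)
    expect_length(unique(sub("_.*", "", cl)), 1L)
})

test_that("one-way ANOVA matches stats::oneway.test and handles degeneracy", {
  g1 <- list(c(1, 2, 3, 2), c(2, 3, 4, 5), c(6, 7, 8, 7))
  res <- one_way_anova(g1)
  ref <- stats::oneway.test(y ~ g,
                            data = data.frame(y = unlist(g1),
                                              g = factor(rep(1:3, each = 4))),
                            var.equal = TRUE)
  expect_equal(res$F, unname(ref$statistic))
  expect_equal(res$p, unname(ref$p.value))
  expect_equal(one_way_anova(list(c(1, 1, 1), c(1, 1, 1))),
               list(F = 0, p = 1, df_between = 1L, df_within = 4L))
  sep <- one_way_anova(list(c(0, 0.01, -0.01), c(10, 10.01, 9.99)))
  expect_lt(sep$p, 0.001)
  expect_error(one_way_anova(list(1, c(1, 2))), "at least two")
})

test_that("similarity networks threshold on E-values and nest monotonically", {
  set.seed(320)
  p <- rand_prot(200)
  twin <- c(a = p, b = p, c = rand_prot(200))
  net <- build_similarity_network(twin, cutoff = 1e-20)
  expect_true(any(net$edges$id1 == "a" & net$edges$id2 == "b"))
  expect_equal(igraph::vcount(net$graph), 3L)   # isolated nodes retained

  # random pairs stay unconnected at a stringent cutoff
  rnd <- setNames(vapply(1:10, function(i) rand_prot(100), character(1)),
                  paste0("r", 1:10))
  net2 <- build_similarity_network(rnd, cutoff = 1e-20)
  expect_equal(nrow(net2$edges), 0L)

  # nesting in the cutoff
  fam <- c(twin, rnd)
  e_strict <- build_similarity_network(fam, cutoff = 1e-20)$edges
  e_loose <- build_similarity_network(fam, cutoff = 1e-10)$edges
  key <- function(e) paste(e$id1, e$id2)
  expect_true(all(key(e_strict) %in% key(e_loose)))
})
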