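# Diversity analysis: SDT-style pairwise-identity matrices, summary
# statistics, threshold clustering, one-way ANOVA across protein classes,
# and E-value similarity networks.

#' SDT-style pairwise identity matrix
#'
#' For each unordered pair of proteins a global (Needleman-Wunsch) affine
#' alignment is computed and the percent identity is the number of
#' identical columns over the alignment length, counting internal gap
#' columns but excluding terminal overhangs. The definition is recorded in
#' the result so matrices are self-describing.
#'
#' @param proteins named character vector (or `AAStringSet`) of protein
#'   sequences
#' @param matrix substitution matrix name (default `"BLOSUM62"`)
#' @param gap_open,gap_extend affine gap penalties
#' @return an `IdentityMatrix`: list with `ids`, `values` (symmetric
#'   percent-identity matrix, diagonal 100), `aligner`, `pi_definition`
#' @export
pairwise_identity_matrix <- function(proteins, matrix = "BLOSUM62",
                                     gap_open = 11, gap_extend = 1) {
  nm <- names(proteins)
  proteins <- as.character(proteins)
  names(proteins) <- nm
  if (length(proteins) < 2L)
    stop("need at least two sequences", call. = FALSE)
  if (is.null(names(proteins)))
    names(proteins) <- paste0("seq", seq_along(proteins))
  empty <- names(proteins)[!nchar(proteins)]
  if (length(empty))
    stop("empty sequence(s): ", paste(empty, collapse = ", "), call. = FALSE)
  sub <- load_sub_matrix(matrix)
  k <- length(proteins)
  values <- matrix(100, k, k, dimnames = list(names(proteins), names(proteins)))
  for (i in seq_len(k - 1L)) {
    for (j in seq.int(i + 1L, k)) {
      al <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(proteins[[i]]), Biostrings::AAString(proteins[[j]]),
        type = "global", substitutionMatrix = sub,
        gapOpening = gap_open, gapExtension = gap_extend)
      idy <- alignment_identity(al, exclude_terminal_gaps = TRUE)
      pi <- if (idy$len) 100 * idy$n_id / idy$len else 0
      values[i, j] <- values[j, i] <- pi
    }
  }
  structure(
    list(ids = names(proteins), values = values,
         aligner = sprintf("needleman-wunsch/%s/open%g/ext%g", matrix,
                           gap_open, gap_extend),
         pi_definition = "identical/aligned columns incl. internal gaps, excl. terminal overhangs"),
    class = "IdentityMatrix")
}

#' @export
print.IdentityMatrix <- function(x, ...) {
  st <- matrix_stats(x)
  cat(sprintf("<IdentityMatrix> %d sequences; mean PI %.1f%% +/- %.1f%% [%s]\n",
              length(x$ids), st$mean, st$sd, x$aligner))
  invisible(x)
}

upper_tri_values <- function(m) {
  v <- if (inherits(m, "IdentityMatrix")) m$values else m
  v[upper.tri(v)]
}

#' Mean and standard deviation of off-diagonal pairwise identities
#'
#' @param m `IdentityMatrix` (or plain symmetric matrix)
#' @param sd_type `"sample"` (n-1 denominator, default) or `"population"`
#' @return list with `mean`, `sd`, `n_pairs`
#' @export
matrix_stats <- function(m, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  v <- upper_tri_values(m)
  if (!length(v)) stop("need at least two sequences", call. = FALSE)
  s <- stats::sd(v)
  if (sd_type == "population") s <- s * sqrt((length(v) - 1) / length(v))
  if (length(v) == 1L) s <- 0
  list(mean = mean(v), sd = s, n_pairs = length(v))
}

#' Threshold clustering of an identity matrix
#'
#' Builds a graph with an edge between two sequences when their pairwise
#' identity lies strictly between `min_pi` and `max_pi`, and reports
#' either connected components (single linkage, default) or maximal
#' groups in which every pair is connected (`mode = "clique"`). Pairs at
#' 100% identity are collapsed to a single representative before
#' clustering, so clusters count nonidentical sequences. Components
#' smaller than `min_size` are dropped. Cluster order is deterministic:
#' by decreasing size, then lexicographic smallest member.
#'
#' @param m `IdentityMatrix`
#' @param min_pi,max_pi strict bounds on pairwise identity (percent)
#' @param min_size smallest cluster reported (default 7, i.e. more than
#'   six members)
#' @param mode `"component"` or `"clique"`
#' @return a `ClusterSet`: list with `clusters` (list of character
#'   vectors of ids), `representatives` (map collapsed id -> members),
#'   `min_pi`, `max_pi`, `min_size`, `linkage`
#' @export
cluster_by_threshold <- function(m, min_pi, max_pi = 100, min_size = 7L,
                                 mode = c("component", "clique")) {
  mode <- match.arg(mode)
  stopifnot(inherits(m, "IdentityMatrix"),
            min_pi >= 0, min_pi < max_pi, max_pi <= 100)
  ids <- sort(m$ids)
  v <- m$values[ids, ids, drop = FALSE]
  # collapse 100%-identical sequences to one representative (first by name)
  reps <- list()
  keep <- character()
  assigned <- setNames(rep(FALSE, length(ids)), ids)
  for (id in ids) {
    if (assigned[[id]]) next
    same <- ids[v[id, ids] >= 100 - 1e-9 & !assigned[ids]]
    same <- union(id, same)
    assigned[same] <- TRUE
    keep <- c(keep, id)
    reps[[id]] <- same
  }
  vv <- v[keep, keep, drop = FALSE]
  adj <- vv > min_pi & vv < max_pi
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  groups <- if (mode == "component") {
    comp <- igraph::components(g)
    split(keep, comp$membership)
  } else {
    # maximal cliques of size >= min_size; assign greedily, largest first
    cl <- igraph::max_cliques(g, min = min_size)
    lapply(cl, function(x) keep[as.integer(x)])
  }
  groups <- Filter(function(x) length(x) >= min_size, groups)
  groups <- lapply(groups, sort)
  ord <- order(-vapply(groups, length, integer(1)),
               vapply(groups, function(x) x[1], character(1)))
  structure(
    list(clusters = unname(groups[ord]), representatives = reps,
         min_pi = min_pi, max_pi = max_pi, min_size = as.integer(min_size),
         linkage = if (mode == "component") "single" else "clique"),
    class = "ClusterSet")
}

#' @export
print.ClusterSet <- function(x, ...) {
  cat(sprintf("<ClusterSet> %d cluster(s) (PI in (%g, %g), min size %d, %s linkage): sizes %s\n",
              length(x$clusters), x$min_pi, x$max_pi, x$min_size, x$linkage,
              paste(vapply(x$clusters, length, integer(1)), collapse = ",")))
  invisible(x)
}

#' One-way analysis of variance across groups
#'
#' Classical between/within mean-square F statistic with its p-value from
#' the F distribution. When all groups have zero within-group variance and
#' equal means, `F = 0` and `p = 1` by convention.
#'
#' @param groups list of (>= 2) numeric vectors, each of length >= 2
#' @return list with `F`, `p`, `df_between`, `df_within`
#' @export
one_way_anova <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (any(vapply(groups, length, integer(1)) < 2L))
    stop("each group needs at least two values", call. = FALSE)
  y <- unlist(groups, use.names = FALSE)
  f <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  ss_between <- sum(tapply(y, f, function(v) length(v) * (mean(v) - mean(y))^2))
  ss_within <- sum(tapply(y, f, function(v) sum((v - mean(v))^2)))
  df_b <- nlevels(f) - 1L
  df_w <- length(y) - nlevels(f)
  if (ss_within == 0 && ss_between == 0)
    return(list(F = 0, p = 1, df_between = df_b, df_within = df_w))
  Fstat <- (ss_between / df_b) / (ss_within / df_w)
  list(F = Fstat, p = stats::pf(Fstat, df_b, df_w, lower.tail = FALSE),
       df_between = df_b, df_within = df_w)
}

#' Build an E-value-thresholded protein similarity network
#'
#' All-vs-all local alignment; each pair's raw Smith-Waterman score is
#' converted to an E-value (`K * m * n * exp(-lambda * S)`) and an edge is
#' drawn when the E-value is below `cutoff`. Isolated nodes are retained.
#'
#' @param proteins named character vector of protein sequences
#' @param groups optional character vector of group labels (same order)
#' @param cutoff E-value threshold (edges strictly below it)
#' @param matrix,gap_open,gap_extend alignment parameters
#' @return a `SimilarityGraph`: list with `graph` (igraph object with
#'   vertex attribute `group` and edge attribute `evalue`), `edges` (data
#'   frame id1, id2, evalue), `cutoff`
#' @export
build_similarity_network <- function(proteins, groups = NULL, cutoff = 1e-20,
                                     matrix = "BLOSUM62", gap_open = 11,
                                     gap_extend = 1) {
  nm <- names(proteins)
  proteins <- as.character(proteins)
  names(proteins) <- nm
  if (length(proteins) < 2L) stop("need at least two proteins", call. = FALSE)
  if (is.null(names(proteins)))
    names(proteins) <- paste0("seq", seq_along(proteins))
  sub <- load_sub_matrix(matrix)
  params <- karlin_altschul_params()
  k <- length(proteins)
  ids <- names(proteins)
  rows <- list()
  for (i in seq_len(k - 1L)) {
    sc <- Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(proteins[seq.int(i + 1L, k)]),
      Biostrings::AAString(proteins[[i]]), type = "local",
      substitutionMatrix = sub, gapOpening = gap_open,
      gapExtension = gap_extend, scoreOnly = TRUE)
    for (jj in seq_along(sc)) {
      j <- i + jj
      ev <- evalue_score(sc[jj], nchar(proteins[[i]]), nchar(proteins[[j]]),
                         params)
      if (ev < cutoff)
        rows[[length(rows) + 1L]] <- data.frame(
          id1 = ids[i], id2 = ids[j], evalue = ev, stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id1 = character(), id2 = character(), evalue = numeric(),
               stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = ids))
  if (!is.null(groups)) igraph::V(g)$group <- groups
  structure(list(graph = g, edges = edges, cutoff = cutoff),
            class = "SimilarityGraph")
}

#' @export
print.SimilarityGraph <- function(x, ...) {
  comp <- igraph::components(x$graph)
  cat(sprintf("<SimilarityGraph> %d nodes, %d edges (E < %g), %d component(s)\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph), x$cutoff,
              comp$no))
  invisible(x)
}

#' Write a similarity network to GraphML and edge-list TSV
#'
#' @param net `SimilarityGraph`
#' @param graphml_path,edges_path output paths (either may be `NULL`)
#' @return invisibly, the paths written
#' @export
write_similarity_network <- function(net, graphml_path = NULL,
                                     edges_path = NULL) {
  if (!is.null(graphml_path))
    igraph::write_graph(net$graph, graphml_path, format = "graphml")
  if (!is.null(edges_path))
    utils::write.table(net$edges, edges_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(c(graphml_path, edges_path))
}
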