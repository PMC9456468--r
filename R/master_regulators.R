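# Master-regulator search on a directed regulatory network: radius-bounded
# downstream reachability, distance-weighted coverage scoring, and a
# permutation null over random gene sets of matched size.

#' Construct a regulatory network
#'
#' Edges are oriented regulator -> target. Self-loops are dropped with a
#' warning; parallel edges are collapsed. Each node may map to a gene
#' identifier (defaults to its own name); unmapped nodes (`NA`) take part
#' in reachability but never count as differential hits and are excluded
#' from the permutation universe.
#'
#' @param edges Data frame (or 2-column matrix) with columns `from`, `to`.
#' @param gene_map Optional named character vector node -> gene symbol.
#' @param nodes Optional character vector of isolated nodes to include.
#' @return A `kr_network` object wrapping an igraph directed graph.
#' @export
regulatory_network <- function(edges, gene_map = NULL, nodes = NULL) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) < 2L) stop("`edges` needs columns from, to")
  from <- as.character(edges[[1L]])
  to <- as.character(edges[[2L]])
  loops <- from == to
  if (any(loops)) {
    warning("dropped ", sum(loops), " self-loop(s)")
    from <- from[!loops]; to <- to[!loops]
  }
  ids <- unique(c(from, to, nodes))
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to, stringsAsFactors = FALSE),
    directed = TRUE, vertices = data.frame(name = ids)
  )
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  gene <- if (is.null(gene_map)) {
    stats::setNames(norm_id(ids), ids)
  } else {
    stats::setNames(norm_id(gene_map[ids]), ids)
  }
  structure(list(graph = g, gene = gene), class = "kr_network")
}

#' @export
print.kr_network <- function(x, ...) {
  cat("Regulatory network:", igraph::vcount(x$graph), "nodes,",
      igraph::ecount(x$graph), "directed edges\n")
  invisible(x)
}

network_nodes <- function(network) igraph::V(network$graph)$name

#' Radius-bounded downstream cone
#'
#' Breadth-first shortest-path distances from `node` following edge
#' direction, truncated at `radius`; the node itself is excluded.
#'
#' @param network A `kr_network`.
#' @param node Node identifier.
#' @param radius Maximum number of steps (default 10).
#' @return Named numeric vector of distances (1..radius) for every
#'   reachable node.
#' @export
downstream_cone <- function(network, node, radius = 10) {
  stopifnot(inherits(network, "kr_network"))
  if (!node %in% network_nodes(network)) stop("unknown node: ", node)
  d <- igraph::distances(network$graph, v = node, mode = "out")[1L, ]
  d <- d[is.finite(d) & d > 0 & d <= radius]
  d
}

#' Distance-weighted coverage score
#'
#' score = sum over differential hits h reached by the cone of 1/d(h),
#' divided by the total number of hits. The score lies in \[0, 1\] and
#' equals 1 exactly when every hit is a direct target (distance 1).
#'
#' @param cone Named distance vector from [downstream_cone()], with names
#'   on the gene scale.
#' @param hits Character vector of differential gene identifiers
#'   (non-empty).
#' @return Numeric score in \[0, 1\].
#' @export
coverage_score <- function(cone, hits) {
  hits <- unique(norm_id(hits))
  if (!length(hits)) stop("`hits` must be non-empty")
  reached <- cone[norm_id(names(cone)) %in% hits]
  if (!length(reached)) return(0)
  sum(1 / reached) / length(hits)
}

# distances on the gene scale for one node: cone over nodes, renamed to
# mapped genes (unmapped nodes dropped)
gene_cone <- function(network, node, radius) {
  cone <- downstream_cone(network, node, radius)
  genes <- network$gene[names(cone)]
  keep <- !is.na(genes)
  stats::setNames(cone[keep], genes[keep])
}

#' Permutation null for one candidate regulator
#'
#' Draws `n_permutations` random gene sets of the same size as `hits`
#' uniformly from the gene-mapped network nodes, computes the coverage
#' score of each against the node's cone, and reports
#' Z = (observed - null mean) / null sd and the add-one empirical p-value
#' (1 + #\{null >= observed\}) / (1 + n_permutations). A null with zero
#' standard deviation (e.g. an empty cone) yields Z = 0 with a degeneracy
#' flag.
#'
#' @param network A `kr_network`.
#' @param node Node identifier.
#' @param hits Observed differential gene set.
#' @param n_permutations Number of null draws (default 1000).
#' @param rng_seed Seed for the permutation sampler (default 1).
#' @param radius Cone radius (default 10).
#' @return List: `observed`, `null` (numeric vector), `z`, `p`,
#'   `degenerate`.
#' @export
permutation_null <- function(network, node, hits, n_permutations = 1000,
                             rng_seed = 1, radius = 10) {
  hits <- unique(norm_id(hits))
  universe <- unique(network$gene[!is.na(network$gene)])
  if (length(hits) > length(universe)) {
    stop("more hits than gene-mapped network nodes")
  }
  cone <- gene_cone(network, node, radius)
  observed <- coverage_score(cone, hits)
  m <- length(hits)
  w <- stats::setNames(numeric(length(universe)), universe)
  w[names(cone)[names(cone) %in% universe]] <-
    1 / cone[names(cone) %in% universe]
  set.seed(rng_seed)
  idx <- replicate(n_permutations, sample.int(length(universe), m))
  nulls <- colSums(matrix(w[idx], nrow = m)) / m
  s <- stats::sd(nulls)
  degenerate <- !is.finite(s) || s == 0
  z <- if (degenerate) 0 else (observed - mean(nulls)) / s
  p <- (1 + sum(nulls >= observed)) / (1 + n_permutations)
  list(observed = observed, null = nulls, z = z, p = p,
       degenerate = degenerate)
}

#' Master-regulator search
#'
#' Evaluates every network node as a candidate regulator of a differential
#' list: coverage score of its radius-bounded downstream cone over the
#' differential genes, permutation Z-score and empirical p-value against
#' random gene sets of matched size, and Benjamini-Hochberg adjustment
#' across nodes. Candidates are retained when score >= `score_min`,
#' Z >= `z_min` and adjusted p <= `fdr_max`, and are ordered by score
#' (descending), then Z (descending), then identifier.
#'
#' The same permutation draws are reused for every node, which makes the
#' search deterministic given `rng_seed` and considerably faster without
#' biasing per-node p-values. The default permutation count is higher than
#' in [permutation_null()] because the add-one empirical p-value is floored
#' at 1/(B + 1): with hundreds of nodes under Benjamini-Hochberg
#' adjustment, B must be large enough that even a handful of genuine
#' regulators can reach adjusted p below `fdr_max`.
#'
#' @param network A `kr_network`.
#' @param de_list A `kr_de_list` (or character vector of gene symbols).
#' @param radius,score_min,z_min,fdr_max Filter cut-offs
#'   (defaults 10, 0.2, 1.0, 0.05).
#' @param n_permutations Null draws per node (default 10000).
#' @param rng_seed Permutation seed (default 1).
#' @return Data frame (`kr_mr_result`): `node`, `gene`, `n_hits_reached`,
#'   `score`, `z`, `p`, `padj`, `degenerate`, filtered and ordered.
#' @export
find_master_regulators <- function(network, de_list, radius = 10,
                                   score_min = 0.2, z_min = 1.0,
                                   fdr_max = 0.05, n_permutations = 10000,
                                   rng_seed = 1) {
  stopifnot(inherits(network, "kr_network"))
  hits <- if (inherits(de_list, "kr_de_list")) de_list$entity else de_list
  hits <- unique(norm_id(hits))
  universe <- unique(network$gene[!is.na(network$gene)])
  hits <- hits[hits %in% universe]
  empty <- data.frame(node = character(), gene = character(),
                      n_hits_reached = integer(), score = numeric(),
                      z = numeric(), p = numeric(), padj = numeric(),
                      degenerate = logical(), stringsAsFactors = FALSE)
  if (!length(hits)) {
    warning("differential list maps to zero network nodes")
    return(empty)
  }
  m <- length(hits)
  nodes <- network_nodes(network)
  dmat <- igraph::distances(network$graph, mode = "out")

  # W[i, g] = 1 / shortest distance from node i to a node mapped to gene
  # g within the radius (0 when unreachable); duplicate gene mappings
  # take the closest node
  wnode <- ifelse(is.finite(dmat) & dmat > 0 & dmat <= radius, 1 / dmat, 0)
  W <- matrix(0, length(nodes), length(universe),
              dimnames = list(nodes, universe))
  geneof <- network$gene[nodes]
  for (j in seq_along(nodes)) {
    g <- geneof[j]
    if (!is.na(g)) W[, g] <- pmax(W[, g], wnode[, j])
  }

  score <- rowSums(W[, hits, drop = FALSE]) / m
  nreach <- rowSums(W[, hits, drop = FALSE] > 0)

  # shared null draws: S is universe x B with m ones per column, so
  # W %*% S gives every node's null scores in one product
  set.seed(rng_seed)
  B <- n_permutations
  S <- matrix(0, length(universe), B)
  idx <- replicate(B, sample.int(length(universe), m))
  S[cbind(as.vector(idx), rep(seq_len(B), each = m))] <- 1
  N <- (W %*% S) / m

  mu <- rowMeans(N)
  s <- sqrt(pmax(0, (rowSums(N^2) - B * mu^2) / (B - 1)))
  degen <- !is.finite(s) | s == 0
  z <- ifelse(degen, 0, (score - mu) / s)
  p <- (1 + rowSums(N >= score)) / (1 + B)
  padj <- stats::p.adjust(p, method = "BH")
  keep <- score >= score_min & z >= z_min & padj <= fdr_max
  res <- data.frame(node = nodes, gene = unname(network$gene[nodes]),
                    n_hits_reached = nreach, score = score, z = z, p = p,
                    padj = padj, degenerate = degen,
                    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  res <- res[order(-res$score, -res$z, res$node), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("kr_mr_result", "data.frame")
  res
}
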