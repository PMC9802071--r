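#' Response-by-target count matrix for one condition
#'
#' Structures cleaned responses into the matrix underlying the group-level
#' semantic network: columns are target words, rows are the unique responses
#' given in the condition, and each cell holds the number of distinct
#' participants who gave that response to that target (0 otherwise).
#'
#' @param clean Cleaned response table.
#' @param condition Condition label to extract.
#' @param targets Optional character vector fixing the column set and order;
#'   defaults to the sorted targets present in the condition.
#' @return Integer matrix with lexicographically ordered response rownames.
#' @export
build_count_matrix <- function(clean, condition, targets = NULL) {
  if (!condition %in% clean$condition)
    stop("condition '", condition, "' absent from the response table")
  x <- clean[clean$condition == condition, ]
  if (is.null(targets)) targets <- sort(unique(x$target))
  ## distinct participants per response-target pair
  x <- unique(x[, c("participant", "target", "response")])
  responses <- sort(unique(x$response))
  M <- matrix(0L, length(responses), length(targets),
              dimnames = list(responses, targets))
  tab <- table(x$response, x$target)
  M[rownames(tab), colnames(tab)] <- as.integer(tab)
  M
}

#' Cosine-similarity semantic network over target words
#'
#' Link weight between two targets is the cosine similarity of their response
#' count vectors: high when many participants gave overlapping responses to
#' both. All-zero columns yield similarity 0 (with a warning).
#'
#' @param M Count matrix from [build_count_matrix()].
#' @param condition Optional condition label stored on the network.
#' @return Object of class `semantic_network`: list with `weights` (symmetric
#'   matrix, zero diagonal), `nodes`, `condition`, `filtered = FALSE`.
#' @export
cosine_network <- function(M, condition = NULL) {
  if (ncol(M) < 2L) stop("need at least 2 targets")
  norms <- sqrt(colSums(M^2))
  zero <- norms == 0
  if (any(zero)) {
    warning("all-zero count column(s): ", paste(colnames(M)[zero], collapse = ", "),
            "; their similarities are set to 0")
    norms[zero] <- 1
  }
  W <- crossprod(M) / tcrossprod(norms)
  W[zero, ] <- 0
  W[, zero] <- 0
  diag(W) <- 0
  structure(list(weights = W, nodes = colnames(M), condition = condition,
                 filtered = FALSE),
            class = "semantic_network")
}

#' @export
print.semantic_network <- function(x, ...) {
  n <- length(x$nodes)
  m <- sum(x$weights[upper.tri(x$weights)] > 0)
  cat(sprintf("Semantic network%s: %d nodes, %d positive links%s\n",
              if (is.null(x$condition)) "" else paste0(" [", x$condition, "]"),
              n, m, if (x$filtered) " (TMFG-filtered)" else ""))
  invisible(x)
}

#' Triangulated Maximally Filtered Graph
#'
#' Sparsifies a dense weighted network to a maximal planar graph with exactly
#' `3n - 6` edges. The greedy construction seeds with the 4-clique of maximal
#' total weight, then repeatedly inserts the outside vertex with the highest
#' summed similarity to one of the current triangular faces, connecting it to
#' that face's three vertices and splitting the face in three. Ties are broken
#' by lowest node index (then lowest face index) for reproducibility. The
#' triangular face list built along the way is retained as a planarity
#' certificate (see [is_planar_triangulation()]).
#'
#' @param net A `semantic_network` (unfiltered, fully weighted).
#' @return The filtered `semantic_network`; weights outside the retained edge
#'   set are zeroed, `filtered = TRUE`, and attributes `faces` (k x 3 matrix)
#'   and `edges` (m x 2 matrix of node indices) record the embedding.
#' @export
tmfg_filter <- function(net) {
  W <- net$weights
  n <- nrow(W)
  if (n < 4L) stop("TMFG requires at least 4 nodes")

  ## seed: the 4-clique with maximal total weight (scored vectorised over
  ## all C(n, 4) candidates)
  quads <- utils::combn(n, 4L)
  prs <- utils::combn(4L, 2L)
  qw <- 0
  for (p in seq_len(ncol(prs)))
    qw <- qw + W[cbind(quads[prs[1, p], ], quads[prs[2, p], ])]
  seed <- quads[, which.max(qw)]

  edges <- t(utils::combn(seed, 2L))
  faces <- rbind(seed[-1], seed[-2], seed[-3], seed[-4])
  in_graph <- logical(n)
  in_graph[seed] <- TRUE

  while (any(!in_graph)) {
    outside <- which(!in_graph)
    ## gain of inserting vertex v into face f
    gain <- matrix(W[outside, faces[, 1], drop = FALSE] +
                     W[outside, faces[, 2], drop = FALSE] +
                     W[outside, faces[, 3], drop = FALSE],
                   nrow = length(outside))
    best <- which(gain == max(gain), arr.ind = TRUE)
    best <- best[order(outside[best[, 1]], best[, 2]), , drop = FALSE][1, ]
    v <- outside[best[1]]
    f <- best[2]
    tri <- faces[f, ]
    edges <- rbind(edges, cbind(v, tri))
    faces <- rbind(faces[-f, , drop = FALSE],
                   c(tri[1], tri[2], v), c(tri[1], tri[3], v), c(tri[2], tri[3], v))
    in_graph[v] <- TRUE
  }

  Wf <- matrix(0, n, n, dimnames = dimnames(W))
  Wf[edges] <- W[edges]
  Wf[edges[, 2:1]] <- W[edges]
  out <- net
  out$weights <- Wf
  out$filtered <- TRUE
  attr(out, "faces") <- faces
  attr(out, "edges") <- edges
  out
}

#' Verify the planar-triangulation certificate of a TMFG network
#'
#' Checks that the filtered network together with its recorded face list forms
#' a valid triangulated planar embedding: `3n - 6` edges, `2n - 4` triangular
#' faces whose edges all exist in the graph, every edge lying on exactly two
#' faces, and a connected graph. By Euler's formula such a certificate exists
#' only for planar graphs, so a `TRUE` result proves planarity.
#'
#' @param net A TMFG-filtered `semantic_network`.
#' @return `TRUE` or `FALSE`.
#' @export
is_planar_triangulation <- function(net) {
  if (!isTRUE(net$filtered)) return(FALSE)
  faces <- attr(net, "faces")
  edges <- attr(net, "edges")
  n <- length(net$nodes)
  if (is.null(faces) || is.null(edges)) return(FALSE)
  if (nrow(edges) != 3L * n - 6L || nrow(faces) != 2L * n - 4L) return(FALSE)
  ekey <- function(a, b) paste(pmin(a, b), pmax(a, b))
  eset <- ekey(edges[, 1], edges[, 2])
  if (anyDuplicated(eset)) return(FALSE)
  face_edges <- c(ekey(faces[, 1], faces[, 2]),
                  ekey(faces[, 1], faces[, 3]),
                  ekey(faces[, 2], faces[, 3]))
  if (!all(face_edges %in% eset)) return(FALSE)
  if (!all(table(face_edges) == 2L)) return(FALSE)
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::is_connected(g)
}

as_igraph <- function(net, weighted = FALSE) {
  edges <- attr(net, "edges")
  if (isTRUE(net$filtered) && !is.null(edges)) {
    ## a TMFG retains its 3n - 6 edges even where the similarity is zero
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, length(net$nodes) - igraph::vcount(g)))
    igraph::V(g)$name <- net$nodes
    if (weighted) igraph::E(g)$weight <- net$weights[edges]
    return(g)
  }
  A <- net$weights
  if (weighted) {
    igraph::graph_from_adjacency_matrix(A, mode = "undirected", weighted = TRUE,
                                        diag = FALSE)
  } else {
    igraph::graph_from_adjacency_matrix((A > 0) * 1, mode = "undirected",
                                        diag = FALSE)
  }
}

## topology quantifiers on an igraph object
topology_graph <- function(g, n_random = 100L, seed = NULL, weighted = FALSE) {
  if (!igraph::is_connected(g)) {
    comp <- igraph::components(g)
    stop("graph is disconnected (components of size ",
         paste(comp$csize, collapse = ", "), ")")
  }
  cc <- igraph::transitivity(g, type = "global")
  aspl <- if (weighted)
    igraph::mean_distance(g, weights = 1 / igraph::E(g)$weight) else
    igraph::mean_distance(g, weights = NA)
  comm <- igraph::cluster_fast_greedy(
    g, weights = if (weighted) igraph::E(g)$weight else NULL)
  q <- igraph::modularity(comm)
  if (!is.null(seed)) set.seed(seed)
  n <- igraph::vcount(g)
  m <- igraph::ecount(g)
  cc_r <- aspl_r <- numeric(n_random)
  for (i in seq_len(n_random)) {
    repeat {
      er <- igraph::sample_gnm(n, m)
      if (igraph::is_connected(er)) break
    }
    cc_r[i] <- igraph::transitivity(er, type = "global")
    aspl_r[i] <- igraph::mean_distance(er, weights = NA)
  }
  s <- (cc / mean(cc_r)) / (aspl / mean(aspl_r))
  data.frame(cc = cc, aspl = aspl, q = q, s = s)
}

#' Topological quantifiers of a filtered semantic network
#'
#' Computes, on the binarised TMFG graph by default: the global clustering
#' coefficient CC (transitivity: 3 x triangles / connected triples), the
#' average shortest path length ASPL over all node pairs, the modularity Q of
#' the partition found by greedy modularity maximisation, and the
#' small-worldness `S = (CC / CC_rand) / (ASPL / ASPL_rand)` where the random
#' baselines are means over `n_random` connected Erdos-Renyi graphs with the
#' same number of nodes and edges (disconnected draws are resampled).
#'
#' @param net A filtered, connected `semantic_network`.
#' @param n_random Number of Erdos-Renyi reference graphs for S.
#' @param seed Seed for the random baselines.
#' @param weighted Use edge weights for ASPL (distances `1/w`) and Q; CC is
#'   always the binary transitivity.
#' @return One-row data frame with columns `cc`, `aspl`, `q`, `s`, and
#'   `provenance = "full"`.
#' @export
topology <- function(net, n_random = 100L, seed = NULL, weighted = FALSE) {
  g <- as_igraph(net, weighted = weighted)
  rep <- topology_graph(g, n_random = n_random, seed = seed, weighted = weighted)
  rep$provenance <- "full"
  rep
}

#' Leave-one-node-out topology
#'
#' Drops each node in turn from the filtered network (without re-running the
#' TMFG filter) and recomputes the topological quantifiers on the remaining
#' graph; if the deletion disconnects the graph, the largest component is used
#' and flagged in the report.
#'
#' @inheritParams topology
#' @return Data frame with one row per left-out node (`provenance` names it)
#'   and a logical `reduced` column marking largest-component fallbacks.
#' @export
lono_topology <- function(net, n_random = 100L, seed = NULL, weighted = FALSE) {
  g0 <- as_igraph(net, weighted = weighted)
  out <- vector("list", length(net$nodes))
  for (i in seq_along(net$nodes)) {
    g <- igraph::delete_vertices(g0, net$nodes[i])
    reduced <- FALSE
    if (!igraph::is_connected(g)) {
      comp <- igraph::components(g)
      g <- igraph::induced_subgraph(g, which(comp$membership == which.max(comp$csize)))
      reduced <- TRUE
    }
    rep <- topology_graph(g, n_random = n_random, seed = seed, weighted = weighted)
    rep$provenance <- paste0("LONO:", net$nodes[i])
    rep$reduced <- reduced
    out[[i]] <- rep
  }
  do.call(rbind, out)
}

#' Leave-one-subject-out topology
#'
#' Excludes each participant in turn and repeats the entire network pipeline —
#' count matrix, cosine similarity, TMFG filter, quantifiers — on the
#' remaining sample.
#'
#' @param clean Cleaned response table.
#' @param condition Condition to analyse.
#' @param targets Optional fixed target set passed to [build_count_matrix()].
#' @inheritParams topology
#' @return Data frame with one row per left-out participant.
#' @export
loso_topology <- function(clean, condition, targets = NULL, n_random = 100L,
                          seed = NULL, weighted = FALSE) {
  participants <- sort(unique(clean$participant))
  out <- vector("list", length(participants))
  for (i in seq_along(participants)) {
    sub <- clean[clean$participant != participants[i], ]
    net <- tmfg_filter(cosine_network(
      build_count_matrix(sub, condition, targets = targets), condition))
    rep <- topology(net, n_random = n_random, seed = seed, weighted = weighted)
    rep$provenance <- paste0("LOSO:", participants[i])
    out[[i]] <- rep
  }
  do.call(rbind, out)
}

#' Modularity of a network partition
#'
#' Newman modularity of a given or greedily optimised partition; unlike
#' [topology()] this accepts disconnected graphs (components are natural
#' communities).
#'
#' @param net A `semantic_network`.
#' @param membership Optional integer community assignment per node; defaults
#'   to the greedy modularity-maximising partition.
#' @param weighted Use edge weights.
#' @return Modularity value.
#' @export
network_modularity <- function(net, membership = NULL, weighted = FALSE) {
  g <- as_igraph(net, weighted = weighted)
  w <- if (weighted) igraph::E(g)$weight else NULL
  if (is.null(membership))
    membership <- igraph::membership(igraph::cluster_fast_greedy(g, weights = w))
  igraph::modularity(g, membership, weights = w)
}

#' Export a semantic network
#'
#' Writes GraphML (via igraph) or a weighted edge-list TSV.
#'
#' @param net A `semantic_network`.
#' @param path Output file path.
#' @param format `"graphml"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("graphml", "tsv")) {
  format <- match.arg(format)
  g <- as_igraph(net, weighted = TRUE)
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else {
    el <- igraph::as_data_frame(g, what = "edges")
    utils::write.table(el, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
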