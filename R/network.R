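#' Build an interaction network from an edge list
#'
#' Networks are represented as simple undirected [igraph][igraph::igraph]
#' graphs with named vertices. Self-loops are dropped and duplicate or
#' reversed-duplicate edges collapsed, so the result is always simple.
#'
#' @param edges Two-column character matrix or data frame of endpoints; may
#'   have zero rows.
#' @param nodes Optional additional isolated node names.
#' @param warn_self_loops Emit a warning when self-loops are removed.
#' @return A simple undirected igraph graph.
#' @export
as_network <- function(edges = NULL, nodes = character(), warn_self_loops = FALSE) {
  if (is.null(edges) || NROW(edges) == 0L) {
    em <- matrix(character(), ncol = 2L)
  } else {
    em <- as.matrix(edges)[, 1:2, drop = FALSE]
    storage.mode(em) <- "character"
  }
  self <- em[, 1L] == em[, 2L]
  if (any(self) && warn_self_loops) {
    warning(sum(self), " self-loop(s) dropped")
  }
  endpoints <- unique(as.character(em))  # loop endpoints remain nodes
  em <- em[!self, , drop = FALSE]
  g <- igraph::graph_from_edgelist(em, directed = FALSE)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  extra <- setdiff(unique(c(endpoints, as.character(nodes))),
                   igraph::V(g)$name %||% character())
  if (length(extra)) g <- igraph::add_vertices(g, length(extra), name = extra)
  g
}

#' Read a network from a two-column edge-list TSV
#'
#' One undirected edge per row, `node1<TAB>node2`, no header. Self-loops are
#' dropped with a warning and duplicate (including reversed) edges are
#' collapsed; the node set is the set of all endpoints. SIF rows
#' (`node1<TAB>relation<TAB>node2`) are also accepted.
#'
#' @param path Path to the TSV/SIF file.
#' @return A simple undirected igraph graph.
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  if (length(lines) == 0L) return(as_network())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(parts, length, 0L)
  bad <- which(nf != 2L & nf != 3L)
  if (length(bad)) {
    stop(sprintf("edge-list parse error at line %d of '%s': expected node1<TAB>node2",
                 which(keep)[bad[1L]], path))
  }
  em <- t(vapply(parts, function(p) if (length(p) == 3L) p[c(1L, 3L)] else p,
                 character(2L)))
  as_network(em, warn_self_loops = TRUE)
}

#' Write a network as an edge-list TSV
#'
#' Edges are written sorted (each edge's smaller endpoint first, rows in
#' lexicographic order) so identical networks always serialize to identical
#' bytes. Isolated nodes are not representable in the format and are
#' omitted.
#'
#' @param network A simple undirected igraph graph.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(network, path) {
  em <- igraph::as_edgelist(network)
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (nrow(em)) {
    swap <- em[, 1L] > em[, 2L]
    em[swap, ] <- em[swap, 2:1]
    em <- em[order(em[, 1L], em[, 2L]), , drop = FALSE]
    writeLines(paste(em[, 1L], em[, 2L], sep = "\t"), con, sep = "\n")
  }
  invisible(path)
}

# normalize a membership vector into a list of blocks: each block sorted,
# blocks ordered by their smallest member id (determinism contract)
membership_to_blocks <- function(membership, names) {
  blocks <- split(names, membership)
  blocks <- lapply(blocks, sort)
  blocks <- blocks[order(vapply(blocks, `[`, "", 1L))]
  names(blocks) <- NULL
  blocks
}

# inverse: named membership vector (block index per node)
blocks_to_membership <- function(blocks) {
  mem <- rep(seq_along(blocks), lengths(blocks))
  names(mem) <- unlist(blocks)
  mem
}

#' Newman-Girvan modularity of a partition
#'
#' For a partition into blocks \eqn{c}, \eqn{Q = \sum_c [ L_c/L - (d_c/2L)^2 ]}
#' where `L` is the total number of edges, `L_c` the number of edges inside
#' block `c` and `d_c` the total degree of block `c`. A single-block
#' partition always scores 0.
#'
#' @param network A simple undirected igraph graph with at least one edge.
#' @param partition A list of character vectors forming an exact cover of
#'   the network's nodes (or a membership vector named by node).
#' @return The modularity score, a number in \[-1, 1).
#' @export
network_modularity <- function(network, partition) {
  nodes <- igraph::V(network)$name
  if (igraph::ecount(network) < 1L) stop("modularity undefined for an edgeless network")
  if (is.list(partition)) {
    mem <- blocks_to_membership(partition)
  } else {
    mem <- partition
  }
  if (is.null(names(mem)) || !setequal(names(mem), nodes) ||
      length(mem) != length(nodes)) {
    stop("partition must cover the network's nodes exactly")
  }
  igraph::modularity(network, as.integer(factor(mem[nodes])))
}

#' Walktrap community detection with maximum-modularity cut
#'
#' Runs the walktrap algorithm: communities are merged agglomeratively using
#' the Euclidean distance between t-step random-walk transition-probability
#' vectors (each coordinate scaled by the inverse square root of the
#' destination degree), choosing at each step the merge with the smallest
#' Ward-style increase in squared distances. The returned partition is the
#' cut of the resulting merge dendrogram with maximum Newman-Girvan
#' modularity. The algorithm is deterministic given the node ordering.
#'
#' @param network A connected simple undirected igraph graph with >= 2
#'   nodes.
#' @param t Random-walk length (default 4, the method's canonical choice).
#' @return A list with `partition` (list of blocks, each sorted, blocks
#'   ordered by smallest member) and `Q` (its modularity).
#' @export
walktrap_partition <- function(network, t = 4L) {
  nodes <- igraph::V(network)$name
  if (length(nodes) < 2L) stop("walktrap needs at least 2 nodes")
  if (!igraph::is_connected(network)) {
    stop("walktrap requires a connected network; split into components first")
  }
  wt <- igraph::cluster_walktrap(network, steps = t)
  mem <- igraph::membership(wt)
  blocks <- membership_to_blocks(as.integer(mem), nodes)
  list(partition = blocks, Q = network_modularity(network, blocks))
}

#' Degree-preserving randomization by edge switching
#'
#' Repeatedly picks two distinct edges `(u,v)`, `(x,y)` uniformly at random
#' and rewires them to `(u,y)`, `(x,v)`, rejecting any swap that would
#' create a self-loop or a multi-edge. The node set, edge count and the
#' degree of every node are preserved exactly, and the output is simple.
#' `n_swaps` counts successful (accepted) swaps; to guarantee termination on
#' rigid graphs where few or no swaps are admissible (e.g. a star, which is
#' always returned unchanged), attempts are capped at `50 * n_swaps`.
#'
#' Randomness is drawn from R's RNG stream, so results are reproducible with
#' [set.seed()].
#'
#' @param network A simple undirected igraph graph.
#' @param n_swaps Target number of successful swaps (>= 0).
#' @return A simple undirected igraph graph on the same nodes with the same
#'   degree sequence.
#' @export
edge_switch <- function(network, n_swaps) {
  if (n_swaps < 0) stop("n_swaps must be >= 0")
  nodes <- igraph::V(network)$name
  em <- igraph::as_edgelist(network, names = FALSE)
  if (n_swaps == 0 || nrow(em) < 2L) return(network)
  storage.mode(em) <- "integer"
  out <- edge_switch_cpp(em, length(nodes), as.double(n_swaps),
                         as.double(50) * as.double(n_swaps))
  g <- igraph::make_empty_graph(n = length(nodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = nodes)
  g <- igraph::add_edges(g, t(out))
  # conservation contract, asserted after every batch: same nodes, same
  # degree of every node, still simple
  stopifnot(igraph::is_simple(g),
            identical(igraph::degree(g), igraph::degree(network)))
  g
}
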