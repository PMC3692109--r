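#' Construct an ontology DAG
#'
#' A category hierarchy stored as child-to-parent edges, in the orientation
#' used by the Gene Ontology: following an edge moves from the more specific
#' category to the more general one. A node may have several parents; the
#' relation must be acyclic and self-edges are rejected.
#'
#' @param edges Two-column character matrix or data frame, columns
#'   `(child, parent)`. May have zero rows.
#' @param node_ids Optional additional isolated node ids.
#' @return An object of class `ontology_dag` with fields `edges` (character
#'   matrix, columns `child`, `parent`) and `node_ids`.
#' @export
ontology_dag <- function(edges = NULL, node_ids = character()) {
  if (is.null(edges) || NROW(edges) == 0L) {
    em <- matrix(character(), ncol = 2L, dimnames = list(NULL, c("child", "parent")))
  } else {
    em <- as.matrix(edges)
    if (ncol(em) != 2L) stop("edges must have two columns (child, parent)")
    storage.mode(em) <- "character"
    colnames(em) <- c("child", "parent")
    if (any(!nzchar(em))) stop("empty identifier in DAG edge")
    self <- em[, 1L] == em[, 2L]
    if (any(self)) {
      stop("self-edge in DAG: ", paste(unique(em[self, 1L]), collapse = ", "))
    }
    em <- unique(em)
  }
  nodes <- sort(unique(c(as.character(em), as.character(node_ids))))
  dag <- structure(list(edges = em, node_ids = nodes), class = "ontology_dag")
  cyc <- find_dag_cycle(dag)
  if (!is.null(cyc)) {
    stop("cycle in DAG: ", paste(cyc, collapse = " -> "))
  }
  dag
}

# returns one offending cycle (node ids, first repeated) or NULL
find_dag_cycle <- function(dag) {
  if (nrow(dag$edges) == 0L) return(NULL)
  g <- igraph::graph_from_edgelist(dag$edges, directed = TRUE)
  if (igraph::is_dag(g)) return(NULL)
  # locate a directed cycle: any strongly connected component of size > 1,
  # or a reciprocal pair
  comp <- igraph::components(g, mode = "strong")
  big <- which(comp$csize > 1L)[1L]
  members <- igraph::V(g)$name[comp$membership == big]
  sub <- igraph::induced_subgraph(g, members)
  # walk the component until a vertex repeats
  cur <- igraph::V(sub)$name[1L]
  path <- cur
  repeat {
    nxt <- igraph::neighbors(sub, cur, mode = "out")$name[1L]
    if (nxt %in% path) return(c(path[which(path == nxt):length(path)], nxt))
    path <- c(path, nxt)
    cur <- nxt
  }
}

#' @export
print.ontology_dag <- function(x, ...) {
  cat(sprintf("<ontology_dag> %d nodes, %d child->parent edges\n",
              length(x$node_ids), nrow(x$edges)))
  invisible(x)
}

#' Read a child/parent TSV into an ontology DAG
#'
#' Expects a headerless two-column tab-separated file, one
#' `child<TAB>parent` pair per line. Cycles and self-edges are rejected with
#' an informative error.
#'
#' @param path Path to the TSV file.
#' @return An [ontology_dag()].
#' @export
read_dag <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  if (length(lines) == 0L) return(ontology_dag())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 0L) != 2L)
  if (length(bad)) {
    stop(sprintf("DAG parse error at line %d of '%s': expected child<TAB>parent",
                 which(keep)[bad[1L]], path))
  }
  ontology_dag(do.call(rbind, parts))
}

#' Write an ontology DAG as child/parent TSV
#'
#' @param dag An [ontology_dag()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dag <- function(dag, path) {
  stopifnot(inherits(dag, "ontology_dag"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (nrow(dag$edges)) {
    writeLines(paste(dag$edges[, "child"], dag$edges[, "parent"], sep = "\t"),
               con, sep = "\n")
  }
  invisible(path)
}

#' Ancestor closure of a seed set
#'
#' Returns the seeds together with every node reachable from them by
#' repeatedly following child-to-parent edges (i.e. all their ancestors, up
#' to the DAG roots). The operation is idempotent and monotone in `seeds`.
#'
#' @param dag An [ontology_dag()].
#' @param seeds Character vector of node ids; must all be known to the DAG.
#' @return Sorted character vector of node ids.
#' @export
ancestor_closure <- function(dag, seeds) {
  stopifnot(inherits(dag, "ontology_dag"))
  seeds <- unique(as.character(seeds))
  if (length(seeds) == 0L) return(character())
  unknown <- setdiff(seeds, dag$node_ids)
  if (length(unknown)) {
    stop("unknown seed id(s): ", paste(unknown, collapse = ", "))
  }
  out <- seeds
  frontier <- seeds
  while (length(frontier)) {
    parents <- dag$edges[dag$edges[, "child"] %in% frontier, "parent"]
    frontier <- setdiff(unique(parents), out)
    out <- c(out, frontier)
  }
  sort(out)
}
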