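# Independent oracles used by the tests. These deliberately avoid the code
# paths they check: enumeration instead of phyper, explicit step-up/step-down
# formulas instead of p.adjust, restricted-growth-string enumeration of all
# partitions instead of walktrap, matrix reachability instead of the
# frontier-based closure.

# upper-tail hypergeometric by exhaustive enumeration of all C(N, n) draws:
# the category is taken to be the first m elements of 1..N
hyper_oracle <- function(k, n, m, N) {
  if (k == 0) return(1)
  draws <- utils::combn(N, n)
  mean(colSums(draws <= m) >= k)
}

# brute-force multiple-testing corrections from their defining formulas
padj_oracle <- function(p, method) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  out <- switch(method,
    bonferroni = pmin(1, p * n),
    holm = {
      q <- cummax(pmin(1, (n - seq_len(n) + 1) * ps))
      r <- numeric(n); r[o] <- q; r
    },
    hochberg = {
      q <- rev(cummin(rev(pmin(1, (n - seq_len(n) + 1) * ps))))
      r <- numeric(n); r[o] <- q; r
    },
    bh = {
      q <- rev(cummin(rev(pmin(1, n / seq_len(n) * ps))))
      r <- numeric(n); r[o] <- q; r
    },
    by = {
      cn <- sum(1 / seq_len(n))
      q <- rev(cummin(rev(pmin(1, cn * n / seq_len(n) * ps))))
      r <- numeric(n); r[o] <- q; r
    },
    stop("unknown method"))
  out
}

# exhaustive-search maximum modularity over ALL partitions of a small graph,
# via recursive enumeration of restricted growth strings
brute_max_modularity <- function(g) {
  n <- igraph::vcount(g)
  em <- igraph::as_edgelist(g, names = FALSE)
  deg <- igraph::degree(g)
  L <- nrow(em)
  best <- -Inf
  a <- integer(n)
  rec <- function(i, mx) {
    if (i > n) {
      mem <- a + 1L
      intra <- sum(mem[em[, 1L]] == mem[em[, 2L]])
      dsq <- sum(as.vector(rowsum(deg, mem))^2)
      q <- intra / L - dsq / (4 * L^2)
      if (q > best) best <<- q
      return(invisible(NULL))
    }
    for (v in 0:(mx + 1L)) {
      a[i] <<- v
      rec(i + 1L, max(mx, v))
    }
  }
  rec(1L, -1L)
  best
}

# random connected Erdos-Renyi graph with named vertices
random_connected_graph <- function(n, p) {
  repeat {
    g <- igraph::sample_gnp(n, p)
    if (igraph::is_connected(g) && igraph::ecount(g) >= 1L) break
  }
  igraph::set_vertex_attr(g, "name", value = sprintf("v%02d", seq_len(n)))
}

# random DAG as child->parent edges: nodes in a random topological order,
# edges only point from later (child) to earlier (parent)
random_dag_edges <- function(n, p = 0.1) {
  ids <- sprintf("t%02d", sample(n))
  e <- list()
  for (j in 2:n) {
    par <- which(stats::runif(j - 1) < p)
    for (i in par) e[[length(e) + 1L]] <- c(ids[j], ids[i])
  }
  if (length(e) == 0L) e[[1L]] <- c(ids[2L], ids[1L])
  do.call(rbind, e)
}

# ancestor closure by boolean matrix reachability (fixpoint of R <- R | R A)
closure_oracle <- function(edges, node_ids, seeds) {
  n <- length(node_ids)
  A <- matrix(FALSE, n, n, dimnames = list(node_ids, node_ids))
  if (NROW(edges)) A[cbind(edges[, 1L], edges[, 2L])] <- TRUE
  reach <- A
  repeat {
    nxt <- reach | ((reach %*% A) > 0)
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  out <- seeds
  for (s in seeds) out <- c(out, node_ids[reach[s, ]])
  sort(unique(out))
}

# canonical multiset of undirected edges, for byte-level graph comparison
edge_signature <- function(g) {
  em <- igraph::as_edgelist(g)
  if (nrow(em) == 0L) return(character())
  swap <- em[, 1L] > em[, 2L]
  em[swap, ] <- em[swap, 2:1]
  sort(paste(em[, 1L], em[, 2L], sep = "|"))
}

# minimal enrichment report wrapper for DAG construction tests
fake_report <- function(set_id, p_adj, cutoff = 0.05) {
  tab <- data.frame(set_id = set_id, name = "", k = 1L, n = 1L, m = 1L,
                    N = 2L, expected = 0.5, ratio = 2, p_raw = p_adj,
                    p_adj = p_adj, significant = as.integer(p_adj < cutoff),
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$p_raw, tab$set_id), , drop = FALSE]
  structure(list(table = tab,
                 params = enrichment_params(significance_cutoff = cutoff),
                 n = 1L, N = 2L),
            class = "enrichment_report")
}

# write lines to a temp file and return its path
tmp_lines <- function(lines, ext = ".tsv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
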