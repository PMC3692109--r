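#' Empirical significance of a network's modular organization
#'
#' Tests whether the best walktrap partition of a network scores a higher
#' modularity than expected for random networks with the same degree
#' sequence. For each of `n_random` replicates, the network is randomized by
#' degree-preserving edge switching (`10 * |edges|` successful swaps), the
#' best walktrap partition of the randomized network is found, and its
#' modularity recorded. The empirical p-value uses plus-one smoothing,
#' \eqn{p = (1 + \#\{Q_{null} \ge Q_{obs}\}) / (1 + n_{random})}, which is a
#' valid permutation-test estimator and can never be exactly 0.
#'
#' Replicate `b` is generated under seed `base_seed + b`, so results are
#' fully reproducible and individual replicates can be regenerated in
#' isolation.
#'
#' @param network A connected simple undirected igraph graph with at least
#'   `min_test_size` nodes.
#' @param n_random Number of null networks (default 1000).
#' @param base_seed Integer seed for the null ensemble.
#' @param t Walktrap walk length.
#' @param min_test_size Minimum network size worth testing (default 10).
#' @return An object of class `modularity_significance`: list with `Q_obs`,
#'   `Q_null` (numeric, length `n_random`), `p_value`, `n_random`, and the
#'   observed best `partition`.
#' @export
partition_significance <- function(network, n_random = 1000L, base_seed = 1L,
                                   t = 4L, min_test_size = 10L) {
  n <- igraph::vcount(network)
  if (n < min_test_size) {
    stop("network has ", n, " nodes; below min_test_size = ", min_test_size)
  }
  if (!igraph::is_connected(network)) {
    stop("network must be connected; decompose into components first")
  }
  obs <- walktrap_partition(network, t = t)
  n_random <- as.integer(n_random)
  q_null <- numeric(n_random)
  n_swaps <- 10L * igraph::ecount(network)
  for (b in seq_len(n_random)) {
    q_null[b] <- with_seed((base_seed + b) %% 2147483647, {
      rn <- edge_switch(network, n_swaps)
      # null networks may be disconnected; the dendrogram cut still yields
      # a best partition per component
      wt <- igraph::cluster_walktrap(rn, steps = t)
      igraph::modularity(rn, igraph::membership(wt))
    })
  }
  p <- (1 + sum(q_null >= obs$Q)) / (1 + n_random)
  structure(list(Q_obs = obs$Q, Q_null = q_null, p_value = p,
                 n_random = n_random, partition = obs$partition),
            class = "modularity_significance")
}

#' @export
print.modularity_significance <- function(x, ...) {
  cat(sprintf("<modularity_significance> Q_obs = %.4f vs %d degree-preserving nulls",
              x$Q_obs, x$n_random))
  if (x$n_random > 0) {
    cat(sprintf(" (null max %.4f)", max(x$Q_null)))
  }
  cat(sprintf("\n  empirical p = %.4g (%d blocks in best partition)\n",
              x$p_value, length(x$partition)))
  invisible(x)
}

#' Detect hierarchical network modules
#'
#' Recursive significance-tested decomposition of an interaction network.
#' At each tree node the induced subnetwork is examined:
#' \itemize{
#'   \item a disconnected subnetwork is first split into its connected
#'     components (children carry no significance record);
#'   \item a connected subnetwork with at least `min_test_size` nodes is
#'     tested with [partition_significance()]; if its modularity is
#'     significant (`p < alpha`) and the best partition has more than one
#'     block, the blocks become child modules and recursion continues into
#'     each of them;
#'   \item otherwise the node is a leaf. Components or blocks smaller than
#'     `min_leaf_size` become leaves and are flagged as small.
#' }
#' No multiplicity correction is applied across the recursion's tests; each
#' split is judged at the per-test level `alpha`. The procedure is fully
#' deterministic given `base_seed` (each significance test draws its null
#' ensemble from a seed derived from `base_seed` and a test counter).
#'
#' @param network A simple undirected igraph graph (non-empty).
#' @param alpha Per-split significance level (default 0.05).
#' @param n_random Null networks per significance test (default 1000).
#' @param min_test_size Smallest subnetwork subjected to the significance
#'   test (default 10).
#' @param min_leaf_size Blocks smaller than this become flagged leaves and
#'   are excluded from the exported gene-set collection (default 3).
#' @param base_seed Integer seed controlling all null ensembles.
#' @param t Walktrap walk length.
#' @return An object of class `module_tree`; see
#'   [module_tree_to_collection()] and [write_module_tree()] for exports.
#' @export
detect_hierarchical_modules <- function(network, alpha = 0.05, n_random = 1000L,
                                        min_test_size = 10L, min_leaf_size = 3L,
                                        base_seed = 1L, t = 4L) {
  if (igraph::vcount(network) == 0L) stop("network is empty")
  state <- new.env(parent = emptyenv())
  state$test_counter <- 0L
  state$depth_counter <- integer()   # per-depth module index

  next_index <- function(depth) {
    d <- as.character(depth)
    i <- (state$depth_counter[d] %||% NA)
    i <- if (is.na(i)) 1L else i + 1L
    state$depth_counter[d] <- i
    i
  }
  next_seed <- function() {
    s <- (as.double(base_seed) + 131071 * as.double(state$test_counter)) %% 2147483647
    state$test_counter <- state$test_counter + 1L
    as.integer(s)
  }

  build <- function(members, depth, kind) {
    members <- sort(members)
    idx <- next_index(depth)
    node <- list(module_id = sprintf("M_%d_%d", depth, idx),
                 depth = depth, index = idx, kind = kind,
                 members = members, small = length(members) < min_leaf_size,
                 split = NULL, children = list())
    if (node$small) return(node)
    sub <- igraph::induced_subgraph(network, members)
    if (!igraph::is_connected(sub)) {
      comp <- igraph::components(sub)
      blocks <- membership_to_blocks(comp$membership, igraph::V(sub)$name)
      node$children <- lapply(blocks, build, depth = depth + 1L, kind = "component")
      return(node)
    }
    if (length(members) < min_test_size) return(node)
    sig <- partition_significance(sub, n_random = n_random,
                                  base_seed = next_seed(), t = t,
                                  min_test_size = min_test_size)
    node$split <- sig
    if (sig$p_value < alpha && length(sig$partition) > 1L) {
      node$children <- lapply(sig$partition, build, depth = depth + 1L,
                              kind = "split")
    }
    node
  }

  root <- build(igraph::V(network)$name, 0L, "root")
  structure(list(root = root,
                 params = list(alpha = alpha, n_random = as.integer(n_random),
                               min_test_size = as.integer(min_test_size),
                               min_leaf_size = as.integer(min_leaf_size),
                               base_seed = as.integer(base_seed), t = as.integer(t))),
            class = "module_tree")
}

# preorder traversal; f(node) applied to each node
walk_module_tree <- function(node, f) {
  f(node)
  for (ch in node$children) walk_module_tree(ch, f)
  invisible(NULL)
}

#' Flatten a module tree to one row per module
#'
#' @param tree A `module_tree`.
#' @return Data frame with columns `module_id`, `depth`, `n_genes`, `kind`,
#'   `small`, `n_children`, `Q_obs`, `p_value` (NA when the node carries no
#'   significance record).
#' @export
module_tree_table <- function(tree) {
  stopifnot(inherits(tree, "module_tree"))
  rows <- list()
  walk_module_tree(tree$root, function(nd) {
    rows[[length(rows) + 1L]] <<- data.frame(
      module_id = nd$module_id, depth = nd$depth, n_genes = length(nd$members),
      kind = nd$kind, small = nd$small,
      n_children = length(nd$children),
      Q_obs = if (is.null(nd$split)) NA_real_ else nd$split$Q_obs,
      p_value = if (is.null(nd$split)) NA_real_ else nd$split$p_value,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.module_tree <- function(x, ...) {
  tab <- module_tree_table(x)
  cat(sprintf("<module_tree> %d modules, max depth %d, root of %d genes\n",
              nrow(tab), max(tab$depth), tab$n_genes[1L]))
  cat(sprintf("  alpha = %g, n_random = %d per test (%d tests run)\n",
              x$params$alpha, x$params$n_random, sum(!is.na(tab$p_value))))
  invisible(x)
}

#' @export
summary.module_tree <- function(object, ...) {
  tab <- module_tree_table(object)
  print(object)
  by_depth <- table(tab$depth)
  cat("  modules per depth: ",
      paste(sprintf("d%s:%d", names(by_depth), by_depth), collapse = "  "), "\n")
  invisible(tab)
}

#' Serialize a module tree to JSON
#'
#' Emits a deterministic nested JSON document (module_id, depth, members,
#' Q_obs, p_value, children), suitable for archiving or downstream tools.
#' Identical trees serialize to identical bytes.
#'
#' @param tree A `module_tree`.
#' @param path Optional output path; when `NULL` the JSON string is
#'   returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
write_module_tree <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "module_tree"))
  as_obj <- function(nd) {
    o <- list(module_id = nd$module_id, depth = nd$depth, kind = nd$kind,
              n_genes = length(nd$members), members = as.list(nd$members))
    if (!is.null(nd$split)) {
      o$Q_obs <- nd$split$Q_obs
      o$p_value <- nd$split$p_value
      o$n_random <- nd$split$n_random
    }
    o$children <- lapply(nd$children, as_obj)
    o
  }
  obj <- list(params = tree$params, root = as_obj(tree$root))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (is.null(path)) return(js)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(js, con, sep = "\n")
  invisible(js)
}

#' Export a module tree as gene sets plus a module hierarchy DAG
#'
#' Every module with at least `min_leaf_size` members (the tree's own
#' setting) becomes a gene set named `<prefix>_<depth>_<index>`; the root is
#' always included. The accompanying DAG holds one child-to-parent edge per
#' retained module pair, so enrichment results over the module sets can be
#' displayed in their hierarchical context.
#'
#' @param tree A `module_tree`.
#' @param prefix Prefix for module set ids (default `"MOD"`).
#' @return A list with `collection` (a [gene_set_collection()]) and `dag`
#'   (an [ontology_dag()]).
#' @export
module_tree_to_collection <- function(tree, prefix = "MOD") {
  stopifnot(inherits(tree, "module_tree"))
  min_leaf <- tree$params$min_leaf_size
  sets <- list()
  edges <- list()
  rec <- function(nd, parent_id) {
    keep <- nd$depth == 0L || length(nd$members) >= min_leaf
    sid <- NULL
    if (keep) {
      sid <- sprintf("%s_%d_%d", prefix, nd$depth, nd$index)
      sets[[length(sets) + 1L]] <<- gene_set(
        sid, sprintf("network module depth %d (%d genes)", nd$depth,
                     length(nd$members)),
        nd$members)
      if (!is.null(parent_id)) {
        edges[[length(edges) + 1L]] <<- c(sid, parent_id)
      }
    }
    for (ch in nd$children) rec(ch, if (keep) sid else parent_id)
  }
  rec(tree$root, NULL)
  list(collection = gene_set_collection(sets, source_label = prefix),
       dag = ontology_dag(if (length(edges)) do.call(rbind, edges)))
}

#' Fraction of modules enriched for at least one annotation category
#'
#' Functional-relevance check for detected modules: each module gene set is
#' tested with [run_ora()] against an annotation collection (e.g. GO terms)
#' using Benjamini-Hochberg correction, and counts as enriched when any
#' category reaches an adjusted p-value below the cutoff. Modules whose
#' genes fall outside the reference, or for which no category survives
#' filtering, count as not enriched.
#'
#' @param modules A [gene_set_collection()] of module gene sets.
#' @param annotation A [gene_set_collection()] of annotation categories over
#'   the same namespace.
#' @param reference Character vector: the reference gene universe.
#' @param params An [enrichment_params()]; the correction is forced to BH.
#' @return The enriched fraction, a number in \[0, 1\].
#' @export
fraction_enriched_modules <- function(modules, annotation, reference,
                                      params = enrichment_params()) {
  stopifnot(inherits(modules, "gene_set_collection"),
            inherits(annotation, "gene_set_collection"))
  if (length(modules$sets) == 0L) stop("module collection is empty")
  params$adjust_method <- "bh"
  enriched <- vapply(modules$sets, function(s) {
    rep <- tryCatch(
      suppressWarnings(run_ora(s$genes, reference, annotation, params)),
      error = function(e) NULL)
    !is.null(rep) && nrow(rep$table) > 0L &&
      any(rep$table$p_adj < params$significance_cutoff)
  }, TRUE)
  mean(enriched)
}

#' Transfer network edges through an ortholog map
#'
#' Infers interactions in a target organism from a curated source-organism
#' network: each source edge `(a, b)` yields every target pair `(a', b')`
#' with `(a, a')` and `(b, b')` in the ortholog table, excluding pairs that
#' would form self-loops. The result is simplified; combining it with any
#' curated target-organism edges is left to the caller.
#'
#' @param network Source-organism network (simple undirected igraph graph).
#' @param ortholog_pairs Two-column character matrix or data frame of
#'   `(source_gene, target_gene)` pairs; may be many-to-many.
#' @return A simple undirected igraph graph over target-organism genes.
#' @export
transfer_edges_by_orthology <- function(network, ortholog_pairs) {
  op <- as.matrix(ortholog_pairs)
  if (NROW(op) == 0L) return(as_network())
  storage.mode(op) <- "character"
  targets <- split(op[, 2L], op[, 1L])
  em <- igraph::as_edgelist(network)
  out <- list()
  for (i in seq_len(nrow(em))) {
    ta <- targets[[em[i, 1L]]]
    tb <- targets[[em[i, 2L]]]
    if (is.null(ta) || is.null(tb)) next
    grid <- expand.grid(a = ta, b = tb, stringsAsFactors = FALSE)
    grid <- grid[grid$a != grid$b, , drop = FALSE]
    if (nrow(grid)) out[[length(out) + 1L]] <- as.matrix(grid)
  }
  if (length(out) == 0L) return(as_network())
  as_network(do.call(rbind, out))
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two clusterings of the same items;
#' 1 for identical partitions, about 0 for independent ones.
#'
#' @param a,b Membership vectors over the same items (same length; if named,
#'   `b` is aligned to `a`'s names) or lists of blocks.
#' @return The adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  if (is.list(a)) a <- blocks_to_membership(a)
  if (is.list(b)) b <- blocks_to_membership(b)
  if (!is.null(names(a)) && !is.null(names(b))) {
    if (!setequal(names(a), names(b))) stop("partitions cover different items")
    b <- b[names(a)]
  }
  if (length(a) != length(b)) stop("memberships must have equal length")
  igraph::compare(as.integer(factor(a)), as.integer(factor(b)),
                  method = "adjusted.rand")
}

#' Per-depth memberships induced by a module tree
#'
#' For each tree depth `d >= 1`, assigns every root gene to the module of
#' depth `d` that contains it (genes whose module chain ended above `d` keep
#' their deepest module). Useful for comparing the recovered hierarchy with
#' a planted one level by level.
#'
#' @param tree A `module_tree`.
#' @param depth Level to extract (>= 1).
#' @return Named integer membership vector over the root's genes.
#' @export
tree_level_membership <- function(tree, depth) {
  stopifnot(inherits(tree, "module_tree"), depth >= 1L)
  mem <- integer()
  nodes <- character()
  idx <- 0L
  rec <- function(nd) {
    if (nd$depth == depth || length(nd$children) == 0L) {
      idx <<- idx + 1L
      mem <<- c(mem, rep(idx, length(nd$members)))
      nodes <<- c(nodes, nd$members)
      return(invisible(NULL))
    }
    for (ch in nd$children) rec(ch)
  }
  rec(tree$root)
  names(mem) <- nodes
  mem[sort(nodes)]
}
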