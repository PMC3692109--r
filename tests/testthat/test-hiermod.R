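test_that("partition significance separates modular from degenerate cases", {
  # two 8-cliques plus one bridge: strongly modular, no null should win
  cl <- function(p) t(utils::combn(paste0(p, 1:8), 2))
  net <- as_network(rbind(cl("A"), cl("B"), c("A1", "B1")))
  sig <- partition_significance(net, n_random = 99, base_seed = 5)
  expect_equal(sig$p_value, 1 / 100)
  expect_length(sig$Q_null, 99L)
  expect_true(all(sig$Q_null < sig$Q_obs))
  expect_identical(sig$partition, list(paste0("A", 1:8), paste0("B", 1:8)))

  # n_random = 0: the plus-one estimator gives exactly 1
  sig0 <- partition_significance(net, n_random = 0, base_seed = 5)
  expect_equal(sig0$p_value, 1)

  expect_error(partition_significance(net, min_test_size = 100), "min_test_size")
  expect_error(partition_significance(
    as_network(rbind(cl("A"), cl("B"))), n_random = 0), "connected")
})

test_that("partition significance is deterministic given its seed", {
  fx <- gen_planted_partition(2, 8, 0.9, 0.1, seed = 21)
  a <- partition_significance(fx$network, n_random = 29, base_seed = 77)
  b <- partition_significance(fx$network, n_random = 29, base_seed = 77)
  expect_identical(a, b)
})

test_that("hierarchical detection splits components and significant modules", {
  # two disjoint triangles: component children, both below min_test_size
  twotri <- as_network(rbind(c("a", "b"), c("b", "c"), c("a", "c"),
                             c("d", "e"), c("e", "f"), c("d", "f")))
  tree <- detect_hierarchical_modules(twotri, n_random = 19, base_seed = 1)
  tab <- module_tree_table(tree)
  expect_equal(nrow(tab), 3L)
  expect_identical(tab$kind, c("root", "component", "component"))
  expect_true(all(is.na(tab$p_value)))  # no significance test consumed

  # two 8-cliques + bridge: one significant split into the cliques
  cl <- function(p) t(utils::combn(paste0(p, 1:8), 2))
  net <- as_network(rbind(cl("A"), cl("B"), c("A1", "B1")))
  tree2 <- detect_hierarchical_modules(net, n_random = 99, base_seed = 2)
  tab2 <- module_tree_table(tree2)
  expect_equal(tab2$n_children[1L], 2L)
  expect_lt(tab2$p_value[1L], 0.05)
  # children are 8-clique blocks; below min_test_size, so they are leaves
  expect_true(all(tab2$n_children[-1L] == 0L))

  expect_error(detect_hierarchical_modules(as_network()), "empty")
})

test_that("module trees are fully deterministic given base_seed", {
  fx <- gen_two_level_network(2, 2, 8, 0.9, 0.15, 0.02, seed = 31)
  t1 <- detect_hierarchical_modules(fx$network, n_random = 29, base_seed = 9)
  t2 <- detect_hierarchical_modules(fx$network, n_random = 29, base_seed = 9)
  expect_identical(write_module_tree(t1), write_module_tree(t2))
})

test_that("tree children partition their parents and leaves tile the root", {
  fx <- gen_planted_partition(3, 8, 0.85, 0.05, seed = 41)
  tree <- detect_hierarchical_modules(fx$network, n_random = 49, base_seed = 3)
  check <- function(nd) {
    if (length(nd$children)) {
      kids <- unlist(lapply(nd$children, `[[`, "members"))
      expect_identical(sort(kids), nd$members)  # exact cover, no overlap
      for (ch in nd$children) check(ch)
    }
  }
  check(tree$root)
  leaves <- character()
  walk <- function(nd) {
    if (length(nd$children) == 0L) leaves <<- c(leaves, nd$members)
    for (ch in nd$children) walk(ch)
  }
  walk(tree$root)
  expect_identical(sort(leaves), tree$root$members)
})

test_that("module trees export to gene sets plus a parent DAG", {
  # root-only tree
  tri <- as_network(rbind(c("a", "b"), c("b", "c"), c("a", "c"),
                          c("a", "d"), c("d", "b")))
  t0 <- detect_hierarchical_modules(tri, n_random = 9, base_seed = 1)
  ex0 <- module_tree_to_collection(t0, prefix = "MOD")
  expect_length(ex0$collection, 1L)
  expect_equal(nrow(ex0$dag$edges), 0L)

  # split tree: one set per retained module, one edge per child
  cl <- function(p) t(utils::combn(paste0(p, 1:8), 2))
  net <- as_network(rbind(cl("A"), cl("B"), c("A1", "B1")))
  t1 <- detect_hierarchical_modules(net, n_random = 99, base_seed = 2)
  ex1 <- module_tree_to_collection(t1, prefix = "HM")
  expect_identical(set_ids(ex1$collection), c("HM_0_1", "HM_1_1", "HM_1_2"))
  expect_equal(nrow(ex1$dag$edges), 2L)
  expect_true(all(ex1$dag$edges[, "parent"] == "HM_0_1"))
  # every child set is a subset of its parent set
  for (i in seq_len(nrow(ex1$dag$edges))) {
    ch <- ex1$collection$sets[[ex1$dag$edges[i, "child"]]]$genes
    pa <- ex1$collection$sets[[ex1$dag$edges[i, "parent"]]]$genes
    expect_true(all(ch %in% pa))
  }
})

test_that("fraction of GO-enriched modules reflects constructed truth", {
  genes <- sprintf("g%03d", 1:120)
  annot <- gene_set_collection(lapply(0:5, function(i) {
    gene_set(sprintf("GO%02d", i), "", genes[(i * 20 + 1):(i * 20 + 20)])
  }))
  # modules identical to annotation sets: every module self-enriches
  expect_equal(fraction_enriched_modules(annot, annot, genes), 1)

  # modules drawn without regard to annotation blocks: none enriched
  set.seed(451)
  noise <- gene_set_collection(lapply(1:6, function(i) {
    gene_set(sprintf("N%02d", i), "", sample(genes, 20))
  }))
  expect_lte(fraction_enriched_modules(noise, annot, genes), 0.2)

  # half the modules spiked from annotation sets
  half <- gene_set_collection(c(annot$sets[1:3], noise$sets[4:6]))
  fr <- fraction_enriched_modules(half, annot, genes)
  expect_gte(fr, 0.5)
  expect_lte(fr, 0.7)

  # modules of genes absent from every annotation set
  outside <- gene_set_collection(list(gene_set("OUT", "", sprintf("x%d", 1:10))))
  expect_equal(fraction_enriched_modules(outside, annot, genes), 0)

  expect_error(fraction_enriched_modules(gene_set_collection(), annot, genes),
               "empty")
})

test_that("ortholog transfer expands edges across the mapping", {
  net <- as_network(rbind(c("a", "b")))
  out1 <- transfer_edges_by_orthology(net, rbind(c("a", "x"), c("b", "y")))
  expect_identical(edge_signature(out1), "x|y")

  # both endpoints mapping to the same target would be a self-loop
  out2 <- transfer_edges_by_orthology(net, rbind(c("a", "x"), c("b", "x")))
  expect_equal(igraph::ecount(out2), 0L)

  # one-to-many source expands to the cross product
  out3 <- transfer_edges_by_orthology(
    net, rbind(c("a", "x"), c("a", "z"), c("b", "y")))
  expect_identical(edge_signature(out3), c("x|y", "y|z"))

  # unmapped endpoints contribute nothing
  out4 <- transfer_edges_by_orthology(net, rbind(c("a", "x")))
  expect_equal(igraph::ecount(out4), 0L)
})

test_that("tree level membership cuts the hierarchy at a given depth", {
  cl <- function(p) t(utils::combn(paste0(p, 1:8), 2))
  net <- as_network(rbind(cl("A"), cl("B"), c("A1", "B1")))
  tree <- detect_hierarchical_modules(net, n_random = 99, base_seed = 2)
  mem <- tree_level_membership(tree, 1L)
  expect_length(mem, 16L)
  expect_equal(length(unique(mem)), 2L)
  expect_equal(adjusted_rand_index(
    mem, structure(rep(1:2, each = 8),
                   names = c(paste0("A", 1:8), paste0("B", 1:8)))), 1)
})
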