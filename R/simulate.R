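#' Generate a planted-partition network
#'
#' Ground-truth benchmark for community recovery: nodes are divided into
#' `n_groups` groups of `group_size`; each intra-group pair is an edge with
#' probability `p_in`, each inter-group pair with probability `p_out`,
#' independently. With `p_in = p_out` this reduces to an Erdos-Renyi graph
#' and the planted blocks carry no signal. Node names are
#' `g<group>_n<index>`. Deterministic per seed.
#'
#' @param n_groups Number of planted groups.
#' @param group_size Nodes per group (>= 2).
#' @param p_in,p_out Intra-/inter-group edge probabilities,
#'   `0 <= p_out <= p_in <= 1`.
#' @param seed Integer seed.
#' @return A list of class `planted_network` with `network` (igraph graph),
#'   `planted_blocks` (list of node-name blocks) and `params`.
#' @export
gen_planted_partition <- function(n_groups, group_size, p_in, p_out, seed = 1L) {
  if (group_size < 2L) stop("group_size must be >= 2")
  if (!(p_out >= 0 && p_out <= p_in && p_in <= 1)) {
    stop("need 0 <= p_out <= p_in <= 1")
  }
  n <- n_groups * group_size
  grp <- rep(seq_len(n_groups), each = group_size)
  nm <- sprintf("g%d_n%02d", grp, sequence(rep(group_size, n_groups)))
  net <- with_seed(seed, {
    pr <- t(utils::combn(n, 2L))
    p <- ifelse(grp[pr[, 1L]] == grp[pr[, 2L]], p_in, p_out)
    keep <- runif(nrow(pr)) < p
    as_network(cbind(nm[pr[keep, 1L]], nm[pr[keep, 2L]]), nodes = nm)
  })
  structure(list(network = net,
                 planted_blocks = membership_to_blocks(grp, nm),
                 params = list(n_groups = n_groups, group_size = group_size,
                               p_in = p_in, p_out = p_out, seed = seed)),
            class = "planted_network")
}

#' Generate a two-level hierarchical benchmark network
#'
#' Nodes form `n_super` super-modules, each containing `groups_per_super`
#' fine groups of `group_size` nodes. Edge probabilities are `p1` within a
#' group, `p2` between groups of the same super-module and `p3` across
#' super-modules, with `p1 > p2 > p3` (equalities collapse the construction
#' to the single-level [gen_planted_partition()] semantics and are allowed
#' when `p2 == p3`). Node names are `s<super>g<group>_n<index>`.
#'
#' @param n_super Number of super-modules.
#' @param groups_per_super Fine groups per super-module.
#' @param group_size Nodes per fine group (>= 2).
#' @param p1,p2,p3 Edge probabilities, `p1 > p2 >= p3` (all in \[0, 1\]).
#' @param seed Integer seed.
#' @return A list of class `planted_network` with `network`,
#'   `planted_blocks` (fine groups), `planted_super` (super-modules) and
#'   `params`.
#' @export
gen_two_level_network <- function(n_super, groups_per_super, group_size,
                                  p1, p2, p3, seed = 1L) {
  if (group_size < 2L) stop("group_size must be >= 2")
  if (!(p1 > p2 && p2 >= p3 && p3 >= 0 && p1 <= 1)) {
    stop("need 1 >= p1 > p2 >= p3 >= 0")
  }
  n <- n_super * groups_per_super * group_size
  super <- rep(seq_len(n_super), each = groups_per_super * group_size)
  grp <- rep(seq_len(n_super * groups_per_super), each = group_size)
  nm <- sprintf("s%dg%d_n%02d", super, grp,
                sequence(rep(group_size, n_super * groups_per_super)))
  net <- with_seed(seed, {
    pr <- t(utils::combn(n, 2L))
    same_g <- grp[pr[, 1L]] == grp[pr[, 2L]]
    same_s <- super[pr[, 1L]] == super[pr[, 2L]]
    p <- ifelse(same_g, p1, ifelse(same_s, p2, p3))
    keep <- runif(nrow(pr)) < p
    as_network(cbind(nm[pr[keep, 1L]], nm[pr[keep, 2L]]), nodes = nm)
  })
  structure(list(network = net,
                 planted_blocks = membership_to_blocks(grp, nm),
                 planted_super = membership_to_blocks(super, nm),
                 params = list(n_super = n_super,
                               groups_per_super = groups_per_super,
                               group_size = group_size,
                               p1 = p1, p2 = p2, p3 = p3, seed = seed)),
            class = "planted_network")
}

#' @export
print.planted_network <- function(x, ...) {
  cat(sprintf("<planted_network> %d nodes, %d edges, %d planted blocks\n",
              igraph::vcount(x$network), igraph::ecount(x$network),
              length(x$planted_blocks)))
  invisible(x)
}

#' Generate a spiked ORA fixture
#'
#' Builds a gene universe of size `N`, a collection of `n_sets` background
#' sets drawn uniformly from the universe, an input list, and one spiked set
#' forced to share `spike_overlap` genes with the input list. With
#' `spike_overlap` well above the expected overlap
#' `input_size * set_size / N`, the spiked set has planted enrichment and
#' should rank first in [run_ora()]; at the expected overlap it is
#' indistinguishable from background.
#'
#' @param N Universe size.
#' @param n_sets Number of gene sets (the last one is spiked).
#' @param set_size Genes per set.
#' @param input_size Genes in the input list.
#' @param spike_overlap Forced overlap between the spiked set and the input
#'   list, `<= min(set_size, input_size)`.
#' @param seed Integer seed.
#' @return A list of class `spiked_ora_fixture` with `reference`,
#'   `input_list`, `collection`, `spiked_set_id` and `params`.
#' @export
gen_spiked_ora_fixture <- function(N = 1000L, n_sets = 50L, set_size = 20L,
                                   input_size = 50L, spike_overlap = 15L,
                                   seed = 1L) {
  if (spike_overlap > min(set_size, input_size)) {
    stop("spike_overlap must not exceed min(set_size, input_size)")
  }
  if (max(set_size, input_size) > N) stop("set_size and input_size must be <= N")
  universe <- sprintf("gene%04d", seq_len(N))
  with_seed(seed, {
    input <- sort(sample(universe, input_size))
    sets <- lapply(seq_len(n_sets - 1L), function(i) {
      gene_set(sprintf("BG%03d", i), "background set",
               sample(universe, set_size))
    })
    spiked <- c(sample(input, spike_overlap),
                sample(setdiff(universe, input), set_size - spike_overlap))
    sets[[n_sets]] <- gene_set("SPIKE", "spiked set", spiked)
    structure(list(reference = universe,
                   input_list = input,
                   collection = gene_set_collection(sets, "spiked fixture"),
                   spiked_set_id = "SPIKE",
                   params = list(N = N, n_sets = n_sets, set_size = set_size,
                                 input_size = input_size,
                                 spike_overlap = spike_overlap, seed = seed)),
              class = "spiked_ora_fixture")
  })
}

#' @export
print.spiked_ora_fixture <- function(x, ...) {
  cat(sprintf("<spiked_ora_fixture> universe %d, %d sets of %d, input %d, spike overlap %d\n",
              x$params$N, x$params$n_sets, x$params$set_size,
              x$params$input_size, x$params$spike_overlap))
  invisible(x)
}
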