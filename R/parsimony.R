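# Wagner parsimony (linear-cost Sankoff) scoring and tree search.

# States of a character_matrix aligned to a tree's tip order, as a 0-based
# integer matrix suitable for the C++ kernel.
tip_states <- function(tree, m) {
  if (is.null(tree$tip.label)) stop("tree has no tip labels")
  states <- m$states
  miss <- setdiff(tree$tip.label, rownames(states))
  if (length(miss))
    stop("tree leaves absent from the character matrix: ",
         paste(miss, collapse = ", "))
  states[tree$tip.label, , drop = FALSE]
}

postorder_edges <- function(tree) {
  tree <- ape::reorder.phylo(tree, "postorder")
  tree$edge
}

#' Wagner parsimony length of a tree
#'
#' Total number of state changes over all characters, minimised over internal
#' node states by Sankoff dynamic programming with the linear cost
#' `c(i, j) = |i - j|` appropriate for linearly ordered, undirected
#' (Wagner) characters. The score is a property of the unrooted topology:
#' the arbitrary rooting used for the dynamic program does not affect it.
#'
#' @param tree A `phylo` tree (rooted or unrooted) whose tips are rows of `m`.
#' @param m A `character_matrix` (see [encode_census()]), or any list with an
#'   integer `states` matrix and state count `S`.
#' @return Total parsimony length (numeric count of state changes).
#' @export
#' @examples
#' tr <- ape::read.tree(text = "((t1,t2),(t3,t4));")
#' m <- list(states = matrix(c(3L, 7L, 5L, 5L), 4, 1,
#'                           dimnames = list(paste0("t", 1:4), "f1")),
#'           S = 24L)
#' sankoff_length(tr, m)  # 4
sankoff_length <- function(tree, m) {
  states <- tip_states(tree, m)
  edge <- postorder_edges(tree)
  .sankoff_score_cpp(edge, length(tree$tip.label),
                     length(tree$tip.label) + tree$Nnode, states, m$S)
}

# Parsimony cost of attaching a hypothetical ancestor tip to each edge of the
# (arbitrarily rooted) tree; returns costs in the postorder edge order along
# with that edge matrix.
ancestor_edge_costs <- function(tree, m, anc_states) {
  states <- tip_states(tree, m)
  edge <- postorder_edges(tree)
  costs <- .sankoff_edge_costs_cpp(edge, length(tree$tip.label),
                                   length(tree$tip.label) + tree$Nnode,
                                   states, m$S, as.integer(anc_states))
  list(edge = edge, costs = costs)
}

# all unrooted binary topologies on the given labels, by recursive stepwise
# addition of each leaf to every edge (newick-based construction)
enumerate_topologies <- function(labels) {
  stopifnot(length(labels) >= 3)
  base <- sprintf("(%s,%s,%s);", labels[1], labels[2], labels[3])
  trees <- list(ape::read.tree(text = base))
  for (k in seq_along(labels)[-(1:3)]) {
    tip <- list(edge = matrix(c(2L, 1L), 1, 2), tip.label = labels[k],
                edge.length = 1, Nnode = 1L)
    class(tip) <- "phylo"
    nxt <- list()
    for (tr in trees) {
      tr$edge.length <- rep(1, nrow(tr$edge))
      for (e in seq_len(nrow(tr$edge))) {
        cand <- ape::bind.tree(tr, tip, where = tr$edge[e, 2], position = 0.5)
        nxt[[length(nxt) + 1L]] <- cand
      }
    }
    trees <- nxt
  }
  trees
}

#' Exhaustive maximum-parsimony search (small-instance oracle)
#'
#' Enumerates every unrooted binary topology over the matrix rows (3, 15,
#' 105, ... , 135135 topologies for 4..9 leaves) and scores each with
#' [sankoff_length()]. Intended as the exact reference for the heuristic
#' search on small instances.
#'
#' @param m A `character_matrix`.
#' @param max_leaves Refuse matrices larger than this (default 9).
#' @return List with `trees` (all optimal topologies), `length` (their
#'   parsimony length) and `n_scored`.
#' @export
exhaustive_search <- function(m, max_leaves = 9) {
  labels <- rownames(m$states)
  if (length(labels) > max_leaves)
    stop("exhaustive search limited to ", max_leaves, " leaves")
  trees <- enumerate_topologies(labels)
  lens <- vapply(trees, sankoff_length, 0, m = m)
  best <- min(lens)
  list(trees = trees[lens == best], length = best, n_scored = length(trees))
}

# greedy random-addition starting tree: leaves joined in random order, each
# placed on the edge that minimises the Wagner length
random_addition_tree <- function(m, order = NULL) {
  labels <- rownames(m$states)
  # canonical label order first: the seeded search then depends only on the
  # set of taxa, not on the row order of the input matrix
  ord <- order %||% sample(sort(labels))
  tr <- ape::read.tree(text = sprintf("(%s,%s,%s);", ord[1], ord[2], ord[3]))
  tr$edge.length <- rep(1, nrow(tr$edge))
  for (lab in ord[-(1:3)]) {
    tip <- list(edge = matrix(c(2L, 1L), 1, 2), tip.label = lab,
                edge.length = 1, Nnode = 1L)
    class(tip) <- "phylo"
    cands <- lapply(seq_len(nrow(tr$edge)), function(e)
      ape::bind.tree(tr, tip, where = tr$edge[e, 2], position = 0.5))
    lens <- vapply(cands, sankoff_length, 0, m = m)
    tr <- cands[[which.min(lens)]]
    tr$edge.length <- rep(1, nrow(tr$edge))
  }
  tr
}

#' Heuristic maximum-parsimony search (random addition + NNI)
#'
#' Hill-climbing over nearest-neighbor-interchange rearrangements from greedy
#' random-addition starting trees, the classic heuristic for Wagner parsimony
#' on ordered multistate characters. Neighbor enumeration is deterministic
#' and the first improving rearrangement is accepted; restarts differ only in
#' the seeded random addition order, so results are reproducible under
#' `seed`.
#'
#' @param m A `character_matrix` with >= 4 rows.
#' @param n_starts Number of random-addition restarts (default 3).
#' @param seed Integer seed controlling the addition orders.
#' @return List with `tree` (best unrooted topology found), `length`, and
#'   `start_lengths` (length reached from each restart).
#' @export
nni_search <- function(m, n_starts = 3, seed = 1) {
  labels <- rownames(m$states)
  if (length(labels) < 4) stop("heuristic search needs >= 4 leaves")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  best <- NULL
  best_len <- Inf
  reached <- numeric(n_starts)
  for (s in seq_len(n_starts)) {
    tr <- random_addition_tree(m)
    len <- sankoff_length(tr, m)
    repeat {
      nbs <- phangorn::nni(tr)
      improved <- FALSE
      for (k in seq_along(nbs)) {
        nb <- nbs[[k]]  # [[ restores tip labels on compressed multiPhylo
        l2 <- sankoff_length(nb, m)
        if (l2 < len) {
          tr <- nb
          len <- l2
          improved <- TRUE
          break  # first improvement
        }
      }
      if (!improved) break
    }
    reached[s] <- len
    if (len < best_len) {
      best <- tr
      best_len <- len
    }
  }
  list(tree = best, length = best_len, start_lengths = reached)
}
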