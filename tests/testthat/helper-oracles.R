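# Independent oracles and small fixture builders shared across tests.

# Brute-force Wagner parsimony length: enumerate every assignment of internal
# node states and sum |state change| over edges. Exponential; <= 6 leaves.
brute_force_length <- function(tree, states, S) {
  tree <- ape::reorder.phylo(ape::unroot(tree), "postorder")
  n <- length(tree$tip.label)
  ni <- tree$Nnode
  total <- 0
  for (ch in seq_len(ncol(states))) {
    s <- states[tree$tip.label, ch]
    grid <- as.matrix(expand.grid(rep(list(0:(S - 1)), ni)))
    cost <- 0
    for (e in seq_len(nrow(tree$edge))) {
      a <- tree$edge[e, 1]
      b <- tree$edge[e, 2]
      va <- grid[, a - n]
      vb <- if (b <= n) rep(s[b], nrow(grid)) else grid[, b - n]
      cost <- cost + abs(va - vb)
    }
    total <- total + min(cost)
  }
  total
}

# single-tip phylo usable with ape::bind.tree
single_tip <- function(lab) {
  y <- list(edge = matrix(c(2L, 1L), 1, 2), tip.label = lab,
            edge.length = 1, Nnode = 1L)
  class(y) <- "phylo"
  y
}

# Explicit Lundberg oracle: attach the ancestor tip to every postorder edge
# with ape::bind.tree and score the enlarged tree.
explicit_attachment_costs <- function(tree, m, anc_states) {
  tp <- ape::reorder.phylo(tree, "postorder")
  tp$edge.length <- rep(1, nrow(tp$edge))
  m2 <- list(states = rbind(m$states,
                            ANC = as.integer(anc_states))[
                              c(rownames(m$states), "ANC"), , drop = FALSE],
             S = m$S)
  rownames(m2$states)[nrow(m2$states)] <- "ANC"
  vapply(seq_len(nrow(tp$edge)), function(e) {
    t2 <- ape::bind.tree(tp, single_tip("ANC"), where = tp$edge[e, 2],
                         position = 0.5)
    sankoff_length(t2, m2)
  }, 0)
}

random_character_matrix <- function(n_leaves, n_char, S = 24) {
  states <- matrix(sample(0:(S - 1), n_leaves * n_char, replace = TRUE),
                   n_leaves, n_char,
                   dimnames = list(paste0("t", seq_len(n_leaves)),
                                   paste0("c", seq_len(n_char))))
  structure(list(states = states, S = as.integer(S)),
            class = "character_matrix")
}

# chronology object built directly from planted birth times (nd = scaled rank)
chronology_from_truth <- function(truth) {
  bt <- sort(truth$birth_time)
  nd <- (rank(bt) - 1) / (length(bt) - 1)
  tab <- data.frame(family = names(bt), nd = unname(nd),
                    age_gya = 3.8 - 3.8 * unname(nd))
  structure(list(table = tab, tree = NULL, clock = c(a = 3.8, b = -3.8)),
            class = "chronology")
}

# additive distance matrix of the quartet tree ((a,b),(c,d)) with unit branches
quartet_tree_metric <- function() {
  d <- matrix(c(0, 2, 3, 3,
                2, 0, 3, 3,
                3, 3, 0, 2,
                3, 3, 2, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  d
}

# unit 4-cycle shortest-path metric (maximally box-like quartet)
four_cycle_metric <- function() {
  d <- matrix(c(0, 1, 2, 1,
                1, 0, 1, 2,
                2, 1, 0, 1,
                1, 2, 1, 0), 4, 4,
              dimnames = list(paste0("x", 1:4), paste0("x", 1:4)))
  d
}

# rigid motion: random rotation (QR of a Gaussian matrix) plus translation
random_rigid_motion <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  list(R = q, t = rnorm(3, sd = 10))
}

apply_motion <- function(loop, mo) {
  f <- function(x) sweep(x %*% t(mo$R), 2, mo$t, `+`)
  loop_structure(f(loop$ss1), if (nrow(loop$loop)) f(loop$loop) else loop$loop,
                 f(loop$ss2), loop$ss1_type, loop$ss2_type, loop$adjacent)
}
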