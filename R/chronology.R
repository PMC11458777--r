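# Lundberg rooting, node distances, molecular-clock calibration.

# Rooted tree obtained by placing the root on edge (u, v) of an unrooted
# tree: newick is rebuilt recursively from the adjacency list so node
# numbering stays canonical. Branch lengths are discarded (the chronology
# uses node counts only).
root_at_edge <- function(tree, u, v) {
  n_tip <- length(tree$tip.label)
  adj <- vector("list", n_tip + tree$Nnode)
  for (e in seq_len(nrow(tree$edge))) {
    a <- tree$edge[e, 1]; b <- tree$edge[e, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  subnwk <- function(node, parent) {
    if (node <= n_tip) return(tree$tip.label[node])
    kids <- setdiff(adj[[node]], parent)
    paste0("(", paste(vapply(kids, subnwk, "", parent = node),
                      collapse = ","), ")")
  }
  nwk <- paste0("(", subnwk(u, v), ",", subnwk(v, u), ");")
  ape::read.tree(text = nwk)
}

#' Root a tree by Lundberg ancestor attachment
#'
#' Attaches a hypothetical ancestor with a fixed character-state vector to
#' every branch of the unrooted tree in turn and roots the tree at the
#' attachment point that minimises the total Wagner parsimony length. The
#' default `"max"` ancestor (all states `S - 1`) encodes the generality
#' criterion of genomic-abundance phylogenies: the oldest families are the
#' most abundant and widespread, so evolution proceeds away from the
#' maximum-abundance state. Ties are broken by the first branch in the
#' deterministic postorder edge enumeration and reported.
#'
#' @param tree Unrooted `phylo` tree over the matrix rows.
#' @param m A `character_matrix`.
#' @param ancestor `"max"`, `"min"`, or an explicit integer state vector of
#'   length `ncol(m$states)`.
#' @return List with `tree` (rooted `phylo`, no ancestor leaf retained),
#'   `edge_costs` (attachment cost per postorder branch), `length` (optimal
#'   attached length) and `tie` (TRUE when several branches are optimal).
#' @export
lundberg_root <- function(tree, m, ancestor = "max") {
  nchar_ <- ncol(m$states)
  anc <- if (is.character(ancestor)) {
    switch(match.arg(ancestor, c("max", "min")),
           max = rep(m$S - 1L, nchar_),
           min = rep(0L, nchar_))
  } else {
    if (length(ancestor) != nchar_) stop("explicit ancestor has wrong length")
    as.integer(ancestor)
  }
  if (any(anc < 0 | anc >= m$S)) stop("ancestor states out of range")
  ec <- ancestor_edge_costs(tree, m, anc)
  best <- which(ec$costs <= min(ec$costs) + 1e-9)
  pick <- best[1]
  rooted <- root_at_edge(tree, ec$edge[pick, 1], ec$edge[pick, 2])
  list(tree = rooted, edge_costs = ec$costs, length = ec$costs[pick],
       edge = ec$edge[pick, ], tie = length(best) > 1)
}

#' Node distances from the root
#'
#' The relative age of each leaf of a rooted tree of domains: the number of
#' internal nodes `d` on the root-to-leaf path (root included), rescaled to
#' the unit interval. `nd = 0` marks the oldest leaves, `nd = 1` the
#' youngest. With the default `"root"` scaling `nd = (d - 1) / (d_max - 1)`
#' (so a leaf hanging directly off the root has nd 0); the `"min"` scaling
#' `(d - d_min) / (d_max - d_min)` is available for sensitivity analysis.
#' Degenerate trees where all leaves are equidistant get `nd = 0`.
#'
#' @param rooted A rooted `phylo` tree.
#' @param scaling `"root"` (default) or `"min"`.
#' @return Named numeric vector of `nd` values in `[0, 1]`, one per leaf.
#' @export
#' @examples
#' node_distances(ape::read.tree(text = "(((t4,t3),t2),t1);"))
node_distances <- function(rooted, scaling = c("root", "min")) {
  scaling <- match.arg(scaling)
  if (!ape::is.rooted(rooted)) stop("a rooted tree is required")
  n_tip <- length(rooted$tip.label)
  depth <- integer(n_tip + rooted$Nnode)
  root <- n_tip + 1L
  depth[root] <- 1L
  edge <- ape::reorder.phylo(rooted, "postorder")$edge
  for (e in rev(seq_len(nrow(edge)))) {  # preorder
    p <- edge[e, 1]; c <- edge[e, 2]
    depth[c] <- depth[p] + as.integer(c > n_tip)
  }
  d <- depth[seq_len(n_tip)]
  lo <- if (scaling == "root") 1L else min(d)
  nd <- if (max(d) == lo) rep(0, n_tip) else (d - lo) / (max(d) - lo)
  setNames(nd, rooted$tip.label)
}

#' Calibrate a molecular clock on node distances
#'
#' Fits the least-squares line `age = a + b * nd` through calibration
#' anchors, pairs of (node distance, age in Gya) tied to biomarker and
#' geomarker evidence. The default anchors place the origin of the domain
#' chronology at 3.8 Gya (`nd = 0`) and the present at `nd = 1`, giving
#' `age = 3.8 - 3.8 nd`. Calibrated ages below zero are clipped to 0 with a
#' warning.
#'
#' @param nd Numeric vector of node distances (named by family).
#' @param anchors Data frame with columns `nd` and `gya`, >= 2 rows with
#'   distinct `nd`.
#' @return List with `a` (intercept, Gya), `b` (slope, Gya per nd unit) and
#'   `age` (named vector of calibrated ages).
#' @export
#' @examples
#' calibrate_clock(c(f1 = 0, f2 = 0.5, f3 = 1))$age
calibrate_clock <- function(nd, anchors = default_clock_anchors()) {
  if (nrow(anchors) < 2 || length(unique(anchors$nd)) < 2)
    stop("need >= 2 anchors with distinct nd")
  fit <- lm(gya ~ nd, data = anchors)
  a <- unname(coef(fit)[1]); b <- unname(coef(fit)[2])
  age <- a + b * nd
  if (any(age < -1e-9)) {
    warning("negative calibrated ages clipped to 0")
    age <- pmax(age, 0)
  }
  list(a = a, b = b, age = age)
}

#' @rdname calibrate_clock
#' @export
default_clock_anchors <- function() data.frame(nd = c(0, 1), gya = c(3.8, 0))

#' Build a chronology of domain families
#'
#' End-to-end inference: heuristic maximum-parsimony search on the ordered
#' character matrix ([nni_search()]), Lundberg rooting with a hypothetical
#' ancestor ([lundberg_root()]), node distances ([node_distances()]) and
#' clock calibration ([calibrate_clock()]). Families are returned sorted by
#' increasing `nd` (oldest first), ties in stable family-ID order.
#'
#' @inheritParams nni_search
#' @inheritParams lundberg_root
#' @inheritParams node_distances
#' @param anchors Clock anchors, see [calibrate_clock()].
#' @return An object of class `chronology`: list with `table` (data frame
#'   `family`, `nd`, `age_gya`), `tree` (rooted `phylo`), `clock` (`a`, `b`),
#'   `length` (parsimony length) and `tie` flag from rooting.
#' @details The encoded census has proteomes in rows and families in
#'   columns; the tree *of domains* takes the families as taxa and the
#'   proteomes as characters, so the state matrix is transposed before the
#'   search. The `"max"` ancestor then reads "abundant in every proteome",
#'   the generality criterion that polarises the chronology.
#' @export
build_chronology <- function(m, n_starts = 3, seed = 1, ancestor = "max",
                             scaling = "root",
                             anchors = default_clock_anchors()) {
  m <- structure(list(states = t(m$states), S = m$S, scope = m$scope),
                 class = "character_matrix")
  fit <- nni_search(m, n_starts = n_starts, seed = seed)
  rooted <- lundberg_root(fit$tree, m, ancestor = ancestor)
  nd <- node_distances(rooted$tree, scaling = scaling)
  clock <- calibrate_clock(nd, anchors)
  tab <- data.frame(family = names(nd), nd = unname(nd),
                    age_gya = unname(clock$age))
  tab <- tab[order(tab$nd, tab$family), ]
  rownames(tab) <- NULL
  structure(list(table = tab, tree = rooted$tree,
                 clock = c(a = clock$a, b = clock$b),
                 length = fit$length, tie = rooted$tie),
            class = "chronology")
}

#' @export
print.chronology <- function(x, ...) {
  cat("Chronology of", nrow(x$table), "domain families;",
      "parsimony length", x$length, "\n")
  cat(sprintf("Clock: age = %.3f %+.3f nd (Gya)\n",
              x$clock["a"], x$clock["b"]))
  print(head(x$table, 5))
  if (nrow(x$table) > 5) cat("...\n")
  invisible(x)
}

#' Write a chronology table as TSV (family, nd, age_Gya)
#'
#' @param chron A [build_chronology()] result.
#' @param path Output path.
#' @export
write_chronology <- function(chron, path) {
  write.table(chron$table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_chronology
#' @export
read_chronology <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  structure(list(table = tab, tree = NULL, clock = NULL), class = "chronology")
}
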