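# Vertical vs reticulate signal among the network taxa: weighted
# uncorrected-P distances, quartet delta scores, Q-residuals, NJ, bootstrap.

#' Venn-weighted binary character matrix of the network taxa
#'
#' Rows are the network taxa — the four supergroups plus a hypothetical
#' all-absent ancestor `ANC` used to polarise the network — and the 15
#' columns are the Venn groups; a cell is 1 when the taxon letter belongs to
#' the column's label. Column weights are the item counts (prototypes or
#' families) observed in each Venn group.
#'
#' @param weights Named non-negative numeric vector; names must be Venn
#'   labels (missing labels get weight 0).
#' @param anc `"absent"` (default, all-0 ancestor row), `"present"` (all-1)
#'   or `"none"` (4 taxa only).
#' @return A `group_character_matrix`: list with binary `x` (taxa x 15),
#'   `weights` (length 15).
#' @export
#' @examples
#' w <- c(ABEV = 128, ABE = 40, B = 11)
#' venn_character_matrix(w)
venn_character_matrix <- function(weights, anc = c("absent", "present", "none")) {
  anc <- match.arg(anc)
  labs <- venn_labels()
  bad <- setdiff(names(weights), labs)
  if (length(bad)) stop("unknown Venn labels: ", paste(bad, collapse = ", "))
  w <- setNames(numeric(15), labs)
  w[names(weights)] <- weights
  if (any(w < 0)) stop("weights must be non-negative")
  if (all(w == 0)) stop("at least one positive weight required")
  x <- t(vapply(SUPERGROUPS,
                function(s) as.integer(grepl(s, labs)), integer(15)))
  dimnames(x) <- list(SUPERGROUPS, labs)
  if (anc != "none") {
    x <- rbind(x, ANC = if (anc == "absent") 0L else 1L)
  }
  structure(list(x = x, weights = w), class = "group_character_matrix")
}

#' Weighted uncorrected-P distances between network taxa
#'
#' The proportion of mismatching binary characters, each character weighted
#' by its Venn-group item count:
#' `d(t, u) = sum_c w_c |x_tc - x_uc| / sum_c w_c`.
#'
#' @param m A [venn_character_matrix()].
#' @return Symmetric distance matrix with zero diagonal, values in `[0, 1]`.
#' @export
weighted_p_distance <- function(m) {
  stopifnot(inherits(m, "group_character_matrix"))
  w <- m$weights
  if (sum(w) <= 0) stop("all-zero weights")
  x <- m$x
  n <- nrow(x)
  d <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d[i, j] <- d[j, i] <- sum(w * abs(x[i, ] - x[j, ])) / sum(w)
  }
  d
}

quartets_of <- function(n) combn(n, 4)

quartet_sums <- function(d, q) {
  s <- c(d[q[1], q[2]] + d[q[3], q[4]],
         d[q[1], q[3]] + d[q[2], q[4]],
         d[q[1], q[4]] + d[q[2], q[3]])
  sort(s, decreasing = TRUE)
}

#' Quartet delta score of a distance matrix
#'
#' For every quartet of taxa the three pairwise-sum combinations are sorted
#' `m1 >= m2 >= m3`; the quartet delta is `(m1 - m2) / (m1 - m3)` (0 when
#' all three sums are equal). On an additive tree metric the four-point
#' condition forces `m1 = m2`, so the score is 0 — a fully bifurcating,
#' vertical signal; on a maximally box-like metric (the unit 4-cycle) the
#' score is 1 — full reticulation. The overall score is the mean over
#' quartets and the per-taxon score the mean over quartets containing the
#' taxon.
#'
#' @param d Symmetric non-negative distance matrix on >= 4 taxa.
#' @return List with `overall`, `per_taxon` (named), and `quartet` (one
#'   delta per quartet).
#' @export
delta_score <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 4) stop("delta score needs >= 4 taxa")
  qs <- quartets_of(n)
  deltas <- apply(qs, 2, function(q) {
    s <- quartet_sums(d, q)
    if (s[1] - s[3] < 1e-12) 0 else (s[1] - s[2]) / (s[1] - s[3])
  })
  per_taxon <- vapply(seq_len(n), function(t)
    mean(deltas[apply(qs == t, 2, any)]), 0)
  list(overall = mean(deltas),
       per_taxon = setNames(per_taxon, rownames(d)),
       quartet = deltas)
}

#' Q-residual score of a distance matrix
#'
#' Companion reticulation statistic to the delta score: distances are first
#' rescaled so the mean off-diagonal distance is 1 (making the score
#' scale-invariant), then each quartet contributes `(m1 - m2)^2` and the
#' score is the mean over quartets. Zero on any additive tree metric.
#'
#' @inheritParams delta_score
#' @return Non-negative scalar.
#' @export
q_residual <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 4) stop("Q-residual needs >= 4 taxa")
  off <- d[upper.tri(d)]
  mu <- mean(off)
  if (mu <= 0) return(0)
  ds <- d / mu
  qs <- quartets_of(n)
  mean(apply(qs, 2, function(q) {
    s <- quartet_sums(ds, q)
    (s[1] - s[2])^2
  }))
}

#' Neighbor-joining tree of the network taxa
#'
#' Standard neighbor joining on the weighted P distances (via `ape::nj`),
#' used as the tree stand-in for the split-network layout. Negative branch
#' lengths, which NJ can produce on non-additive input, are clamped to 0 and
#' flagged.
#'
#' @param d Distance matrix on >= 3 taxa.
#' @return List with `tree` (unrooted `phylo`) and `clamped` (TRUE when
#'   negative branch lengths were zeroed).
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3) stop("NJ needs >= 3 taxa")
  tr <- ape::nj(as.dist(d))
  clamped <- any(tr$edge.length < 0)
  tr$edge.length <- pmax(tr$edge.length, 0)
  list(tree = tr, clamped = clamped)
}

# non-trivial splits of an unrooted tree as canonical strings: the side not
# containing the alphabetically first taxon, sorted and joined by "|".
# Splits whose internal branch length is <= tol are treated as unresolved.
tree_splits <- function(tree, tol = 1e-12) {
  tips <- sort(tree$tip.label)
  n <- length(tree$tip.label)
  out <- character(0)
  desc <- function(node, edge, ntip) {
    kids <- edge[edge[, 1] == node, 2]
    unlist(c(lapply(kids[kids > ntip], desc, edge = edge, ntip = ntip),
             kids[kids <= ntip]))
  }
  rooted <- ape::root(tree, outgroup = tips[1], resolve.root = TRUE)
  edge <- rooted$edge
  ntip <- length(rooted$tip.label)
  has_len <- !is.null(rooted$edge.length)
  for (e in seq_len(nrow(edge))) {
    ch <- edge[e, 2]
    if (ch <= ntip) next
    if (has_len && rooted$edge.length[e] <= tol) next
    side <- sort(rooted$tip.label[desc(ch, edge, ntip)])
    if (length(side) < 2 || length(side) > n - 2) next
    if (tips[1] %in% side) side <- sort(setdiff(tips, side))
    out <- c(out, paste(side, collapse = "|"))
  }
  unique(out)
}

#' Bootstrap support for NJ splits of the Venn network
#'
#' Resamples the item-level units (the prototypes or families behind the
#' column weights) with replacement, regenerates the 15 Venn-group weights,
#' recomputes weighted P distances and the NJ tree, and reports for each
#' resolved split of the original tree the percentage of replicates
#' containing it. With signal-free weights the original tree has no
#' resolved splits and the support table is empty.
#'
#' @param m A [venn_character_matrix()].
#' @param replicates Number of bootstrap replicates (default 2000).
#' @param seed Integer seed.
#' @return List with `support` (data frame `split`, `support_pct`), `tree`
#'   (original NJ result) and `replicates`.
#' @export
bootstrap_support <- function(m, replicates = 2000, seed = 1) {
  stopifnot(inherits(m, "group_character_matrix"))
  if (replicates < 1) stop("need at least one replicate")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  base <- nj_tree(weighted_p_distance(m))
  orig <- tree_splits(base$tree)
  hits <- setNames(numeric(length(orig)), orig)
  N <- round(sum(m$weights))
  for (r in seq_len(replicates)) {
    w <- as.numeric(rmultinom(1, N, m$weights / sum(m$weights)))
    names(w) <- names(m$weights)
    mb <- m
    mb$weights <- w
    if (all(w == 0)) next
    spl <- tree_splits(nj_tree(weighted_p_distance(mb))$tree, tol = -1)
    hits[orig %in% spl] <- hits[orig %in% spl] + 1
  }
  list(support = data.frame(split = orig,
                            support_pct = 100 * unname(hits) / replicates,
                            stringsAsFactors = FALSE),
       tree = base, replicates = replicates)
}

#' Cumulative Venn weights from an accretion table
#'
#' Sums the per-(phase, Venn group) counts of a [phase_table()] through a
#' chosen phase endpoint, yielding the 15 column weights of the network
#' analysis at that point of the chronology.
#'
#' @param vpt A `venn_phase_table` (or its long `counts` data frame).
#' @param through_phase Last phase included (default 5, the present).
#' @param what `"prototypes"` or `"families"`.
#' @param cumulative If `FALSE`, only the counts of `through_phase` itself.
#' @return Named numeric vector over the 15 Venn labels.
#' @export
venn_weights <- function(vpt, through_phase = 5,
                         what = c("prototypes", "families"),
                         cumulative = TRUE) {
  what <- match.arg(what)
  counts <- if (inherits(vpt, "venn_phase_table")) vpt$counts else vpt
  sel <- if (cumulative) counts$phase <= through_phase
         else counts$phase == through_phase
  w <- tapply(counts[[what]][sel], counts$venn[sel], sum)[venn_labels()]
  w[is.na(w)] <- 0
  setNames(as.numeric(w), venn_labels())
}
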