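# ArchDB-style internal coordinates of supersecondary loop motifs.

vnorm <- function(v) sqrt(sum(v^2))
unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("zero-length vector")
  v / n
}
deg <- function(rad) rad * 180 / pi
angle_between <- function(a, b) deg(acos(max(-1, min(1, sum(unit(a) * unit(b))))))

# Rodrigues rotation matrix taking unit vector `a` onto unit vector `b`
rotation_between <- function(a, b) {
  a <- unit(a); b <- unit(b)
  v <- c(a[2] * b[3] - a[3] * b[2],
         a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  c_ <- sum(a * b)
  if (vnorm(v) < 1e-12) {
    if (c_ > 0) return(diag(3))
    # antiparallel: rotate pi about any axis orthogonal to a
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- unit(p - sum(p * a) * a)
    return(2 * outer(ax, ax) - diag(3))
  }
  K <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + K + K %*% K / (1 + c_)
}

#' A supersecondary loop structure
#'
#' Two sequential periodic bracing elements (alpha-helix H, beta-strand E or
#' 3-10 helix G) connected by an aperiodic region, held as ordered C-alpha
#' coordinate matrices.
#'
#' @param ss1,ss2 Numeric matrices (n x 3) of C-alpha coordinates for the N-
#'   and C-terminal bracing elements, >= 4 residues each.
#' @param loop Coordinates of the aperiodic region (may have 0 rows).
#' @param ss1_type,ss2_type Secondary-structure labels in \{"H","E","G"\}.
#' @param adjacent Are the two elements sequence-adjacent strands (used for
#'   the beta-hairpin / beta-link split)? Default TRUE.
#' @return An object of class `loop_structure`.
#' @export
loop_structure <- function(ss1, loop, ss2, ss1_type, ss2_type,
                           adjacent = TRUE) {
  ss1 <- as.matrix(ss1); ss2 <- as.matrix(ss2); loop <- as.matrix(loop)
  if (nrow(ss1) < 4 || nrow(ss2) < 4)
    stop("bracing elements need >= 4 residues (principal axis unstable)")
  if (!all(is.finite(ss1)) || !all(is.finite(ss2)) ||
      (nrow(loop) > 0 && !all(is.finite(loop))))
    stop("coordinates must be finite")
  if (!ss1_type %in% c("H", "E", "G") || !ss2_type %in% c("H", "E", "G"))
    stop("secondary-structure labels must be H, E or G")
  structure(list(ss1 = ss1, loop = loop, ss2 = ss2,
                 ss1_type = ss1_type, ss2_type = ss2_type,
                 adjacent = isTRUE(adjacent)),
            class = "loop_structure")
}

#' Oriented principal axis of a bracing element
#'
#' First principal axis of the centered C-alpha coordinates (dominant right
#' singular vector), with the sign chosen so the axis points from the N- to
#' the C-terminus (positive dot product with last minus first point).
#'
#' @param coords Ordered n x 3 coordinate matrix, n >= 4.
#' @return Unit 3-vector.
#' @export
principal_vector <- function(coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 4) stop("need >= 4 points")
  cen <- sweep(coords, 2, colMeans(coords))
  if (max(abs(cen)) < 1e-9) stop("coincident points: no principal axis")
  v <- svd(cen, nu = 0, nv = 1)$v[, 1]
  d <- coords[nrow(coords), ] - coords[1, ]
  if (sum(v * d) < 0) v <- -v
  unit(v)
}

#' Internal coordinates (D, hoist, packing, meridian) of a loop motif
#'
#' The four ArchDB internal coordinates, computed from the oriented
#' principal vectors `M1` and `M2` of the bracing elements and the vector
#' `D` joining the boundaries of the aperiodic region (last C-alpha of the
#' first element to first C-alpha of the second):
#' * `D` — Euclidean distance in Angstroms between the boundary atoms;
#' * `delta` (hoist) — angle between `M1` and the D-vector, in \[0, 180\];
#' * `theta` (packing) — angle between `M1` and `M2`, in \[0, 180\];
#' * `rho` (meridian) — right-handed rotation, about the D-vector, of the
#'   projection of `M2` from the projection of `M1` onto the plane normal to
#'   the D-vector, in \[0, 360). When a projection degenerates (an element
#'   parallel to the D-vector) `rho` is reported as 0 and flagged.
#'
#' @param loop A [loop_structure()].
#' @return A `loop_geometry` list: `D`, `delta`, `theta`, `rho`, `M1`, `M2`,
#'   `rho_defined`.
#' @export
internal_coordinates <- function(loop) {
  stopifnot(inherits(loop, "loop_structure"))
  M1 <- principal_vector(loop$ss1)
  M2 <- principal_vector(loop$ss2)
  dvec <- loop$ss2[1, ] - loop$ss1[nrow(loop$ss1), ]
  D <- vnorm(dvec)
  if (D < 1e-9) stop("coincident boundary atoms: zero-length D")
  dhat <- dvec / D
  delta <- angle_between(M1, dvec)
  theta <- angle_between(M1, M2)
  p1 <- M1 - sum(M1 * dhat) * dhat
  p2 <- M2 - sum(M2 * dhat) * dhat
  rho_defined <- vnorm(p1) > 1e-8 && vnorm(p2) > 1e-8
  rho <- if (rho_defined) {
    cr <- c(p1[2] * p2[3] - p1[3] * p2[2],
            p1[3] * p2[1] - p1[1] * p2[3],
            p1[1] * p2[2] - p1[2] * p2[1])
    (deg(atan2(sum(cr * dhat), sum(p1 * p2))) + 360) %% 360
  } else 0
  structure(list(D = D, delta = delta, theta = theta, rho = rho,
                 M1 = M1, M2 = M2, rho_defined = rho_defined),
            class = "loop_geometry")
}

#' @export
print.loop_geometry <- function(x, ...) {
  cat(sprintf("Loop geometry: D=%.2f A, hoist=%.1f, packing=%.1f, meridian=%.1f deg\n",
              x$D, x$delta, x$theta, x$rho))
  invisible(x)
}

#' Classify a loop motif into the ten ArchDB loop types
#'
#' The type is the concatenation of the bracing secondary-structure labels
#' (HH, HE, EH, GG, GH, HG, GE, EG), except for strand-strand motifs, which
#' split into beta-hairpins (`BN`: sequence-adjacent antiparallel strands,
#' packing angle > 90 degrees) and beta-links (`BK`) otherwise.
#'
#' @param loop A [loop_structure()].
#' @param geom Its [internal_coordinates()] (computed if missing).
#' @return One of `"HH","HE","EH","BN","BK","GG","GH","HG","GE","EG"`.
#' @export
classify_loop_type <- function(loop, geom = NULL) {
  stopifnot(inherits(loop, "loop_structure"))
  if (loop$ss1_type == "E" && loop$ss2_type == "E") {
    if (is.null(geom)) geom <- internal_coordinates(loop)
    if (loop$adjacent && geom$theta > 90) "BN" else "BK"
  } else {
    paste0(loop$ss1_type, loop$ss2_type)
  }
}

#' Segment lengths of a loop motif
#'
#' @param loop A [loop_structure()].
#' @return Named integer vector `n_ss1`, `n_loop`, `n_ss2` (residue counts).
#' @export
element_lengths <- function(loop) {
  stopifnot(inherits(loop, "loop_structure"))
  c(n_ss1 = nrow(loop$ss1), n_loop = nrow(loop$loop), n_ss2 = nrow(loop$ss2))
}

#' Per-phase trends of loop geometry
#'
#' Box-plot statistics (median, quartiles, whisker limits) of each geometric
#' metric per evolutionary phase, plus per-(loop type, metric) medians.
#'
#' @param geoms Data frame with a `phase` column, optionally `loop_type`,
#'   and one column per metric (e.g. `D`, `delta`, `theta`, `rho`, `n_ss1`,
#'   `n_loop`, `n_ss2`).
#' @param metrics Metric columns to summarise (default: all numeric columns
#'   other than `phase`).
#' @return List with `by_phase` (phase, metric, n, median, q1, q3, lower,
#'   upper) and `by_type` (loop_type, metric, n, median) when types are
#'   present.
#' @export
geometry_phase_trends <- function(geoms, metrics = NULL) {
  metrics <- metrics %||% setdiff(names(geoms)[vapply(geoms, is.numeric, TRUE)],
                                  c("phase"))
  box <- function(x) {
    q <- unname(quantile(x, c(0.25, 0.5, 0.75), type = 7))
    iqr <- q[3] - q[1]
    lo <- min(x[x >= q[1] - 1.5 * iqr])
    hi <- max(x[x <= q[3] + 1.5 * iqr])
    c(n = length(x), median = q[2], q1 = q[1], q3 = q[3],
      lower = lo, upper = hi)
  }
  rows <- list()
  for (ph in sort(unique(geoms$phase))) for (mt in metrics) {
    x <- geoms[[mt]][geoms$phase == ph]
    x <- x[!is.na(x)]
    if (!length(x)) next
    rows[[length(rows) + 1]] <- data.frame(phase = ph, metric = mt,
                                           t(box(x)))
  }
  by_phase <- do.call(rbind, rows)
  by_type <- NULL
  if ("loop_type" %in% names(geoms)) {
    rows <- list()
    for (tp in sort(unique(geoms$loop_type))) for (mt in metrics) {
      x <- geoms[[mt]][geoms$loop_type == tp]
      x <- x[!is.na(x)]
      if (!length(x)) next
      rows[[length(rows) + 1]] <- data.frame(loop_type = tp, metric = mt,
                                             n = length(x), median = median(x))
    }
    by_type <- do.call(rbind, rows)
  }
  list(by_phase = by_phase, by_type = by_type)
}

#' Approximate secondary-structure labels from C-alpha geometry
#'
#' A crude rise/turn heuristic for coordinate sets lacking secondary
#' structure labels: the span between C-alpha `i` and `i+3` is about
#' 5-6.5 Angstroms in an alpha-helix, 6.5-8.5 in a 3-10 helix and above
#' 9 in an extended strand. This is an *approximate* fallback only — real
#' assignments (DSSP and kin) use hydrogen bonding and full backbone
#' geometry; prefer supplying labels via the sidecar TSV.
#'
#' @param coords Ordered n x 3 C-alpha coordinate matrix, n >= 4.
#' @return Character vector of per-residue labels in \{"H","G","E","C"\}.
#' @export
guess_secondary_structure <- function(coords) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 4) stop("need >= 4 residues")
  span3 <- vapply(seq_len(n - 3), function(i)
    sqrt(sum((coords[i + 3, ] - coords[i, ])^2)), 0)
  lab <- rep("C", n)
  res_lab <- function(s) {
    # ideal i..i+3 spans: alpha ~5.1 A, 3-10 ~6.0 A, strand ~9.9 A
    if (s < 5.6) "H" else if (s < 8) "G" else if (s > 9) "E" else "C"
  }
  # each i..i+3 window votes for its four residues; majority wins
  win <- vapply(span3, res_lab, "")
  for (i in seq_len(n)) {
    w <- win[max(1, i - 3):min(length(win), i)]
    lab[i] <- names(sort(table(w), decreasing = TRUE))[1]
  }
  lab
}

#' Read / write loop structures as minimal PDB plus SS sidecar
#'
#' Structures are stored as CA-only ATOM records (chain A, 1-based residue
#' numbers) with a sidecar TSV giving the per-residue secondary-structure
#' label (H/E/G for bracing elements, C for the aperiodic region). PDB I/O
#' goes through bio3d.
#'
#' @param loop A [loop_structure()].
#' @param path PDB file path; the sidecar is written to `<path>.ss.tsv`.
#' @return `write_loop_structure()` returns `path` invisibly;
#'   `read_loop_structure()` returns a [loop_structure()].
#' @export
write_loop_structure <- function(loop, path) {
  xyz <- rbind(loop$ss1, loop$loop, loop$ss2)
  n <- nrow(xyz)
  bio3d::write.pdb(file = path, xyz = as.vector(t(xyz)),
                   resno = seq_len(n), chain = rep("A", n),
                   resid = rep("ALA", n), elety = rep("CA", n))
  ss <- c(rep(loop$ss1_type, nrow(loop$ss1)),
          rep("C", nrow(loop$loop)),
          rep(loop$ss2_type, nrow(loop$ss2)))
  write.table(data.frame(resno = seq_len(n), ss = ss,
                         adjacent = loop$adjacent),
              paste0(path, ".ss.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_loop_structure
#' @export
read_loop_structure <- function(path) {
  pdb <- bio3d::read.pdb(path)
  ca <- pdb$atom[pdb$atom$elety == "CA", ]
  xyz <- as.matrix(ca[order(ca$resno), c("x", "y", "z")])
  side <- read.delim(paste0(path, ".ss.tsv"), stringsAsFactors = FALSE)
  ss <- side$ss[order(side$resno)]
  if (length(ss) != nrow(xyz)) stop("sidecar does not match PDB residues")
  i1 <- which(ss %in% c("H", "E", "G"))
  brk <- which(diff(i1) > 1)
  if (length(brk) != 1) stop("expected exactly two bracing elements")
  seg1 <- i1[seq_len(brk)]
  seg2 <- i1[(brk + 1):length(i1)]
  loop_structure(xyz[seg1, , drop = FALSE],
                 xyz[setdiff(seq_len(nrow(xyz)), c(seg1, seg2)), , drop = FALSE],
                 xyz[seg2, , drop = FALSE],
                 ss[seg1[1]], ss[seg2[1]],
                 adjacent = isTRUE(side$adjacent[1]))
}
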