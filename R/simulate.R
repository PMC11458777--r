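# Seeded synthetic-data generators: censuses with planted accretion
# histories, prototype-family mappings with planted modularity, and ideal
# loop structures with requested internal coordinates.

#' Default Venn-group schedule of the accretion simulator
#'
#' Probability of each Venn label for a family born in each phase. The
#' schedule mimics the qualitative accretion narrative of comparative
#' genomics: the oldest phases are dominated by the universal ABEV group,
#' superkingdom losses (ABE, BE, BEV) appear in the middle phases, and
#' lineage-specific groups only late.
#'
#' @return 6 x 15 matrix, rows phases 0..5, columns [venn_labels()], each
#'   row summing to 1.
#' @export
default_venn_schedule <- function() {
  labs <- venn_labels()
  m <- matrix(0, 6, 15, dimnames = list(paste0("phase", 0:5), labs))
  m[1, "ABEV"] <- 1
  m[2, c("ABEV", "ABE")] <- c(0.85, 0.15)
  m[3, c("ABEV", "ABE", "BEV", "BE")] <- c(0.55, 0.35, 0.05, 0.05)
  m[4, c("ABEV", "ABE", "AB", "ABV", "B", "BV", "BE")] <-
    c(0.35, 0.30, 0.10, 0.05, 0.10, 0.05, 0.05)
  m[5, c("ABEV", "ABE", "AB", "B", "E", "A", "V", "AE", "AEV", "BE", "BEV")] <-
    c(0.15, 0.15, 0.10, 0.15, 0.15, 0.05, 0.05, 0.05, 0.05, 0.05, 0.05)
  m[6, c("ABEV", "ABE", "E", "EV", "AE", "AEV", "BE", "BEV", "A", "V")] <-
    c(0.10, 0.05, 0.30, 0.15, 0.10, 0.05, 0.10, 0.05, 0.025, 0.075)
  m
}

#' Parameters of the accretion census simulator
#'
#' Encodes the generality premise of abundance-based chronologies: families
#' born earlier are more abundant (expected abundance decays exponentially
#' with birth time) and more widespread (Venn labels drawn from a
#' phase-indexed schedule that starts universal and diversifies late).
#'
#' @param n_families Number of domain families (>= 4).
#' @param group_sizes Named counts of proteomes per supergroup (A, B, E, V),
#'   each >= 2.
#' @param lambda0 Expected abundance of the oldest family (default 50).
#' @param decay Exponential decay rate of abundance with birth time
#'   (default 2).
#' @param dropout Per-cell zeroing probability in `[0, 1)` (default 0.05).
#' @param venn_schedule 6 x 15 phase-by-label probability matrix, rows
#'   summing to 1 (default [default_venn_schedule()]).
#' @param seed Integer seed.
#' @return An `accretion_params` list.
#' @export
accretion_params <- function(n_families = 60,
                             group_sizes = c(A = 8, B = 8, E = 8, V = 8),
                             lambda0 = 50, decay = 2, dropout = 0.05,
                             venn_schedule = default_venn_schedule(),
                             seed = 1) {
  if (n_families < 4) stop("need at least 4 families")
  if (!all(SUPERGROUPS %in% names(group_sizes)) ||
      any(group_sizes[SUPERGROUPS] < 2))
    stop("group_sizes must cover A, B, E, V with >= 2 proteomes each")
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  if (lambda0 <= 0 || decay < 0) stop("lambda0 > 0 and decay >= 0 required")
  if (!all(abs(rowSums(venn_schedule) - 1) < 1e-9))
    stop("every venn_schedule row must sum to 1")
  if (!identical(colnames(venn_schedule), venn_labels()))
    stop("venn_schedule columns must be venn_labels() in order")
  structure(list(n_families = as.integer(n_families),
                 group_sizes = group_sizes[SUPERGROUPS],
                 lambda0 = lambda0, decay = decay, dropout = dropout,
                 venn_schedule = venn_schedule, seed = as.integer(seed)),
            class = "accretion_params")
}

#' Simulate a genomic-abundance census with a planted accretion history
#'
#' Families receive sorted-uniform birth times on `[0, 1]` (0 = oldest) and
#' a Venn label drawn from the phase schedule at their birth phase. The
#' abundance of family `f` in proteome `p` is
#' `Poisson(lambda0 * exp(-decay * t_f))` when `p`'s supergroup belongs to
#' `f`'s Venn label and 0 otherwise, then zeroed with probability `dropout`.
#' Any all-zero family column (possible only at extreme parameters) is
#' redrawn from the same seeded stream so the census invariant holds.
#'
#' @param params An [accretion_params()].
#' @return List with `census` (a [census_matrix()]) and `truth` (list:
#'   `birth_time`, `venn`, `phase`, `age_gya` per family, plus `params`).
#' @export
simulate_accretion <- function(params = accretion_params()) {
  stopifnot(inherits(params, "accretion_params"))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(params$seed)
  nf <- params$n_families
  fam <- sprintf("f%03d", seq_len(nf))
  t_f <- sort(runif(nf))
  age <- 3.8 * (1 - t_f)
  phase <- assign_phase(age)
  venn <- vapply(seq_len(nf), function(i) {
    sample(venn_labels(), 1, prob = params$venn_schedule[phase[i] + 1, ])
  }, "")
  groups <- rep(SUPERGROUPS, params$group_sizes)
  prot <- sprintf("%s%02d", groups, unlist(lapply(params$group_sizes, seq_len)))
  lam <- params$lambda0 * exp(-params$decay * t_f)
  g <- matrix(0L, length(prot), nf, dimnames = list(prot, fam))
  for (j in seq_len(nf)) {
    present <- grepl(paste0("[", venn[j], "]"), groups)
    repeat {
      col <- integer(length(prot))
      col[present] <- rpois(sum(present), lam[j])
      if (params$dropout > 0)
        col[runif(length(col)) < params$dropout] <- 0L
      if (any(col > 0)) break
    }
    g[, j] <- col
  }
  census <- census_matrix(g, groups)
  truth <- list(birth_time = setNames(t_f, fam),
                venn = setNames(venn, fam),
                phase = setNames(phase, fam),
                age_gya = setNames(age, fam),
                params = params)
  list(census = census, truth = truth)
}

LOOP_TYPES <- c("HH", "HE", "EH", "BN", "BK", "GG", "GH", "HG", "GE", "EG")

#' Simulate prototype-to-family mappings with planted modularity
#'
#' Non-modular prototypes map to a single family (each family has its own
#' birth time under the sorted-uniform birth model, so a single time of
#' origin means a single family); modular prototypes map to 2-4 families
#' with distinct birth times. True links get synthetic e-values below
#' 0.001; decoy rows with e-values at or above the threshold are planted so
#' the filter has something to remove.
#'
#' @param truth The `truth` element of [simulate_accretion()].
#' @param n_prototypes Number of prototypes (default 100).
#' @param modular_fraction Proportion of modular prototypes in `[0, 1]`
#'   (default 0.3).
#' @param decoy_fraction Expected decoy rows per prototype (default 0.3).
#' @param seed Integer seed.
#' @return List with `mappings` (data frame `prototype`, `family`,
#'   `e_value`, including decoys), `truth` (data frame `prototype`,
#'   `modularity`, `age_nd` planted rank-age, `birth_time`).
#' @export
simulate_prototype_mappings <- function(truth, n_prototypes = 100,
                                        modular_fraction = 0.3,
                                        decoy_fraction = 0.3, seed = 1) {
  if (modular_fraction < 0 || modular_fraction > 1)
    stop("modular_fraction must be in [0, 1]")
  fams <- names(truth$birth_time)
  if (length(fams) < 2) stop("need at least two families")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  n_mod <- round(n_prototypes * modular_fraction)
  is_mod <- rep(c(TRUE, FALSE), c(n_mod, n_prototypes - n_mod))
  ids <- sprintf("DS.%s.%d.%d.%d",
                 sample(LOOP_TYPES, n_prototypes, replace = TRUE),
                 sample(2:10, n_prototypes, replace = TRUE),
                 sample(1:60, n_prototypes, replace = TRUE),
                 sample(1:4, n_prototypes, replace = TRUE))
  ids <- make.unique(ids, sep = "_")
  rows <- list()
  tr <- list()
  for (i in seq_len(n_prototypes)) {
    k <- if (is_mod[i]) sample(2:min(4, length(fams)), 1) else 1L
    mapped <- sample(fams, k)
    ev <- 10^runif(k, -10, log10(0.001) - 0.05)
    rows[[i]] <- data.frame(prototype = ids[i], family = mapped,
                            e_value = ev, stringsAsFactors = FALSE)
    tr[[i]] <- data.frame(prototype = ids[i],
                          modularity = if (is_mod[i]) "modular" else "non-modular",
                          birth_time = min(truth$birth_time[mapped]),
                          stringsAsFactors = FALSE)
  }
  mappings <- do.call(rbind, rows)
  n_decoy <- rpois(1, decoy_fraction * n_prototypes)
  if (n_decoy > 0) {
    decoys <- data.frame(prototype = sample(ids, n_decoy, replace = TRUE),
                         family = sample(fams, n_decoy, replace = TRUE),
                         e_value = 10^runif(n_decoy, -3, -1),
                         stringsAsFactors = FALSE)
    mappings <- rbind(mappings, decoys)
  }
  rownames(mappings) <- NULL
  list(mappings = mappings, truth = do.call(rbind, tr))
}

#' Simulate prototype and family annotations with known frequencies
#'
#' Loop types are parsed from the prototype ids; disorder levels and
#' major/minor function categories are drawn from fixed frequency vectors.
#'
#' @param prototype_ids Character vector of ArchDB-style ids.
#' @param seed Integer seed.
#' @return Data frame `prototype`, `loop_type`, `disorder`,
#'   `function_major`, `function_minor`.
#' @export
simulate_annotations <- function(prototype_ids, seed = 1) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  majors <- c("Metabolism", "Information", "Intracellular processes",
              "Extracellular processes", "Regulation", "General",
              "Other/Unknown")
  major <- sample(majors, length(prototype_ids), replace = TRUE,
                  prob = c(0.35, 0.2, 0.15, 0.1, 0.1, 0.05, 0.05))
  data.frame(
    prototype = prototype_ids,
    loop_type = vapply(strsplit(prototype_ids, ".", fixed = TRUE),
                       `[`, "", 2),
    disorder = sample(c("ordered", "moderate", "high"),
                      length(prototype_ids), replace = TRUE,
                      prob = c(0.75, 0.2, 0.05)),
    function_major = major,
    function_minor = paste0(major, " ",
                            sample(1:7, length(prototype_ids), replace = TRUE)),
    stringsAsFactors = FALSE)
}

# ideal C-alpha traces along +z, one row per residue
ideal_trace <- function(type, n) {
  if (n < 4) stop("bracing elements need >= 4 residues")
  i <- seq_len(n) - 1
  switch(type,
    H = cbind(2.3 * cos(i * 100 * pi / 180), 2.3 * sin(i * 100 * pi / 180),
              1.5 * i),
    G = cbind(1.9 * cos(i * 120 * pi / 180), 1.9 * sin(i * 120 * pi / 180),
              2.0 * i),
    E = cbind(rep(0, n), 0.95 * (-1)^i, 3.3 * i),
    stop("unknown secondary-structure type: ", type))
}

#' Simulate a loop structure with requested internal coordinates
#'
#' Builds ideal C-alpha traces for the two bracing elements (alpha-helix:
#' 2.3 A radius, 1.5 A rise, 100 deg/residue; 3-10 helix: 1.9 A, 2.0 A,
#' 120 deg; beta-strand: 3.3 A/residue extended zigzag), orients each so its
#' *computed* principal axis realises the requested geometry exactly, and
#' places the boundary atoms `D` Angstroms apart. The four coordinates are
#' not independent: given `delta`, `theta` and `rho`, the polar angle of the
#' second axis must satisfy
#' `cos(theta) = cos(delta) cos(alpha) + sin(delta) cos(rho) sin(alpha)`,
#' and the generator errors when no solution exists. Gaussian noise of sd
#' `noise_sd` is finally added per coordinate.
#'
#' @param type Loop-type label (`"HH"`, `"EH"`, ..., `"BN"`/`"BK"` count as
#'   strand-strand).
#' @param D Boundary distance in Angstroms (> 0).
#' @param delta,theta Hoist and packing angles in degrees, `[0, 180]`.
#' @param rho Meridian angle in degrees, `[0, 360)`.
#' @param n_res Residue counts, length 3: bracing 1, aperiodic region,
#'   bracing 2 (bracing >= 4 each).
#' @param noise_sd Gaussian noise sd in Angstroms (default 0).
#' @param seed Integer seed (used only when `noise_sd > 0`).
#' @return A [loop_structure()] carrying the requested coordinates in
#'   attribute `"requested"`.
#' @export
simulate_loop_coordinates <- function(type = "HE", D = 6, delta = 30,
                                      theta = 90, rho = 90,
                                      n_res = c(8, 6, 8), noise_sd = 0,
                                      seed = 1) {
  if (D <= 0) stop("D must be positive")
  if (theta < 0 || theta > 180 || delta < 0 || delta > 180)
    stop("theta and delta must lie in [0, 180]")
  if (rho < 0 || rho >= 360) stop("rho must lie in [0, 360)")
  ss_types <- if (type %in% c("BN", "BK")) c("E", "E")
              else strsplit(type, "")[[1]]
  if (length(ss_types) != 2 || !all(ss_types %in% c("H", "E", "G")))
    stop("unknown loop type: ", type)
  if (length(n_res) != 3 || any(n_res[c(1, 3)] < 4))
    stop("n_res must give >= 4 residues per bracing element")

  to_rad <- pi / 180
  # solve the polar angle alpha of M2 about the D-axis
  a <- cos(delta * to_rad)
  b <- sin(delta * to_rad) * cos(rho * to_rad)
  r <- sqrt(a^2 + b^2)
  ct <- cos(theta * to_rad)
  if (abs(ct) > r + 1e-12)
    stop("requested (delta, theta, rho) are geometrically incompatible")
  phi <- atan2(b, a)
  cand <- phi + c(1, -1) * acos(max(-1, min(1, ct / r)))
  cand <- c(cand, cand + 2 * pi, cand - 2 * pi)  # all representatives
  cand <- cand[cand > -1e-12 & cand < pi + 1e-12]
  if (!length(cand))
    stop("requested (delta, theta, rho) are geometrically incompatible: ",
         "no M2 polar angle in [0, 180]")
  # prefer the least degenerate solution (largest sin: M2 farthest from the
  # D-axis, where the meridian is well defined)
  alpha <- max(0, min(pi, cand[which.max(sin(cand))]))

  M1 <- c(sin(delta * to_rad), 0, cos(delta * to_rad))
  M2 <- c(sin(alpha) * cos(rho * to_rad), sin(alpha) * sin(rho * to_rad),
          cos(alpha))

  place <- function(tr, target, anchor_last) {
    ax <- principal_vector(tr)
    R <- rotation_between(ax, target)
    out <- tr %*% t(R)
    shift <- if (anchor_last) out[nrow(out), ] else out[1, ]
    sweep(out, 2, shift)
  }
  ss1 <- place(ideal_trace(ss_types[1], n_res[1]), M1, anchor_last = TRUE)
  ss2 <- place(ideal_trace(ss_types[2], n_res[3]), M2, anchor_last = FALSE)
  ss2 <- sweep(ss2, 2, c(0, 0, D), `+`)
  lp <- if (n_res[2] > 0) {
    f <- seq_len(n_res[2]) / (n_res[2] + 1)
    cbind(2 * sin(pi * f), 0.5 * sin(2 * pi * f), D * f)
  } else matrix(0, 0, 3)
  if (noise_sd > 0) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
    jig <- function(x) x + matrix(rnorm(length(x), 0, noise_sd), nrow(x), 3)
    ss1 <- jig(ss1); ss2 <- jig(ss2)
    if (nrow(lp)) lp <- jig(lp)
  }
  out <- loop_structure(ss1, lp, ss2, ss_types[1], ss_types[2],
                        adjacent = all(ss_types == "E"))
  attr(out, "requested") <- c(D = D, delta = delta, theta = theta, rho = rho)
  out
}
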