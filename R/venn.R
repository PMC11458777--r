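# Four-set Venn groups, evolutionary phases, accretion tables, urancestors.

#' Canonical Venn-group label of a presence set
#'
#' The 15 Venn groups are the non-empty subsets of \{Archaea (A), Bacteria
#' (B), Eukarya (E), viruses (V)\}; a family present in all four belongs to
#' the universal ABEV group, one restricted to Bacteria to B, and so on.
#' Letters are always concatenated in the fixed order A, B, E, V.
#'
#' @param presence Character vector, a non-empty subset of `c("A","B","E","V")`.
#' @return The canonical label string.
#' @export
#' @examples
#' venn_group(c("E", "A", "B"))  # "ABE"
venn_group <- function(presence) {
  presence <- unique(as.character(presence))
  if (length(presence) == 0)
    stop("empty presence set: item absent from every supergroup")
  if (!all(presence %in% SUPERGROUPS))
    stop("presence letters must be in {A, B, E, V}")
  paste(SUPERGROUPS[SUPERGROUPS %in% presence], collapse = "")
}

#' Supergroup presence of a family in a census
#'
#' A family counts as present in a supergroup when at least `min_proteomes`
#' of its proteomes have nonzero abundance (default 1: a single genome
#' suffices).
#'
#' @param census A [census_matrix()].
#' @param family Family id (column name) or vector of ids.
#' @param min_proteomes Minimum number of proteomes with `g > 0` (default 1).
#' @return For one family, the character vector of supergroups; for several,
#'   a named character vector of Venn labels (via [venn_group()]).
#' @export
presence_from_census <- function(census, family, min_proteomes = 1) {
  stopifnot(inherits(census, "census_matrix"))
  miss <- setdiff(family, colnames(census$abundance))
  if (length(miss)) stop("unknown families: ", paste(miss, collapse = ", "))
  one <- function(f) {
    nz <- census$abundance[, f] > 0
    counts <- tapply(nz, census$supergroup, sum)
    names(counts)[!is.na(counts) & counts >= min_proteomes]
  }
  if (length(family) == 1) return(one(family))
  setNames(vapply(family, function(f) venn_group(one(f)), ""), family)
}

#' Evolutionary phase configuration
#'
#' The six phases of the chronology, delimited in Gya: Phase 0 the communal
#' world (3.8-3.6), Phase I the rise of viral ancestors (3.6-3.2), Phase II
#' the birth of ancestors of Archaea (3.2-2.5), Phase III diversified
#' Bacteria (2.5-2.0), Phase IV the rise of diversified superkingdoms and
#' viruses (2.0-0.9) and Phase V the rise of Eukarya (0.9 to the present).
#'
#' @param boundaries Strictly decreasing numeric vector of 7 phase limits in
#'   Gya, oldest first, ending at 0.
#' @return A `phase_config` list with `boundaries` and `labels`.
#' @export
phase_config <- function(boundaries = c(3.8, 3.6, 3.2, 2.5, 2.0, 0.9, 0)) {
  if (any(diff(boundaries) >= 0)) stop("boundaries must strictly decrease")
  if (tail(boundaries, 1) != 0) stop("youngest boundary must be 0 (present)")
  structure(list(boundaries = boundaries,
                 labels = paste0("Phase ", c("0", "I", "II", "III", "IV", "V"))[
                   seq_len(length(boundaries) - 1)]),
            class = "phase_config")
}

#' Assign ages to evolutionary phases
#'
#' Intervals are closed at the older end and open at the younger end, so an
#' age sitting exactly on an internal boundary belongs to the younger phase
#' (2.5 Gya falls in Phase III, which spans 2.5-2.0). Age 0 (the present)
#' belongs to the last phase.
#'
#' @param age_gya Numeric vector of ages in Gya.
#' @param cfg A [phase_config()].
#' @return Integer vector of phase indices, 0 (oldest) .. 5.
#' @export
#' @examples
#' assign_phase(c(3.7, 2.5, 0))  # 0, 3, 5
assign_phase <- function(age_gya, cfg = phase_config()) {
  b <- cfg$boundaries
  k <- length(b) - 1  # number of phases
  vapply(age_gya, function(a) {
    if (is.na(a) || a < -1e-9 || a > b[1] + 1e-6)
      stop("age ", a, " outside the chronology range [0, ", b[1], "]")
    hit <- which(b < a - 1e-12)  # phases whose *lower* bound is below a
    if (length(hit) == 0) return(as.integer(k - 1))  # a == 0: the present
    as.integer(hit[1] - 2L)                           # b[p+2] < a <= b[p+1]
  }, integer(1))
}

#' Venn-group / phase accretion table
#'
#' The machine form of the accretion analysis: counts of non-modular
#' prototypes and of domain families per (phase, Venn group), per-phase
#' totals and the per-phase prototype/family ratio rounded half away from
#' zero to two decimals. Phases without families get a flagged undefined
#' ratio.
#'
#' @param prototypes Data frame with columns `age_gya` (or `phase`) and
#'   `venn` for dated prototypes.
#' @param families Same layout for dated domain families.
#' @param cfg A [phase_config()].
#' @return A `venn_phase_table`: list with `counts` (long data frame `phase`,
#'   `venn`, `prototypes`, `families`) and `phase_summary` (`phase`,
#'   `prototypes`, `families`, `ratio`, `ratio_defined`).
#' @export
phase_table <- function(prototypes, families, cfg = phase_config()) {
  k <- length(cfg$boundaries) - 1
  prep <- function(d) {
    if (!"phase" %in% names(d)) d$phase <- assign_phase(d$age_gya, cfg)
    if (!"venn" %in% names(d)) d$venn <- "ABEV"
    d
  }
  prototypes <- prep(prototypes)
  families <- prep(families)
  grid <- expand.grid(venn = venn_labels(), phase = 0:(k - 1),
                      stringsAsFactors = FALSE)[, c("phase", "venn")]
  cnt <- function(d) {
    t <- table(factor(d$phase, levels = 0:(k - 1)),
               factor(d$venn, levels = venn_labels()))
    as.vector(t(t))  # venn fastest within each phase, matching `grid`
  }
  grid$prototypes <- cnt(prototypes)
  grid$families <- cnt(families)
  ps <- aggregate(cbind(prototypes, families) ~ phase, grid, sum)
  ps$ratio <- ifelse(ps$families > 0,
                     round_half_up(ps$prototypes / ps$families, 2), NA_real_)
  ps$ratio_defined <- ps$families > 0
  structure(list(counts = grid, phase_summary = ps, labels = cfg$labels),
            class = "venn_phase_table")
}

#' @export
print.venn_phase_table <- function(x, ...) {
  cat("Venn-group / phase accretion table\n")
  print(x$phase_summary)
  invisible(x)
}

#' Write the accretion table as TSV
#'
#' @param vpt A [phase_table()] result.
#' @param path Output path (long counts); the per-phase summary goes to
#'   `<path>` with suffix `.summary.tsv` alongside.
#' @export
write_phase_table <- function(vpt, path) {
  write.table(vpt$counts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(vpt$phase_summary, paste0(path, ".summary.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Urancestor prototype repertoires
#'
#' The repertoire of the last universal common ancestor of cells and viruses
#' (LUCA) is everything dated to Phase 0; the last universal cellular
#' ancestor (LUCellA), which closes Phase I, additionally carries Phase I
#' prototypes. LUCA is therefore always nested in LUCellA.
#'
#' @param prototypes Dated prototype data frame with `prototype` and
#'   `age_gya` (or `phase`) columns.
#' @param cfg A [phase_config()].
#' @param which `"LUCA"` or `"LUCellA"`.
#' @return Character vector of prototype ids in the repertoire.
#' @export
urancestor_repertoire <- function(prototypes, cfg = phase_config(),
                                  which = c("LUCA", "LUCellA")) {
  which <- match.arg(which)
  ph <- if ("phase" %in% names(prototypes)) prototypes$phase
        else assign_phase(prototypes$age_gya, cfg)
  cut <- if (which == "LUCA") 0L else 1L
  prototypes$prototype[ph <= cut]
}

#' Annotation summary of a prototype repertoire
#'
#' Contingency tables of a repertoire by loop type, intrinsic-disorder level
#' and major/minor function category. Prototypes missing an annotation are
#' assigned `"Other/Unknown"` rather than dropped.
#'
#' @param ids Character vector of prototype ids (e.g. a repertoire).
#' @param annotations Data frame with column `prototype` plus any of
#'   `loop_type`, `disorder`, `function_major`, `function_minor`.
#' @return Named list of data frames (`loop_type`, `disorder`, ...), each
#'   with `category`, `count`, `proportion` summing to the repertoire size.
#' @export
summarize_repertoire <- function(ids, annotations) {
  out <- list()
  for (col in intersect(c("loop_type", "disorder",
                          "function_major", "function_minor"),
                        names(annotations))) {
    v <- annotations[[col]][match(ids, annotations$prototype)]
    v[is.na(v) | !nzchar(v)] <- "Other/Unknown"
    t <- table(v)
    out[[col]] <- data.frame(category = names(t), count = as.integer(t),
                             proportion = as.numeric(t) / length(ids),
                             row.names = NULL, stringsAsFactors = FALSE)
  }
  out
}
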