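# Loop prototypes: e-value filtering, modularity, ages, bipartite network.

chronology_nd <- function(chronology) {
  setNames(chronology$table$nd, chronology$table$family)
}

chronology_clock <- function(chronology) {
  if (!is.null(chronology$clock)) return(chronology$clock)
  tab <- chronology$table
  if (!"age_gya" %in% names(tab) || length(unique(tab$nd)) < 2)
    return(c(a = 3.8, b = -3.8))
  fit <- lm(age_gya ~ nd, data = tab)
  c(a = unname(coef(fit)[1]), b = unname(coef(fit)[2]))
}

#' Load prototype-to-family mappings and apply the e-value filter
#'
#' Keeps only mapping rows with `e_value` strictly below the threshold
#' (default `0.001`, the significance cutoff used when assigning ArchDB
#' prototypes to domain families). Prototypes left without any
#' significant family are dropped and counted.
#'
#' @param table Data frame with columns `prototype`, `family`, `e_value`, or
#'   a path to a TSV with those columns.
#' @param e_threshold Strict upper bound on the e-value (default 0.001).
#' @return List with `mappings` (the surviving rows), `n_dropped_rows` and
#'   `dropped_prototypes` (ids excluded entirely by the filter).
#' @export
load_and_filter_mappings <- function(table, e_threshold = 0.001) {
  if (is.character(table)) table <- read.delim(table, stringsAsFactors = FALSE)
  need <- c("prototype", "family", "e_value")
  if (!all(need %in% names(table)))
    stop("mapping table needs columns: ", paste(need, collapse = ", "))
  ev <- suppressWarnings(as.numeric(table$e_value))
  if (any(is.na(ev))) stop("malformed e-values in mapping table")
  keep <- ev < e_threshold
  kept <- table[keep, , drop = FALSE]
  rownames(kept) <- NULL
  dropped <- setdiff(unique(table$prototype), unique(kept$prototype))
  list(mappings = kept,
       n_dropped_rows = sum(!keep),
       dropped_prototypes = dropped)
}

#' Classify a prototype as modular or non-modular
#'
#' A prototype is *non-modular* when every domain family it maps to shares a
#' single time of origin (identical node distance in the chronology), and
#' *modular* when its families span several ages — the signature of a loop
#' prototype recruited by younger domains. `tol` admits jittered ties in
#' real chronologies; the default is an exact tie.
#'
#' @param families Character vector of mapped family ids for one prototype.
#' @param chronology A `chronology` (see [build_chronology()]).
#' @param tol Tie tolerance in nd units (default 1e-12).
#' @return `"modular"` or `"non-modular"`.
#' @export
classify_modularity <- function(families, chronology, tol = 1e-12) {
  nd <- chronology_nd(chronology)
  miss <- setdiff(families, names(nd))
  if (length(miss))
    stop("families absent from the chronology: ", paste(miss, collapse = ", "))
  v <- sort(nd[families])
  if (max(v) - min(v) <= tol) "non-modular" else "modular"
}

#' Date prototypes against a chronology
#'
#' Assigns each filtered prototype a time of origin: the minimum node
#' distance among its mapped families (its first appearance in the domain
#' world), converted to Gya through the chronology's clock, together with
#' its modularity class.
#'
#' @param mappings Filtered mapping rows from [load_and_filter_mappings()].
#' @param chronology A `chronology`.
#' @param tol Tie tolerance passed to [classify_modularity()].
#' @return Data frame with one row per prototype: `prototype`, `modularity`,
#'   `age_nd`, `age_gya`, `n_families`.
#' @export
assign_prototype_age <- function(mappings, chronology, tol = 1e-12) {
  if (is.list(mappings) && !is.data.frame(mappings)) mappings <- mappings$mappings
  if (nrow(mappings) == 0) stop("no mappings to date")
  nd <- chronology_nd(chronology)
  clock <- chronology_clock(chronology)
  sp <- split(mappings$family, mappings$prototype)
  res <- data.frame(
    prototype = names(sp),
    modularity = vapply(sp, classify_modularity, "",
                        chronology = chronology, tol = tol),
    age_nd = vapply(sp, function(f) min(nd[f]), 0),
    n_families = lengths(sp),
    row.names = NULL, stringsAsFactors = FALSE)
  res$age_gya <- pmax(clock["a"] + clock["b"] * res$age_nd, 0)
  res[, c("prototype", "modularity", "age_nd", "age_gya", "n_families")]
}

#' Bipartite prototype-domain network edges
#'
#' One edge per surviving mapping row, carrying both endpoint ages. An edge
#' is a *recruitment* when the family is younger than the prototype itself
#' (`family_nd > prototype_nd`): the prototype, born in an older family, was
#' reused to build a newer domain.
#'
#' @param mappings Filtered mapping rows.
#' @param chronology A `chronology`.
#' @return Data frame `prototype`, `family`, `prototype_nd`, `family_nd`,
#'   `is_recruitment`.
#' @export
bipartite_edges <- function(mappings, chronology) {
  if (is.list(mappings) && !is.data.frame(mappings)) mappings <- mappings$mappings
  ages <- assign_prototype_age(mappings, chronology)
  nd <- chronology_nd(chronology)
  p_nd <- setNames(ages$age_nd, ages$prototype)
  data.frame(prototype = mappings$prototype,
             family = mappings$family,
             prototype_nd = unname(p_nd[mappings$prototype]),
             family_nd = unname(nd[mappings$family]),
             is_recruitment = unname(nd[mappings$family] >
                                       p_nd[mappings$prototype] + 1e-12),
             stringsAsFactors = FALSE)
}
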