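# Census -> ordered multistate character coding and NEXUS export.

NEXUS_SYMBOLS <- c(0:9, LETTERS)  # state s is written as NEXUS_SYMBOLS[s + 1]

#' Map one genomic abundance to an ordered character state
#'
#' Abundances are rescaled logarithmically onto `S` linearly ordered states,
#' so that absence is state 0 and the maximum observed abundance of the
#' character is the top state `S - 1`:
#' \deqn{state(g) = round\left(\frac{\ln(1+g)}{\ln(1+g_{max})} (S-1)\right)}
#' with rounding half away from zero. The log scale compresses the heavy
#' right tail of genomic abundance distributions while preserving order, the
#' property the Wagner parsimony cost model acts on.
#'
#' @param g Non-negative integer abundance (vectorised).
#' @param g_max Maximum abundance used for scaling; must be >= 1 and >= `g`.
#' @param S Number of states (default 24, encodable as 0-9A-N).
#' @return Integer state(s) in `0 .. S-1`.
#' @export
#' @examples
#' normalize_abundance(7, 100)    # 10
#' normalize_abundance(0:5, 5)    # monotone, endpoints exact
normalize_abundance <- function(g, g_max, S = 24) {
  if (length(g_max) != 1 || g_max < 1) stop("g_max must be a single count >= 1")
  if (S < 2) stop("S must be >= 2")
  if (any(g < 0) || any(g > g_max)) stop("g must lie in [0, g_max]")
  as.integer(round_half_up(log1p(g) / log1p(g_max) * (S - 1)))
}

#' Encode a census as a matrix of ordered multistate characters
#'
#' Each family column becomes one linearly ordered phylogenetic character.
#' With the default `"per-family"` scope every character is scaled by its own
#' maximum abundance, so the most abundant proteome for a family always takes
#' the top state; `"global"` scales all characters by the single matrix-wide
#' maximum (available for sensitivity analysis).
#'
#' @param census A [census_matrix()].
#' @param S Number of states (default 24).
#' @param scope `"per-family"` (default) or `"global"`.
#' @return A `character_matrix`: list with `states` (integer matrix, same
#'   dimnames as the census), `S`, `scope`, and the proteome `supergroup`s.
#' @export
#' @examples
#' g <- matrix(c(0L, 5L, 10L), 3, 1,
#'             dimnames = list(paste0("p", 1:3), "c.37.1.12"))
#' cm <- encode_census(census_matrix(g, c("A", "B", "E")))
#' cm$states  # 0, 17, 23
encode_census <- function(census, S = 24, scope = c("per-family", "global")) {
  scope <- match.arg(scope)
  stopifnot(inherits(census, "census_matrix"))
  g <- census$abundance
  if (length(g) == 0) stop("empty census")
  states <- if (scope == "per-family") {
    vals <- lapply(seq_len(ncol(g)),
                   function(j) normalize_abundance(g[, j], max(g[, j]), S))
    matrix(unlist(vals), nrow(g), ncol(g))
  } else {
    matrix(normalize_abundance(g, max(g), S), nrow(g), ncol(g))
  }
  dimnames(states) <- dimnames(g)
  structure(list(states = states, S = as.integer(S), scope = scope,
                 supergroup = census$supergroup),
            class = "character_matrix")
}

#' @export
print.character_matrix <- function(x, ...) {
  cat("Ordered multistate character matrix:", nrow(x$states), "taxa x",
      ncol(x$states), "characters,", x$S, "states, scope =", x$scope, "\n")
  invisible(x)
}

#' Write / read an ordered character matrix as NEXUS
#'
#' Emits a `DATA` block (datatype STANDARD, symbols `0-9A-N` for the default
#' 24 states) and an `ASSUMPTIONS` block typing every character as ordered,
#' the form consumed by standard parsimony programs. `read_character_matrix()`
#' parses files written by `write_character_matrix()` bit-exactly.
#'
#' @param m A `character_matrix` from [encode_census()].
#' @param path Output file path.
#' @return `write_character_matrix()` returns `path` invisibly;
#'   `read_character_matrix()` returns a `character_matrix`.
#' @export
write_character_matrix <- function(m, path) {
  stopifnot(inherits(m, "character_matrix"))
  if (m$S > length(NEXUS_SYMBOLS))
    stop("state count exceeds the alphanumeric symbol set")
  states <- m$states
  sym <- NEXUS_SYMBOLS[seq_len(m$S)]
  rows <- apply(states, 1, function(r) paste(sym[r + 1], collapse = ""))
  labels <- rownames(states)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "#NEXUS",
    sprintf("[loopchron character matrix; scope=%s]", m$scope),
    "BEGIN DATA;",
    sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", nrow(states), ncol(states)),
    sprintf("  FORMAT DATATYPE=STANDARD SYMBOLS=\"%s\";",
            paste(sym, collapse = "")),
    "  MATRIX"), con)
  writeLines(sprintf("    %s  %s", format(labels), rows), con)
  writeLines(c("  ;", "END;", "", "BEGIN ASSUMPTIONS;",
               "  TYPESET * default = ord: all;", "END;", "",
               "BEGIN CHARACTERS;",
               sprintf("  [CHARLABELS %s]",
                       paste(colnames(states), collapse = " ")),
               "END;"), con)
  invisible(path)
}

#' @rdname write_character_matrix
#' @export
read_character_matrix <- function(path) {
  ln <- readLines(path)
  scope <- sub(".*scope=([a-z-]+).*", "\\1", grep("scope=", ln, value = TRUE)[1])
  fmt <- grep("FORMAT", ln, value = TRUE)[1]
  sym <- strsplit(sub('.*SYMBOLS="([^"]+)".*', "\\1", fmt), "")[[1]]
  i0 <- grep("^\\s*MATRIX", ln)[1]
  i1 <- i0 + which(grepl("^\\s*;", ln[(i0 + 1):length(ln)]))[1]
  body <- trimws(ln[(i0 + 1):(i1 - 1)])
  body <- body[nzchar(body)]
  parts <- strsplit(body, "\\s+")
  labels <- vapply(parts, `[`, "", 1)
  chars <- vapply(parts, function(p) p[length(p)], "")
  states <- t(vapply(strsplit(chars, ""),
                     function(s) match(s, sym) - 1L,
                     integer(nchar(chars[1]))))
  rownames(states) <- labels
  cl <- grep("CHARLABELS", ln, value = TRUE)
  if (length(cl)) {
    fam <- strsplit(sub(".*CHARLABELS ([^]]*)\\].*", "\\1", cl[1]), " ")[[1]]
    if (length(fam) == ncol(states)) colnames(states) <- fam
  }
  structure(list(states = states, S = length(sym), scope = scope,
                 supergroup = NULL),
            class = "character_matrix")
}
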