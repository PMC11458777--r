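#' Genomic-abundance census of domain families across proteomes
#'
#' A `census_matrix` holds the raw observable of the chronology pipeline:
#' counts `g` of how many times each structural domain family occurs in each
#' sampled proteome, with every proteome labeled by its supergroup —
#' Archaea (A), Bacteria (B), Eukarya (E) or viruses (V).
#'
#' @param abundance Non-negative integer matrix, proteomes in rows, domain
#'   families in columns. Row and column names are required (proteome and
#'   family identifiers).
#' @param supergroup Character vector over \{"A","B","E","V"\}, one entry per
#'   proteome row.
#' @return An object of class `census_matrix`: a list with elements
#'   `abundance` (the matrix) and `supergroup` (named character vector).
#' @export
#' @examples
#' g <- matrix(c(4L, 0L, 2L, 1L), 2, 2,
#'             dimnames = list(c("p1", "p2"), c("c.37.1.12", "d.58.4.1")))
#' census_matrix(g, c("A", "B"))
census_matrix <- function(abundance, supergroup) {
  abundance <- as.matrix(abundance)
  if (is.null(rownames(abundance)) || is.null(colnames(abundance)))
    stop("abundance matrix must have proteome row names and family column names")
  if (any(abundance < 0) || any(abundance != floor(abundance)))
    stop("abundances must be non-negative integers")
  if (length(supergroup) != nrow(abundance))
    stop("one supergroup label per proteome row is required")
  supergroup <- as.character(supergroup)
  if (!all(supergroup %in% SUPERGROUPS))
    stop("supergroup labels must be in {A, B, E, V}")
  if (any(colSums(abundance) == 0))
    stop("every family column must contain at least one nonzero abundance")
  storage.mode(abundance) <- "integer"
  structure(list(abundance = abundance,
                 supergroup = setNames(supergroup, rownames(abundance))),
            class = "census_matrix")
}

#' @export
print.census_matrix <- function(x, ...) {
  cat("Genomic-abundance census:", nrow(x$abundance), "proteomes x",
      ncol(x$abundance), "domain families\n")
  cat("Supergroups:", paste(sprintf("%s=%d", names(table(x$supergroup)),
                                    table(x$supergroup)), collapse = " "), "\n")
  invisible(x)
}

#' Read / write a census as TSV
#'
#' The file layout has one row per proteome: columns `proteome`, `supergroup`,
#' then one column per domain family holding the abundance counts.
#'
#' @param path File path.
#' @return `read_census()` returns a [census_matrix()]; `write_census()`
#'   returns `path` invisibly.
#' @export
read_census <- function(path) {
  d <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("proteome", "supergroup") %in% names(d)[1:2]))
    stop("census TSV must start with columns 'proteome' and 'supergroup'")
  m <- as.matrix(d[, -(1:2), drop = FALSE])
  rownames(m) <- d$proteome
  census_matrix(m, d$supergroup)
}

#' @rdname read_census
#' @param census A [census_matrix()].
#' @export
write_census <- function(census, path) {
  d <- data.frame(proteome = rownames(census$abundance),
                  supergroup = unname(census$supergroup),
                  census$abundance, check.names = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
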