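# Plain-text interchange: insertion-site CSV (position,strand,count), gene
# annotation TSV, and context-profile TSV export.

#' Write / read an insertion library as CSV
#'
#' The on-disk form mirrors the saved first-mapped-position tables:
#' `position,strand,count` with 0-based positions.
#'
#' @param lib An [insertion_library()].
#' @param path File path.
#' @return `path` invisibly (write); an [insertion_library()] (read).
#' @export
write_insertions <- function(lib, path) {
  stopifnot(inherits(lib, "insertion_library"))
  utils::write.csv(lib$sites[, c("position", "strand", "count")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_insertions
#' @param label Library label applied on read.
#' @export
read_insertions <- function(path, label = "library") {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("position", "strand", "count")
  if (!all(need %in% names(x))) {
    stop("insertion CSV must have columns position,strand,count", call. = FALSE)
  }
  insertion_library(x$position, x$strand, x$count, label)
}

#' Read a gene annotation table
#'
#' Tab-separated `name start end strand` with 0-based half-open intervals
#' (BED-like).
#'
#' @param path TSV file path.
#' @return data.frame suitable for [tn_genome()]'s `genes` argument.
#' @export
read_gene_table <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "start", "end", "strand")
  if (!all(need %in% names(x))) {
    stop("gene table must have columns name, start, end, strand", call. = FALSE)
  }
  x[, need]
}

#' Export a context profile as a TSV matrix
#'
#' Contexts x incorporated bases, as counts or frequencies.
#'
#' @param profile A `context_profile`.
#' @param path Output TSV path.
#' @param what `"frequencies"` (default) or `"counts"`.
#' @return `path`, invisibly.
#' @export
write_context_profile <- function(profile, path,
                                  what = c("frequencies", "counts")) {
  stopifnot(inherits(profile, "context_profile"))
  what <- match.arg(what)
  m <- profile[[what]]
  utils::write.table(data.frame(context = rownames(m), m, check.names = FALSE),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
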