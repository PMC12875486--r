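#' Read set container
#'
#' Lightweight container for simulated or ingested amplicon reads: sequences
#' in sense orientation with ids, optional per-base quality strings, and a
#' provenance record (generator parameters and seed) for reproducibility.
#'
#' @param sequences Character vector of DNA sequences (non-empty).
#' @param ids Read identifiers; defaults to `read1..readN`.
#' @param qualities Optional character vector of Phred+33 quality strings,
#'   same lengths as `sequences`.
#' @param provenance Optional list recording how the reads were made.
#' @return Object of class `read_set`.
#' @export
read_set <- function(sequences, ids = NULL, qualities = NULL, provenance = list()) {
  stopifnot(is.character(sequences), length(sequences) >= 1)
  if (any(is.na(sequences) | nchar(sequences) == 0)) {
    stop("all read sequences must be non-empty", call. = FALSE)
  }
  if (is.null(ids)) ids <- paste0("read", seq_along(sequences))
  stopifnot(length(ids) == length(sequences))
  if (!is.null(qualities)) {
    stopifnot(length(qualities) == length(sequences),
              all(nchar(qualities) == nchar(sequences)))
  }
  structure(list(sequences = unname(sequences), ids = as.character(ids),
                 qualities = qualities, provenance = provenance),
            class = "read_set")
}

#' @export
length.read_set <- function(x) length(x$sequences)

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("read_set: %d reads, lengths %s, qualities %s\n",
              length(x), paste(range(nchar(x$sequences)), collapse = "-"),
              if (is.null(x$qualities)) "absent" else "present"))
  invisible(x)
}

#' Subsample a read set without replacement
#'
#' Mirrors the common practice of profiling a fixed random subset of a large
#' pooled run (e.g. ten million reads from pooled replicates).
#'
#' @param reads A [read_set()].
#' @param n Number of reads to keep; must not exceed `length(reads)`.
#' @param seed Integer seed; the same seed always selects the same subset.
#' @return A [read_set()] of `n` reads.
#' @export
subsample <- function(reads, n, seed = 1) {
  stopifnot(inherits(reads, "read_set"))
  if (n > length(reads)) {
    stop("n exceeds the number of reads (", length(reads), ")", call. = FALSE)
  }
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  idx <- with_seed(seed, sample.int(length(reads), n))
  read_set(reads$sequences[idx], reads$ids[idx],
           if (is.null(reads$qualities)) NULL else reads$qualities[idx],
           provenance = c(reads$provenance, list(subsample_n = n, subsample_seed = seed)))
}

#' Write reads to FASTQ or FASTA
#'
#' FASTQ is written when the reads carry qualities (or `format = "fastq"` is
#' forced, in which case a constant Q37 is emitted); FASTA otherwise.
#'
#' @param rs A [read_set()].
#' @param path Output file path.
#' @param format `"auto"` (default), `"fasta"`, or `"fastq"`.
#' @return `path`, invisibly.
#' @export
write_reads <- function(rs, path, format = c("auto", "fasta", "fastq")) {
  stopifnot(inherits(rs, "read_set"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (is.null(rs$qualities)) "fasta" else "fastq"
  }
  x <- Biostrings::DNAStringSet(rs$sequences)
  names(x) <- rs$ids
  if (format == "fasta") {
    Biostrings::writeXStringSet(x, path)
  } else {
    quals <- rs$qualities
    if (is.null(quals)) quals <- strrep("F", nchar(rs$sequences))  # Q37
    Biostrings::writeXStringSet(x, path, format = "fastq",
                                qualities = Biostrings::BStringSet(quals))
  }
  invisible(path)
}

#' Read reads from FASTQ or FASTA
#'
#' Format is detected from the first record character (`@` FASTQ, `>` FASTA).
#' FASTA input yields a read set without qualities (none are fabricated).
#' Truncated FASTQ files are rejected with the index of the incomplete record.
#'
#' @param path Input file path.
#' @return A [read_set()].
#' @export
read_reads <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  first <- substr(readLines(path, n = 1L), 1, 1)
  if (length(first) == 0) stop("empty read file: ", path, call. = FALSE)
  if (first == "@") {
    n_lines <- length(readLines(path))
    if (n_lines %% 4L != 0L) {
      stop(sprintf("truncated FASTQ: record %d is incomplete in %s",
                   n_lines %/% 4L + 1L, path), call. = FALSE)
    }
    x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
    read_set(as.character(x), names(x),
             qualities = as.character(S4Vectors::mcols(x)$qualities),
             provenance = list(source = path))
  } else if (first == ">") {
    x <- Biostrings::readDNAStringSet(path)
    read_set(as.character(x), names(x), provenance = list(source = path))
  } else {
    stop("unrecognised read format (expected FASTA or FASTQ): ", path,
         call. = FALSE)
  }
}
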