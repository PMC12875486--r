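# Internal helpers shared across modules.

BASES <- c("A", "C", "G", "T")

# Watson-Crick complement for vectors of single bases or full sequences.
dna_complement <- function(x) chartr("ACGT", "TGCA", x)

dna_revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(dna_complement(s), "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# All generator/subsampling randomness is scoped: the caller's RNG state is
# untouched and the same (parameters, seed) pair is bit-reproducible.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

assert_dna <- function(x, what = "sequence") {
  if (length(x) != 1 || !is.character(x) || is.na(x) || nchar(x) == 0 ||
      grepl("[^ACGT]", x)) {
    stop(what, " must be a non-empty DNA string over {A,C,G,T}", call. = FALSE)
  }
  invisible(x)
}

# Split a sequence into its character vector once; used by hot loops.
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]
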