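# Context profiler: per-context incorporated-base matrices, position
# probability matrices, and amino-acid sampling spectra from length-matched
# amplicon reads.

#' Anchor a read between primers and trim to the reference segment
#'
#' Keeps only reads containing both primer binding sites (within
#' `max_mismatch` each) and whose inter-primer segment has exactly the
#' reference length; indel-bearing or unanchored reads are rejected with a
#' reason, not an error.
#'
#' @param read A single read sequence.
#' @param ref A [template_repeat()] giving the expected inter-primer segment.
#' @param primers Character vector of length 2: forward primer and reverse
#'   primer (the reverse primer is given in its own orientation; its reverse
#'   complement is searched in the read).
#' @param max_mismatch Maximum mismatches tolerated per primer match.
#' @return List with `status` (`"ok"`, `"no_anchor"`, or `"length_mismatch"`)
#'   and, when ok, `segment`.
#' @export
anchor_and_trim <- function(read, ref, primers, max_mismatch = 1) {
  stopifnot(inherits(ref, "template_repeat"), length(primers) == 2,
            all(nchar(primers) > 0))
  subject <- Biostrings::DNAString(read)
  fwd <- Biostrings::matchPattern(Biostrings::DNAString(primers[[1]]), subject,
                                  max.mismatch = max_mismatch)
  rev_rc <- Biostrings::matchPattern(
    Biostrings::reverseComplement(Biostrings::DNAString(primers[[2]])), subject,
    max.mismatch = max_mismatch)
  if (length(fwd) == 0 || length(rev_rc) == 0) {
    return(list(status = "no_anchor"))
  }
  from <- IRanges::end(fwd)[1] + 1L
  to <- IRanges::start(rev_rc)[length(rev_rc)] - 1L
  if (to - from + 1L != nchar(ref$sequence)) {
    return(list(status = "length_mismatch"))
  }
  list(status = "ok", segment = substr(read, from, to))
}

#' Anchor and trim a whole read set
#'
#' @param reads A [read_set()].
#' @inheritParams anchor_and_trim
#' @return List with `reads` (a [read_set()] of accepted segments; `NULL` when
#'   none pass) and `rejections` (named integer vector of counts by reason).
#' @export
anchor_and_trim_set <- function(reads, ref, primers, max_mismatch = 1) {
  stopifnot(inherits(reads, "read_set"))
  res <- lapply(reads$sequences, anchor_and_trim, ref = ref, primers = primers,
                max_mismatch = max_mismatch)
  status <- vapply(res, `[[`, character(1), "status")
  keep <- status == "ok"
  rejections <- c(no_anchor = sum(status == "no_anchor"),
                  length_mismatch = sum(status == "length_mismatch"))
  out <- NULL
  if (any(keep)) {
    out <- read_set(vapply(res[keep], `[[`, character(1), "segment"),
                    ids = reads$ids[keep],
                    provenance = c(reads$provenance, list(trimmed = TRUE)))
  }
  list(reads = out, rejections = rejections)
}

#' Count incorporated cDNA bases opposite template adenines
#'
#' For every annotated adenine of the template, tallies the incorporated cDNA
#' base observed in each read: incorporated = complement(sense base), with
#' cognate incorporation T (sense A). Returns a per-context counts matrix in
#' incorporated-base space, the primary reporting frame for context profiles.
#'
#' @param reads A [read_set()] of reads length-matched to the template
#'   (post [anchor_and_trim_set()]).
#' @param template A [template_repeat()].
#' @return Object of class `context_profile`: list with `counts` (contexts x
#'   `A,C,G,T` incorporated-base matrix), `totals`, `frequencies`, and
#'   `pooled_rate` (observation-weighted fraction of non-T incorporations).
#' @export
count_incorporations <- function(reads, template) {
  stopifnot(inherits(reads, "read_set"), inherits(template, "template_repeat"))
  L <- nchar(template$sequence)
  if (any(nchar(reads$sequences) != L)) {
    stop("reads must be length-matched to the template (", L, " nt)",
         call. = FALSE)
  }
  ctx_keys <- sort(unique(template$contexts))
  counts <- matrix(0L, nrow = length(ctx_keys), ncol = 4,
                   dimnames = list(ctx_keys, BASES))
  offsets <- as.integer(names(template$contexts))
  for (i in seq_along(offsets)) {
    obs_sense <- substr(reads$sequences, offsets[i] + 1L, offsets[i] + 1L)
    inc <- dna_complement(obs_sense)
    tab <- table(factor(inc, levels = BASES))
    counts[template$contexts[[i]], ] <- counts[template$contexts[[i]], ] + as.integer(tab)
  }
  totals <- rowSums(counts)
  freqs <- counts / ifelse(totals == 0, 1, totals)
  pooled <- 1 - sum(counts[, "T"]) / sum(counts)
  structure(list(counts = counts, totals = totals, frequencies = freqs,
                 pooled_rate = pooled),
            class = "context_profile")
}

#' @export
print.context_profile <- function(x, ...) {
  cat(sprintf("context_profile: %d contexts, %d observations, pooled misincorporation %.2f%%\n",
              nrow(x$counts), sum(x$counts), 100 * x$pooled_rate))
  print(round(100 * x$frequencies, 2))
  invisible(x)
}

#' Conditional misincorporation spectrum of a context profile
#'
#' Shares of A, C and G among non-cognate incorporations, pooled over
#' contexts (observation-weighted) or per context.
#'
#' @param profile A `context_profile`.
#' @param pooled Pool over contexts (default) or return a per-context matrix.
#' @return Named numeric vector over `A,C,G` (or matrix when `pooled = FALSE`).
#' @export
misincorporation_spectrum <- function(profile, pooled = TRUE) {
  stopifnot(inherits(profile, "context_profile"))
  mis <- profile$counts[, c("A", "C", "G"), drop = FALSE]
  if (pooled) {
    tot <- colSums(mis)
    tot / sum(tot)
  } else {
    mis / ifelse(rowSums(mis) == 0, 1, rowSums(mis))
  }
}

#' Convert a context profile to sense-substitution space
#'
#' Pure relabelling: incorporated base -> complement (sense read base).
#' Applying the transformation twice is the identity.
#'
#' @param profile A `context_profile`.
#' @return The profile with columns relabelled to sense-space bases.
#' @export
as_sense_profile <- function(profile) {
  stopifnot(inherits(profile, "context_profile"))
  relabel <- function(m) {
    colnames(m) <- dna_complement(colnames(m))
    m[, BASES, drop = FALSE]
  }
  profile$counts <- relabel(profile$counts)
  profile$frequencies <- relabel(profile$frequencies)
  profile
}

#' Position probability matrix of a read set
#'
#' Per-template-position base probabilities in sense space, suitable for
#' probability-scaled sequence-logo rendering.
#'
#' @param reads A non-empty [read_set()], length-matched to the template.
#' @param template A [template_repeat()] (used for length validation).
#' @return Numeric matrix, positions x `A,C,G,T`; rows sum to 1.
#' @export
position_ppm <- function(reads, template) {
  stopifnot(inherits(reads, "read_set"), inherits(template, "template_repeat"))
  if (length(reads) == 0) stop("empty read set", call. = FALSE)
  L <- nchar(template$sequence)
  if (any(nchar(reads$sequences) != L)) {
    stop("reads must be length-matched to the template", call. = FALSE)
  }
  cm <- Biostrings::consensusMatrix(Biostrings::DNAStringSet(reads$sequences),
                                    as.prob = TRUE, baseOnly = TRUE)
  ppm <- t(cm[BASES, , drop = FALSE])
  rownames(ppm) <- seq_len(L) - 1L  # 0-based positions
  ppm
}

#' Amino-acid sampling spectrum at expected AAN codons
#'
#' For each in-frame codon of the template matching `AAN` (given
#' `frame_offset`), translates the observed in-read codons with the standard
#' genetic code (`*` for stops) and reports per-site and per-expected-codon
#' proportions, mirroring amino-acid sampling heatmaps.
#'
#' @param reads A length-matched [read_set()].
#' @param template A [template_repeat()].
#' @param frame_offset 0-based offset of the first codon position.
#' @return Object of class `aa_sampling_spectrum`: list with `per_site`
#'   (list of `position`, `expected_codon`, `proportions`) and `by_codon`
#'   (proportions pooled over sites sharing an expected codon).
#' @export
aa_sampling <- function(reads, template, frame_offset = 0) {
  stopifnot(inherits(reads, "read_set"), inherits(template, "template_repeat"))
  L <- nchar(template$sequence)
  starts <- seq(frame_offset + 1L, L - 2L, by = 3L)  # 1-based codon starts
  expected <- substring(template$sequence, starts, starts + 2L)
  sel <- grepl("^AA[ACGT]$", expected)
  if (!any(sel)) {
    stop("no in-frame AAN codon at frame_offset ", frame_offset, call. = FALSE)
  }
  starts <- starts[sel]; expected <- expected[sel]
  gc_map <- Biostrings::GENETIC_CODE
  per_site <- vector("list", length(starts))
  pooled <- list()
  for (i in seq_along(starts)) {
    codons <- substring(reads$sequences, starts[i], starts[i] + 2L)
    ok <- nchar(codons) == 3L & !grepl("[^ACGT]", codons)
    aa <- unname(gc_map[codons[ok]])
    tab <- table(aa)
    prop <- as.numeric(tab) / sum(tab)
    names(prop) <- names(tab)
    per_site[[i]] <- list(position = starts[i] - 1L,
                          expected_codon = expected[i],
                          n_skipped = sum(!ok),
                          proportions = prop)
    key <- expected[i]
    pooled[[key]] <- if (is.null(pooled[[key]])) tab else {
      all_aa <- union(names(pooled[[key]]), names(tab))
      out <- stats::setNames(numeric(length(all_aa)), all_aa)
      out[names(pooled[[key]])] <- pooled[[key]]
      out[names(tab)] <- out[names(tab)] + tab
      out
    }
  }
  by_codon <- lapply(pooled, function(tab) {
    prop <- as.numeric(tab) / sum(tab)
    names(prop) <- names(tab)
    sort(prop, decreasing = TRUE)
  })
  structure(list(per_site = per_site, by_codon = by_codon),
            class = "aa_sampling_spectrum")
}

#' Concordance between replicate context profiles
#'
#' Maximum absolute incorporated-base frequency deviation per context across
#' a set of profiles (e.g. reordered template variants); zero for identical
#' profiles and symmetric in the inputs.
#'
#' @param profiles List of >= 2 `context_profile`s over identical context keys.
#' @return Named numeric vector: per-context maximum absolute deviation.
#' @export
profile_concordance <- function(profiles) {
  stopifnot(is.list(profiles), length(profiles) >= 2,
            all(vapply(profiles, inherits, logical(1), "context_profile")))
  keys <- rownames(profiles[[1]]$frequencies)
  for (p in profiles[-1]) {
    if (!identical(sort(rownames(p$frequencies)), sort(keys))) {
      stop("profiles must share identical context keys", call. = FALSE)
    }
  }
  dev <- stats::setNames(numeric(length(keys)), keys)
  for (k in keys) {
    rows <- vapply(profiles, function(p) p$frequencies[k, ], numeric(4))
    dev[k] <- max(apply(rows, 1, function(v) diff(range(v))))
  }
  dev
}
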