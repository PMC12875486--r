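# Signature-gated quantification of DGR-mediated target editing, pileup-style
# per-position substitution rates with quality floors, and repair-frequency
# arithmetic for the kanamycin colony assay.

#' Call a read as DGR-edited
#'
#' A read is called edited iff it carries the designed signature mutation
#' (e.g. the G-to-T co-transferred from the template) AND at least one A-to-N
#' difference at the reference's designated adenine positions. Differences at
#' non-designated positions are ignored for the call.
#'
#' @param read A single read sequence, length-matched to the reference.
#' @param ref A [template_repeat()] whose `adenine_positions` define the
#'   designated adenines.
#' @param signature A [signature_spec()].
#' @return List with `has_signature`, `n_A_mut`, `edited`.
#' @export
call_edited <- function(read, ref, signature) {
  stopifnot(inherits(ref, "template_repeat"), inherits(signature, "signature_spec"))
  if (nchar(read) != nchar(ref$sequence)) {
    stop("read must be length-matched to the reference", call. = FALSE)
  }
  has_sig <- substr(read, signature$position + 1L, signature$position + 1L) ==
    signature$alt_base
  obs <- substring(read, ref$adenine_positions + 1L, ref$adenine_positions + 1L)
  n_mut <- sum(obs != "A")
  list(has_signature = has_sig, n_A_mut = n_mut,
       edited = has_sig && n_mut >= 1L)
}

# Vectorised edit calls over a read set; internal engine for editing_rate.
editing_calls <- function(reads, ref, signature) {
  L <- nchar(ref$sequence)
  if (any(nchar(reads$sequences) != L)) {
    stop("reads must be length-matched to the reference", call. = FALSE)
  }
  sig_obs <- substr(reads$sequences, signature$position + 1L, signature$position + 1L)
  has_sig <- sig_obs == signature$alt_base
  mut_by_pos <- matrix(FALSE, nrow = length(reads),
                       ncol = length(ref$adenine_positions),
                       dimnames = list(NULL, ref$adenine_positions))
  for (j in seq_along(ref$adenine_positions)) {
    pos <- ref$adenine_positions[j]
    mut_by_pos[, j] <- substr(reads$sequences, pos + 1L, pos + 1L) != "A"
  }
  n_mut <- rowSums(mut_by_pos)
  calls <- data.frame(id = reads$ids, has_signature = has_sig, n_A_mut = n_mut,
                      edited = has_sig & n_mut >= 1L)
  attr(calls, "mut_by_pos") <- mut_by_pos
  calls
}

#' Signature-gated editing rate of a read set
#'
#' The mutagenesis rate of the target: the fraction of reads carrying both
#' the designed signature mutation and at least one A-to-N mutation at a
#' designated adenine, plus per-position mutation rates over the designated
#' adenines.
#'
#' @param reads A non-empty [read_set()], length-matched to `ref`.
#' @param ref A [template_repeat()].
#' @param signature A [signature_spec()].
#' @param normalize Denominator for per-position rates: `"total"` (default;
#'   mutation counts among edited reads divided by all reads) or `"edited"`
#'   (divided by the number of edited reads).
#' @return Object of class `editing_summary`: `n_total`, `n_edited`, `rate`,
#'   `rate_rpm` (reads per million), `per_position` (named numeric vector over
#'   designated adenine offsets), `calls` (per-read data.frame).
#' @export
editing_rate <- function(reads, ref, signature, normalize = c("total", "edited")) {
  stopifnot(inherits(reads, "read_set"))
  if (length(reads) == 0) stop("empty read set", call. = FALSE)
  normalize <- match.arg(normalize)
  calls <- editing_calls(reads, ref, signature)
  mut_by_pos <- attr(calls, "mut_by_pos")
  n_total <- nrow(calls)
  n_edited <- sum(calls$edited)
  denom <- if (normalize == "total") n_total else max(n_edited, 1L)
  per_pos <- colSums(mut_by_pos[calls$edited, , drop = FALSE]) / denom
  structure(list(n_total = n_total, n_edited = n_edited,
                 rate = n_edited / n_total,
                 rate_rpm = 1e6 * n_edited / n_total,
                 per_position = per_pos, normalize = normalize,
                 calls = calls),
            class = "editing_summary")
}

#' @export
print.editing_summary <- function(x, ...) {
  cat(sprintf("editing_summary: %d / %d reads edited (rate %.4g, %.1f RPM)\n",
              x$n_edited, x$n_total, x$rate, x$rate_rpm))
  invisible(x)
}

#' Per-position substitution rates with quality floors
#'
#' Pileup-style counting over per-base alignment records: reads below the
#' mapping-quality floor are excluded entirely, bases below the base-quality
#' floor are excluded individually, and no indels are emitted (the records
#' carry matched bases only), mirroring an mpileup run with
#' `--min-MQ 20 --min-BQ 30` and indel output suppressed.
#'
#' @param alignments data.frame with one row per aligned base: columns
#'   `read` (read id), `mapq` (per-read mapping quality), `pos` (0-based
#'   reference position), `ref` (reference base), `base` (observed base),
#'   `baseq` (base quality).
#' @param min_bq Base-quality floor (bases with `baseq < min_bq` dropped).
#' @param min_mq Mapping-quality floor (reads with `mapq < min_mq` dropped).
#' @return data.frame per reference position: `pos`, `coverage`,
#'   `mismatches`, `rate`.
#' @export
pileup_rates <- function(alignments, min_bq = 30, min_mq = 20) {
  need <- c("read", "mapq", "pos", "ref", "base", "baseq")
  if (!all(need %in% names(alignments))) {
    stop("alignments must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  keep <- alignments$mapq >= min_mq & alignments$baseq >= min_bq
  a <- alignments[keep, , drop = FALSE]
  if (nrow(a) == 0) {
    return(data.frame(pos = integer(), coverage = integer(),
                      mismatches = integer(), rate = numeric()))
  }
  cov <- tapply(rep(1L, nrow(a)), a$pos, sum)
  mis <- tapply(a$base != a$ref, a$pos, sum)
  out <- data.frame(pos = as.integer(names(cov)),
                    coverage = as.integer(cov),
                    mismatches = as.integer(mis))
  out$rate <- out$mismatches / out$coverage
  out[order(out$pos), , drop = FALSE]
}

#' Repair frequency from a colony-count assay
#'
#' The assay readout for retrohoming efficiency: calibrated CFU/mL divided by
#' the total cells plated, with cell number inferred from optical density.
#' `frequency = (colony_count * dilution_factor / plated_volume) /
#' (od600 * calib)`. Vectorised over assay rows, so a CSV of replicate
#' measurements can be processed with one call.
#'
#' @param colony_count Colony-forming units counted (>= 0).
#' @param dilution_factor Dilution applied before plating (> 0).
#' @param plated_volume Plated volume in mL (> 0).
#' @param od600 Culture OD600 (> 0).
#' @param calib Cells per mL per OD600 unit; default 8e8.
#' @return Numeric repair frequency (frequencies, when inputs are vectors).
#' @examples
#' repair_frequency(100, 1, 1, 2)  # 6.25e-08
#' @export
repair_frequency <- function(colony_count, dilution_factor = 1,
                             plated_volume = 1, od600 = 1, calib = 8e8) {
  if (any(colony_count < 0) || any(dilution_factor <= 0) ||
      any(plated_volume <= 0) || any(od600 <= 0) || any(calib <= 0)) {
    stop("counts must be >= 0 and all factors strictly positive", call. = FALSE)
  }
  (colony_count * dilution_factor / plated_volume) / (od600 * calib)
}
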