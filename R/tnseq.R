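# Tn-seq analysis: junction trimming, exact-prefix insertion mapping (or SAM
# ingestion), RPM normalisation, per-gene enrichment with Mann-Whitney
# testing, hit calling, and origin-recentered orientation analysis.

TN_JUNCTION <- "AAGAGACAG"

#' Preprocess raw Tn-seq reads
#'
#' Removes a terminal poly-G tail (a run of at least `poly_g_min` G at the 3'
#' end), locates the transposon junction sequence and trims everything through
#' it, and retains only reads whose genomic remainder is at least `min_length`
#' nt. Rejections are counted by reason, never raised as errors.
#'
#' @param reads A [read_set()] of raw reads.
#' @param junction Expected transposon junction sequence (default
#'   `AAGAGACAG`).
#' @param min_length Minimum post-trim length retained (default 25).
#' @param poly_g_min Minimum length of a terminal G run to strip (default 10).
#' @return List with `reads` (trimmed [read_set()]; `NULL` when none pass) and
#'   `rejections` (counts: `no_junction`, `too_short`).
#' @export
preprocess_reads <- function(reads, junction = TN_JUNCTION, min_length = 25,
                             poly_g_min = 10) {
  stopifnot(inherits(reads, "read_set"))
  seqs <- sub(sprintf("G{%d,}$", poly_g_min), "", reads$sequences)
  hit <- regexpr(junction, seqs, fixed = TRUE)
  trimmed <- ifelse(hit > 0,
                    substring(seqs, hit + nchar(junction)), NA_character_)
  no_junction <- hit < 0
  too_short <- !no_junction & nchar(trimmed) < min_length
  keep <- !no_junction & !too_short
  out <- NULL
  if (any(keep)) {
    out <- read_set(trimmed[keep], ids = reads$ids[keep],
                    provenance = c(reads$provenance, list(junction = junction)))
  }
  list(reads = out,
       rejections = c(no_junction = sum(no_junction),
                      too_short = sum(too_short)))
}

#' Map trimmed reads to insertion sites by exact unique prefix match
#'
#' The internal mapper: the first `k` bases of each trimmed read are matched
#' exactly against both strands of the genome sequence; reads with exactly one
#' genome-wide hit are kept (the analogue of demanding the aligner's maximal
#' mapping quality) and the leftmost matched coordinate and strand are
#' recorded as the insertion site. Multi-hit and no-hit reads are discarded.
#'
#' @param reads A trimmed [read_set()] (all reads >= `k` nt).
#' @param genome A [tn_genome()] carrying a sequence.
#' @param k Prefix length (default 25).
#' @param label Library label for the result.
#' @return An [insertion_library()] with one row per distinct site.
#' @export
map_insertions <- function(reads, genome, k = 25, label = "library") {
  stopifnot(inherits(reads, "read_set"), inherits(genome, "tn_genome"))
  if (is.null(genome$sequence)) {
    stop("genome has no sequence; provide one or ingest a SAM file instead",
         call. = FALSE)
  }
  if (any(nchar(reads$sequences) < k)) {
    stop("all reads must be at least k = ", k, " nt", call. = FALSE)
  }
  prefixes <- substr(reads$sequences, 1L, k)
  uniq <- unique(prefixes)
  n_per <- as.integer(table(factor(prefixes, levels = uniq)))
  subject <- Biostrings::DNAString(genome$sequence)
  pd <- Biostrings::PDict(uniq)
  fwd <- Biostrings::matchPDict(pd, subject)
  rev <- Biostrings::matchPDict(Biostrings::PDict(dna_revcomp(uniq)), subject)
  n_fwd <- lengths(fwd)
  n_rev <- lengths(rev)
  idx <- which((n_fwd + n_rev) == 1L)
  if (length(idx) == 0) {
    return(insertion_library(integer(0), character(0), integer(0), label,
                             genome$length))
  }
  pos <- vapply(idx, function(i) {
    if (n_fwd[i] == 1L) IRanges::start(fwd[[i]]) else IRanges::start(rev[[i]])
  }, integer(1)) - 1L
  strand <- ifelse(n_fwd[idx] == 1L, "+", "-")
  count <- n_per[idx]
  agg <- stats::aggregate(count,
                          by = list(position = pos, strand = strand), FUN = sum)
  insertion_library(agg$position, agg$strand, agg$x, label, genome$length)
}

#' Ingest pre-mapped insertion sites from a SAM file
#'
#' Alternative front end for real genomes mapped with an external aligner:
#' keeps primary alignments with mapping quality exactly `mapq` (the
#' aligner's unique-hit value) and records the first mapped position (0-based
#' leftmost coordinate) and reference strand of each.
#'
#' @param path Path to a SAM file.
#' @param mapq Required mapping quality (default 60).
#' @param label Library label.
#' @param genome_length Optional length for validation.
#' @return An [insertion_library()].
#' @export
read_sam_insertions <- function(path, mapq = 60, label = "library",
                                genome_length = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  bam <- Rsamtools::asBam(path,
                          destination = tempfile(fileext = ""),
                          overwrite = TRUE, indexDestination = FALSE)
  on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
  flags <- Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE,
                                  isUnmappedQuery = FALSE)
  rec <- Rsamtools::scanBam(bam,
                            param = Rsamtools::ScanBamParam(
                              flag = flags, what = c("pos", "strand", "mapq")))[[1]]
  keep <- !is.na(rec$mapq) & rec$mapq == mapq
  pos <- rec$pos[keep] - 1L  # SAM is 1-based
  strand <- as.character(rec$strand[keep])
  if (length(pos) == 0) {
    return(insertion_library(integer(0), character(0), integer(0), label,
                             genome_length))
  }
  agg <- stats::aggregate(rep(1L, length(pos)),
                          by = list(position = pos, strand = strand), FUN = sum)
  insertion_library(agg$position, agg$strand, agg$x, label, genome_length)
}

#' Reads-per-million normalisation of an insertion library
#'
#' @param lib An [insertion_library()] with `total_reads > 0`.
#' @return The library with an `rpm` column added to `sites`
#'   (`count * 1e6 / total_reads`; RPM values sum to 1e6).
#' @export
normalize_rpm <- function(lib) {
  stopifnot(inherits(lib, "insertion_library"))
  if (lib$total_reads <= 0) stop("library has zero total reads", call. = FALSE)
  lib$sites$rpm <- lib$sites$count * 1e6 / lib$total_reads
  lib
}

#' Mann-Whitney U test
#'
#' Rank-based two-sample test: `U` counts pairs where an `x` value exceeds a
#' `y` value (ties counted half). The p-value is exact (from the null
#' distribution of U) for small tie-free samples, and otherwise uses the
#' normal approximation with the tie-corrected variance and no continuity
#' correction. Two-sided.
#'
#' @param x,y Numeric samples.
#' @param exact Force the exact (`TRUE`) or approximate (`FALSE`) p-value;
#'   default `NULL` chooses exact when there are no ties and both samples
#'   have fewer than 50 values.
#' @return List with `u`, `p_value`, `method`.
#' @export
mw_test <- function(x, y, exact = NULL) {
  n <- length(x); m <- length(y)
  stopifnot(n >= 1, m >= 1)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  ties <- table(r)
  has_ties <- any(ties > 1)
  if (is.null(exact)) exact <- !has_ties && n < 50 && m < 50
  if (exact && !has_ties) {
    p <- if (u > n * m / 2) {
      2 * stats::pwilcox(u - 1, n, m, lower.tail = FALSE)
    } else {
      2 * stats::pwilcox(u, n, m)
    }
    method <- "exact"
  } else {
    N <- n + m
    mu <- n * m / 2
    sigma2 <- n * m / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (u - mu) / sqrt(sigma2)
      p <- 2 * stats::pnorm(-abs(z))
    }
    method <- "normal_tie_corrected"
  }
  list(u = u, p_value = min(1, p), method = method)
}

#' Per-gene Tn-seq enrichment
#'
#' For each annotated gene, collects the union of insertion sites within the
#' gene body from both libraries (a site absent from one library contributes
#' 0 RPM there), compares site-level RPM vectors between Output and Input
#' with the two-sided Mann-Whitney U test (normal approximation, tie
#' corrected), and reports a smoothed pooled-RPM fold change
#' `(sum RPM_out + 0.5) / (sum RPM_in + 0.5)`.
#'
#' @param input,output [insertion_library()]s mapped to the same genome.
#' @param genome A [tn_genome()] with a gene annotation.
#' @param min_sites Minimum Input sites for a gene to be hit-eligible
#'   (default 5); genes below are reported but never flagged by
#'   [call_hits()].
#' @return data.frame (class `gene_enrichment`): one row per gene with
#'   `gene`, `n_sites_input`, `n_sites_output`, `rpm_input`, `rpm_output`,
#'   `fold_change`, `u_stat`, `p_value`, `eligible`.
#' @export
gene_enrichment <- function(input, output, genome, min_sites = 5) {
  stopifnot(inherits(input, "insertion_library"),
            inherits(output, "insertion_library"),
            inherits(genome, "tn_genome"))
  if (nrow(genome$genes) == 0) stop("empty gene annotation", call. = FALSE)
  input <- normalize_rpm(input)
  output <- normalize_rpm(output)
  in_s <- input$sites; out_s <- output$sites
  union_sites <- merge(in_s[, c("position", "strand", "rpm")],
                       out_s[, c("position", "strand", "rpm")],
                       by = c("position", "strand"), all = TRUE,
                       suffixes = c("_in", "_out"))
  union_sites$rpm_in[is.na(union_sites$rpm_in)] <- 0
  union_sites$rpm_out[is.na(union_sites$rpm_out)] <- 0
  gene <- assign_genes(union_sites$position, genome)
  rows <- lapply(seq_len(nrow(genome$genes)), function(i) {
    g <- genome$genes$name[i]
    s <- union_sites[!is.na(gene) & gene == g, , drop = FALSE]
    n_in <- sum(s$rpm_in > 0)
    n_out <- sum(s$rpm_out > 0)
    fc <- (sum(s$rpm_out) + 0.5) / (sum(s$rpm_in) + 0.5)
    if (nrow(s) >= 1) {
      mw <- mw_test(s$rpm_out, s$rpm_in, exact = FALSE)
      u <- mw$u; p <- mw$p_value
    } else {
      u <- NA_real_; p <- NA_real_
    }
    data.frame(gene = g, n_sites_input = n_in, n_sites_output = n_out,
               rpm_input = sum(s$rpm_in), rpm_output = sum(s$rpm_out),
               fold_change = fc, u_stat = u, p_value = p,
               eligible = n_in >= min_sites)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("gene_enrichment", class(out))
  out
}

#' Flag enrichment hits
#'
#' A gene is a hit iff its smoothed fold change passes the threshold in the
#' requested direction and its Mann-Whitney p-value is below `p_threshold`
#' (and it is hit-eligible, i.e. has enough Input sites). Defaults follow the
#' screen's thresholds (2-fold, p < 0.05); `preset = "stringent"` applies the
#' 4-fold / p <= 0.01 volcano-plot lines instead.
#'
#' @param enrichments A `gene_enrichment` data.frame.
#' @param fc_threshold Fold-change threshold (default 2).
#' @param p_threshold p-value threshold (default 0.05).
#' @param direction `"both"`, `"up"` (enriched), or `"down"` (depleted).
#' @param preset `"methods"` (default thresholds) or `"stringent"`
#'   (4-fold, p <= 0.01).
#' @return The data.frame with a logical `hit` column added.
#' @export
call_hits <- function(enrichments, fc_threshold = 2, p_threshold = 0.05,
                      direction = c("both", "up", "down"),
                      preset = c("methods", "stringent")) {
  direction <- match.arg(direction)
  preset <- match.arg(preset)
  if (preset == "stringent") {
    fc_threshold <- 4
    p_threshold <- 0.01
  }
  if (fc_threshold <= 0 || p_threshold <= 0) {
    stop("thresholds must be positive", call. = FALSE)
  }
  fc <- enrichments$fold_change
  up <- fc >= fc_threshold
  down <- fc <= 1 / fc_threshold
  pass_fc <- switch(direction, both = up | down, up = up, down = down)
  enrichments$hit <- enrichments$eligible & pass_fc &
    !is.na(enrichments$p_value) & enrichments$p_value < p_threshold
  enrichments
}

#' Recenter insertion sites around the replication origin
#'
#' Maps each 0-based genome coordinate to a signed circular offset
#' `d = ((pos - oric + L/2) mod L) - L/2` in `[-L/2, L/2)` — a bijection from
#' `[0, L)` — and classifies the insert orientation: away from the origin iff
#' `(strand == "+" and d > 0)` or `(strand == "-" and d < 0)`; sites exactly
#' at the origin are classed by strand (`+` -> away).
#'
#' @param position 0-based coordinates (or an [insertion_library()], in which
#'   case its sites are used and counts carried along).
#' @param strand Strand vector over `+`/`-`.
#' @param genome A [tn_genome()].
#' @return data.frame (class `oric_map`): `position`, `strand`, `d`,
#'   `orientation` (`"away"`/`"toward"`), plus `count` when a library was
#'   given.
#' @export
recenter_oric <- function(position, strand = NULL, genome = NULL) {
  count <- NULL
  if (inherits(position, "insertion_library")) {
    lib <- position
    position <- lib$sites$position
    strand <- lib$sites$strand
    count <- lib$sites$count
  }
  stopifnot(inherits(genome, "tn_genome"), length(position) == length(strand))
  if (any(position < 0 | position >= genome$length)) {
    stop("positions must lie in [0, genome length)", call. = FALSE)
  }
  L <- genome$length
  d <- ((position - genome$oric + L / 2) %% L) - L / 2
  away <- (strand == "+" & d > 0) | (strand == "-" & d < 0) |
    (d == 0 & strand == "+")
  orientation <- ifelse(away, "away", "toward")
  out <- data.frame(position = position, strand = strand, d = d,
                    orientation = orientation)
  if (!is.null(count)) out$count <- count
  class(out) <- c("oric_map", class(out))
  out
}

#' Binned away/toward enrichment around the origin
#'
#' Splits the recentered axis into `n_bins` equal bins and, per bin, compares
#' the Output/Input RPM enrichment of away-pointing versus toward-pointing
#' inserts (0.5-RPM smoothing; a bin missing one class reports `NA` rather
#' than a fabricated ratio). The summary reports the per-side strand
#' preference and whether the preferred strand flips across the origin — the
#' fingerprint of selection that favours inserts pointing away from it.
#'
#' @param input,output [insertion_library()]s over the same genome.
#' @param genome A [tn_genome()].
#' @param n_bins Even number of bins >= 2 (default 10).
#' @return List with `bins` (data.frame: bin bounds, away/toward enrichment
#'   ratios and their ratio) and `summary` (list: `left_pref`, `right_pref` —
#'   plus/minus strand enrichment ratio per side — and `strand_flips`).
#' @export
orientation_preference <- function(input, output, genome, n_bins = 10) {
  stopifnot(inherits(input, "insertion_library"),
            inherits(output, "insertion_library"),
            inherits(genome, "tn_genome"))
  if (n_bins < 2 || n_bins %% 2 != 0) {
    stop("n_bins must be an even number >= 2", call. = FALSE)
  }
  input <- normalize_rpm(input)
  output <- normalize_rpm(output)
  m <- merge(input$sites[, c("position", "strand", "rpm")],
             output$sites[, c("position", "strand", "rpm")],
             by = c("position", "strand"), all = TRUE,
             suffixes = c("_in", "_out"))
  m$rpm_in[is.na(m$rpm_in)] <- 0
  m$rpm_out[is.na(m$rpm_out)] <- 0
  rc <- recenter_oric(m$position, m$strand, genome)
  m$d <- rc$d
  m$orientation <- rc$orientation
  L <- genome$length
  breaks <- seq(-L / 2, L / 2, length.out = n_bins + 1)
  m$bin <- cut(m$d, breaks, include.lowest = TRUE, labels = FALSE)
  enr <- function(rows) (sum(rows$rpm_out) + 0.5) / (sum(rows$rpm_in) + 0.5)
  bins <- do.call(rbind, lapply(seq_len(n_bins), function(b) {
    rows <- m[m$bin == b, , drop = FALSE]
    away <- rows[rows$orientation == "away", , drop = FALSE]
    toward <- rows[rows$orientation == "toward", , drop = FALSE]
    r_away <- if (nrow(away) > 0) enr(away) else NA_real_
    r_toward <- if (nrow(toward) > 0) enr(toward) else NA_real_
    data.frame(bin = b, lower = breaks[b], upper = breaks[b + 1],
               n_sites = nrow(rows),
               away_enrichment = r_away, toward_enrichment = r_toward,
               away_toward_ratio = r_away / r_toward)
  }))
  side_pref <- function(rows) {
    plus <- rows[rows$strand == "+", , drop = FALSE]
    minus <- rows[rows$strand == "-", , drop = FALSE]
    if (nrow(plus) == 0 || nrow(minus) == 0) return(NA_real_)
    enr(plus) / enr(minus)
  }
  left_pref <- side_pref(m[m$d < 0, , drop = FALSE])
  right_pref <- side_pref(m[m$d > 0, , drop = FALSE])
  strand_flips <- !is.na(left_pref) && !is.na(right_pref) &&
    sign(log(left_pref)) != 0 && sign(log(right_pref)) != 0 &&
    sign(log(left_pref)) != sign(log(right_pref))
  list(bins = bins,
       summary = list(left_pref = left_pref, right_pref = right_pref,
                      strand_flips = strand_flips))
}
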