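# Tn-seq ground-truth simulator: paired Input/Output insertion libraries on a
# circular genome, with selection that depends on gene identity, distance from
# the replication origin, and insert orientation relative to the origin.

#' Circular genome configuration for Tn-seq analysis
#'
#' @param length Genome length in bp (circular).
#' @param oric 0-based coordinate of the replication origin in `[0, length)`.
#' @param genes data.frame with columns `name`, `start`, `end`, `strand`
#'   (0-based half-open intervals within `[0, length)`).
#' @param sequence Optional genome DNA string of length `length` (needed only
#'   for read mapping fixtures).
#' @return Object of class `tn_genome`.
#' @export
tn_genome <- function(length, oric, genes, sequence = NULL) {
  stopifnot(length >= 1, oric >= 0, oric < length)
  need <- c("name", "start", "end", "strand")
  if (!is.data.frame(genes) || !all(need %in% names(genes))) {
    stop("genes must be a data.frame with columns name, start, end, strand",
         call. = FALSE)
  }
  if (any(genes$start < 0 | genes$end > length | genes$start >= genes$end)) {
    stop("gene intervals must be 0-based half-open within [0, length)",
         call. = FALSE)
  }
  if (!is.null(sequence)) {
    assert_dna(sequence, "genome sequence")
    stopifnot(nchar(sequence) == length)
  }
  structure(list(length = as.integer(length), oric = as.integer(oric),
                 genes = genes, sequence = sequence),
            class = "tn_genome")
}

#' Toy genome with evenly tiled genes
#'
#' Convenience builder for simulation studies: `n_genes` genes of
#' `gene_length` bp tiled evenly around a circular genome, with alternating
#' strands, and (optionally) a uniform-random genome sequence for mapping.
#'
#' @param length Genome length; default 1e6 bp.
#' @param oric Origin coordinate; default `length / 2`.
#' @param n_genes,gene_length Gene tiling parameters.
#' @param sequence_seed If non-NULL, generate a random genome sequence with
#'   this seed.
#' @return A [tn_genome()].
#' @export
toy_tn_genome <- function(length = 1e6, oric = length / 2, n_genes = 50,
                          gene_length = 10000, sequence_seed = NULL) {
  spacing <- floor(length / n_genes)
  stopifnot(gene_length < spacing)
  starts <- (seq_len(n_genes) - 1L) * spacing
  genes <- data.frame(name = sprintf("gene%03d", seq_len(n_genes)),
                      start = starts, end = starts + gene_length,
                      strand = rep(c("+", "-"), length.out = n_genes))
  sequence <- NULL
  if (!is.null(sequence_seed)) {
    sequence <- with_seed(sequence_seed,
                          paste(sample(BASES, length, replace = TRUE), collapse = ""))
  }
  tn_genome(length, oric, genes, sequence)
}

#' Selection model for Tn-seq output libraries
#'
#' Multiplicative per-site selection: a gene-specific factor, a copy-number
#' gradient that interpolates log-linearly from `copy_gradient` at the origin
#' to 1 at the terminus (emulating multi-fork replication), and an orientation
#' factor applied to inserts pointing away from the origin.
#'
#' @param gene_weight Named numeric vector of per-gene selection factors
#'   (genes absent from the names get 1).
#' @param copy_gradient Fold-excess of copy number at the origin relative to
#'   the terminus (>= 1 typically, must be > 0).
#' @param orientation_factor Fold-preference for away-pointing inserts (> 0).
#' @return Object of class `selection_model`.
#' @export
selection_model <- function(gene_weight = numeric(0), copy_gradient = 1,
                            orientation_factor = 1) {
  if (any(gene_weight <= 0) || copy_gradient <= 0 || orientation_factor <= 0) {
    stop("all selection factors must be > 0", call. = FALSE)
  }
  structure(list(gene_weight = gene_weight, copy_gradient = copy_gradient,
                 orientation_factor = orientation_factor),
            class = "selection_model")
}

#' Insertion library
#'
#' Mapped transposon insertion sites with read counts.
#'
#' @param position Integer vector of 0-based site coordinates.
#' @param strand Character vector over `+`/`-`.
#' @param count Non-negative integer read counts.
#' @param label Library label, e.g. `"Input"` or `"Output"`.
#' @param genome_length Optional genome length for validation.
#' @return Object of class `insertion_library`: data.frame-backed list with
#'   `sites` (`position`, `strand`, `count`) and `total_reads`.
#' @export
insertion_library <- function(position, strand, count, label = "library",
                              genome_length = NULL) {
  stopifnot(length(position) == length(strand),
            length(position) == length(count),
            all(strand %in% c("+", "-")), all(count >= 0))
  if (!is.null(genome_length) && any(position >= genome_length)) {
    stop("site positions must be < genome length", call. = FALSE)
  }
  sites <- data.frame(position = as.integer(position),
                      strand = as.character(strand),
                      count = as.integer(count))
  structure(list(label = label, sites = sites,
                 total_reads = sum(sites$count)),
            class = "insertion_library")
}

#' @export
print.insertion_library <- function(x, ...) {
  cat(sprintf("insertion_library '%s': %d sites, %d reads\n",
              x$label, nrow(x$sites), x$total_reads))
  invisible(x)
}

# Per-site selection weight under a selection model.
selection_weights <- function(position, strand, genome, selection) {
  rc <- recenter_oric(position, strand, genome)
  half <- genome$length / 2
  copy <- selection$copy_gradient ^ (1 - abs(rc$d) / half)
  orient <- ifelse(rc$orientation == "away", selection$orientation_factor, 1)
  gw <- rep(1, length(position))
  if (length(selection$gene_weight) > 0) {
    gene <- assign_genes(position, genome)
    hit <- !is.na(gene) & gene %in% names(selection$gene_weight)
    gw[hit] <- selection$gene_weight[gene[hit]]
  }
  gw * copy * orient
}

# Map site positions to gene names via interval overlap (NA outside genes).
assign_genes <- function(position, genome) {
  g <- genome$genes
  q <- IRanges::IRanges(start = position + 1L, width = 1L)
  s <- IRanges::IRanges(start = g$start + 1L, end = g$end)
  hits <- IRanges::findOverlaps(q, s, select = "first")
  g$name[hits]
}

#' Simulate paired Input/Output Tn-seq insertion libraries
#'
#' Sites are placed uniformly on both strands of the genome; Input counts are
#' multinomial with uniform site weights, and Output counts are multinomial
#' with per-site weights `input_weight * gene_weight * copy(d) *
#' orientation(strand, side of origin)` under the selection model. Both
#' libraries total exactly `depth` reads.
#'
#' @param genome A [tn_genome()].
#' @param selection A [selection_model()].
#' @param n_sites Number of distinct insertion sites (>= 1).
#' @param depth Total reads per library (>= n_sites).
#' @param seed Integer seed.
#' @return List with `input` and `output` ([insertion_library()]s over the
#'   same sites) and `truth` (per-site selection weights).
#' @export
simulate_tnseq <- function(genome, selection = selection_model(), n_sites,
                           depth, seed = 1) {
  stopifnot(inherits(genome, "tn_genome"), inherits(selection, "selection_model"))
  if (n_sites < 1) stop("n_sites must be >= 1", call. = FALSE)
  if (depth < n_sites) stop("depth must be >= n_sites", call. = FALSE)
  n_sites <- as.integer(n_sites)
  res <- with_seed(seed, {
    # keep sites clear of the linearisation point so mapping fixtures can
    # extract 25-mers without wrapping
    position <- sort(sample.int(genome$length - 30L, n_sites) - 1L)
    strand <- sample(c("+", "-"), n_sites, replace = TRUE)
    w_out <- selection_weights(position, strand, genome, selection)
    input <- as.integer(stats::rmultinom(1, depth, rep(1, n_sites)))
    output <- as.integer(stats::rmultinom(1, depth, w_out))
    list(position = position, strand = strand,
         input = input, output = output, w_out = w_out)
  })
  list(input = insertion_library(res$position, res$strand, res$input,
                                 "Input", genome$length),
       output = insertion_library(res$position, res$strand, res$output,
                                  "Output", genome$length),
       truth = data.frame(position = res$position, strand = res$strand,
                          weight = res$w_out))
}

#' Emit junction-tagged reads from an insertion library
#'
#' Produces the raw-read view of a simulated library for exercising the
#' preprocessing and mapping stages: each read is the transposon junction
#' followed by `fragment_length` bases of genome sequence starting at the
#' insertion site (reverse-complemented for minus-strand sites). With the
#' default `fragment_length = 25` (the mapper's k), the exact-prefix mapper
#' recovers the generated coordinates on both strands exactly.
#'
#' @param lib An [insertion_library()].
#' @param genome A [tn_genome()] with a sequence.
#' @param junction Junction sequence prepended to every read.
#' @param fragment_length Genomic bases after the junction.
#' @return A [read_set()] with one read per library read.
#' @export
tnseq_reads <- function(lib, genome, junction = "AAGAGACAG",
                        fragment_length = 25) {
  stopifnot(inherits(lib, "insertion_library"), inherits(genome, "tn_genome"))
  if (is.null(genome$sequence)) {
    stop("genome has no sequence; cannot emit reads", call. = FALSE)
  }
  s <- lib$sites[lib$sites$count > 0, , drop = FALSE]
  frag <- substring(genome$sequence, s$position + 1L,
                    s$position + fragment_length)
  neg <- s$strand == "-"
  frag[neg] <- dna_revcomp(frag[neg])
  reads <- rep(paste0(junction, frag), s$count)
  read_set(reads, provenance = list(generator = "tnseq_reads",
                                    label = lib$label,
                                    fragment_length = fragment_length))
}
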