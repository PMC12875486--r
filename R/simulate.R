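# Read simulators: error-prone cDNA reads over a profiling template, and
# signature-tagged VR amplicons for editing quantification. Both emit reads in
# sense space; the incorporated-base (cDNA) view is recovered downstream by
# complementation.

# Core mutator: returns an n x L character matrix of reads derived from the
# template, with the adenine-misincorporation model applied at annotated
# adenines of rows where `active` is TRUE, and uniform sequencing error
# applied everywhere.
mutate_matrix <- function(template, model, n, active = rep(TRUE, n)) {
  chars <- seq_chars(template$sequence)
  L <- length(chars)
  m <- matrix(rep(chars, each = n), nrow = n, ncol = L)
  offsets <- as.integer(names(template$contexts))
  for (i in seq_along(offsets)) {
    ctx <- template$contexts[[i]]
    p <- model_p(model, ctx)
    hit <- active & (stats::runif(n) < p)
    k <- sum(hit)
    if (k > 0) {
      spec <- model_spectrum(model, ctx)
      incorporated <- sample(names(spec), k, replace = TRUE, prob = spec)
      m[hit, offsets[i] + 1L] <- dna_complement(incorporated)
    }
  }
  if (model$seq_error > 0) {
    err <- matrix(stats::runif(n * L) < model$seq_error, nrow = n)
    idx <- which(err)
    if (length(idx) > 0) {
      cur <- m[idx]
      # uniform over the three other bases
      shift <- sample.int(3L, length(idx), replace = TRUE)
      pos <- (match(cur, BASES) - 1L + shift) %% 4L + 1L
      m[idx] <- BASES[pos]
    }
  }
  m
}

collapse_rows <- function(m) do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))

#' Simulate error-prone cDNA reads over a template
#'
#' Each read is the template sequence with, independently at each annotated
#' adenine, probability `p_ctx` of carrying the sense-space complement of a
#' spectrum-drawn incorporated base (cognate T maps back to sense A);
#' every position is additionally subject to the model's uniform sequencing
#' error. Deterministic given `(template, model, n, seed)`.
#'
#' @param template A [template_repeat()].
#' @param model A [misincorporation_model()].
#' @param n Number of reads (>= 1).
#' @param seed Integer seed.
#' @return A [read_set()] of `n` reads, sense orientation.
#' @export
simulate_cdna_reads <- function(template, model, n, seed = 1) {
  stopifnot(inherits(template, "template_repeat"),
            inherits(model, "misincorporation_model"))
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  n <- as.integer(n)
  m <- with_seed(seed, mutate_matrix(template, model, n))
  read_set(collapse_rows(m),
           provenance = list(generator = "simulate_cdna_reads",
                             template = template$id, n = n, seed = seed))
}

#' Simulate signature-tagged VR amplicons
#'
#' Emulates deep sequencing of a target (VR) region in a population where a
#' fraction of molecules have undergone DGR editing. An edited read carries
#' the signature alt base and adenine mutations drawn from the model; an
#' unedited read carries only sequencing error. The number of edited reads is
#' drawn as Binomial(`n`, `editing_fraction`) under the seed, and edited
#' status is assigned to a random subset of reads.
#'
#' @param vr_ref A [template_repeat()] for the unedited VR reference.
#' @param editing_fraction Probability in \[0,1\] that a molecule is edited.
#' @param model A [misincorporation_model()] for the edited reads.
#' @param signature A [signature_spec()]; its position must lie inside the
#'   reference.
#' @param n Number of reads.
#' @param seed Integer seed.
#' @return A [read_set()]; the logical vector of true edited states is kept in
#'   `provenance$edited` for ground-truth checks.
#' @export
simulate_vr_amplicons <- function(vr_ref, editing_fraction, model, signature,
                                  n, seed = 1) {
  stopifnot(inherits(vr_ref, "template_repeat"),
            inherits(model, "misincorporation_model"),
            inherits(signature, "signature_spec"))
  if (editing_fraction < 0 || editing_fraction > 1) {
    stop("editing_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (signature$position >= nchar(vr_ref$sequence)) {
    stop("signature position lies outside the reference", call. = FALSE)
  }
  n <- as.integer(n)
  res <- with_seed(seed, {
    k <- stats::rbinom(1L, n, editing_fraction)
    edited <- rep(FALSE, n)
    if (k > 0) edited[sample.int(n, k)] <- TRUE
    m <- mutate_matrix(vr_ref, model, n, active = edited)
    m[edited, signature$position + 1L] <- signature$alt_base
    list(reads = collapse_rows(m), edited = edited)
  })
  read_set(res$reads,
           provenance = list(generator = "simulate_vr_amplicons",
                             template = vr_ref$id,
                             editing_fraction = editing_fraction,
                             n = n, seed = seed, edited = res$edited))
}
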