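# Exact analytic model of codon outcomes under adenine-specific mutagenesis.
#
# Each adenine of a codon independently mutates with probability p; conditional
# on mutation it becomes one of the three other bases according to a
# sense-space substitution spectrum (uniform by default, i.e. each specific
# substitution occurs at rate p/3). Non-adenine positions never change.

uniform_sense_spectrum <- c(C = 1, G = 1, T = 1) / 3

normalize_sense_spectrum <- function(spectrum) {
  if (is.null(names(spectrum)) || !all(names(spectrum) %in% c("C", "G", "T")) ||
      any(spectrum < 0) || sum(spectrum) <= 0) {
    stop("spectrum must be a non-negative named vector over {C,G,T} (sense space)",
         call. = FALSE)
  }
  full <- c(C = 0, G = 0, T = 0)
  full[names(spectrum)] <- spectrum
  full / sum(full)
}

#' Convert an incorporated-base (cDNA) spectrum to sense space
#'
#' The conditional misincorporation spectrum is naturally measured in
#' incorporated-base space over `{A, C, G}` (cognate T). A sense-space
#' substitution spectrum over `{T, G, C}` is its complement: incorporated
#' A -> sense T, C -> sense G, G -> sense C.
#'
#' @param spectrum Named numeric vector over a subset of `c("A","C","G")`.
#' @return Named numeric vector over `c("C","G","T")`, normalised.
#' @export
sense_spectrum <- function(spectrum) {
  if (is.null(names(spectrum)) || !all(names(spectrum) %in% c("A", "C", "G"))) {
    stop("incorporated-base spectrum must be named over {A,C,G}", call. = FALSE)
  }
  names(spectrum) <- dna_complement(names(spectrum))
  normalize_sense_spectrum(spectrum)
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Exact codon-fate distribution under the adenine-mutation model
#'
#' Enumerates all `4^k` outcomes (`k` = number of adenines in the codon),
#' assuming independence across adenines and zero mutation elsewhere, and
#' returns the exact probability distribution over outcome codons and its
#' push-forward to amino acids (with `*` for stops) under the standard
#' genetic code.
#'
#' @param codon DNA triplet over `{A,C,G,T}`.
#' @param p Per-adenine mutation probability in \[0,1\].
#' @param spectrum Sense-space substitution spectrum over `{C,G,T}`
#'   (conditional on mutation); default uniform, each substitution `p/3`.
#'   Use [sense_spectrum()] to convert a spectrum measured in
#'   incorporated-base space.
#' @return Object of class `codon_fate_table`: list with `codon`, `p`,
#'   `spectrum`, `outcome_codons` (named probabilities summing to 1) and
#'   `outcome_aas`.
#' @examples
#' ft <- codon_fate("AAG", p = 0.3065)
#' ft$outcome_codons["TAG"]  # ~ 0.0709
#' @export
codon_fate <- function(codon, p = 0.3065, spectrum = uniform_sense_spectrum) {
  if (!is.character(codon) || length(codon) != 1 || nchar(codon) != 3 ||
      grepl("[^ACGT]", codon)) {
    stop("codon must be a DNA triplet over {A,C,G,T}", call. = FALSE)
  }
  if (p < 0 || p > 1) stop("p must lie in [0, 1]", call. = FALSE)
  spectrum <- normalize_sense_spectrum(spectrum)
  chars <- seq_chars(codon)
  per_pos <- lapply(chars, function(b) {
    if (b == "A") {
      c(A = 1 - p, p * spectrum)[BASES]
    } else {
      stats::setNames(as.numeric(BASES == b), BASES)
    }
  })
  grid <- expand.grid(BASES, BASES, BASES, stringsAsFactors = FALSE)
  outcomes <- paste0(grid[[1]], grid[[2]], grid[[3]])
  probs <- per_pos[[1]][grid[[1]]] * per_pos[[2]][grid[[2]]] * per_pos[[3]][grid[[3]]]
  names(probs) <- outcomes
  probs <- probs[probs > 0 | outcomes == codon]
  aas <- unname(Biostrings::GENETIC_CODE[names(probs)])
  outcome_aas <- tapply(probs, aas, sum)
  structure(list(codon = codon, p = p, spectrum = spectrum,
                 outcome_codons = probs,
                 outcome_aas = outcome_aas[order(-outcome_aas)]),
            class = "codon_fate_table")
}

#' @export
print.codon_fate_table <- function(x, ...) {
  cat(sprintf("codon_fate_table: %s, p = %.4g\n", x$codon, x$p))
  top <- sort(x$outcome_codons, decreasing = TRUE)
  top <- top[seq_len(min(8, length(top)))]
  for (i in seq_along(top)) {
    cat(sprintf("  %s -> %s  %.4f%%\n", x$codon, names(top)[i], 100 * top[i]))
  }
  invisible(x)
}

#' Probability that a codon converts to any stop codon
#'
#' @inheritParams codon_fate
#' @return Total probability over outcomes TAA, TAG, TGA.
#' @examples
#' stop_conversion("AAA", p = 0.3065)  # ~ 0.0636
#' @export
stop_conversion <- function(codon, p = 0.3065, spectrum = uniform_sense_spectrum) {
  ft <- codon_fate(codon, p, spectrum)
  sum(ft$outcome_codons[intersect(STOP_CODONS, names(ft$outcome_codons))])
}

#' Amino acids accessible from a codon by mutating its adenines
#'
#' Enumerates every codon obtained by substituting the mutable positions
#' (default: adenines) with all four bases, and translates them with the
#' standard genetic code.
#'
#' @param codon DNA triplet.
#' @param mutable_base The base whose positions are mutable; default `"A"`.
#' @return List with `reachable` (distinct amino acids over all outcomes,
#'   source included, stops excluded), `reachable_excluding_source` (the same
#'   minus the source amino acid), and `stop_codons` (reachable stop codons;
#'   empty when no stop is accessible).
#' @examples
#' accessible_amino_acids("AAC")  # 15 amino acids, no stops
#' @export
accessible_amino_acids <- function(codon, mutable_base = "A") {
  if (!is.character(codon) || length(codon) != 1 || nchar(codon) != 3 ||
      grepl("[^ACGT]", codon)) {
    stop("codon must be a DNA triplet over {A,C,G,T}", call. = FALSE)
  }
  chars <- seq_chars(codon)
  mut_pos <- which(chars == mutable_base)
  choices <- lapply(seq_len(3), function(i) {
    if (i %in% mut_pos) BASES else chars[i]
  })
  grid <- expand.grid(choices, stringsAsFactors = FALSE)
  outcomes <- unique(do.call(paste0, grid))
  aas <- unname(Biostrings::GENETIC_CODE[outcomes])
  source_aa <- unname(Biostrings::GENETIC_CODE[codon])
  reachable <- sort(unique(aas[aas != "*"]))
  list(source_aa = source_aa,
       reachable = reachable,
       reachable_excluding_source = setdiff(reachable, source_aa),
       stop_codons = sort(outcomes[aas == "*"]))
}

#' Compare an observed stop-conversion rate with the uniform-spectrum expectation
#'
#' Pure arithmetic (no test statistic): the expectation under a uniform
#' substitution spectrum, the observed rate, and their ratio.
#'
#' @param observed_rate Observed stop-conversion rate in \[0,1\].
#' @param codon Source codon.
#' @param p Per-adenine mutation probability.
#' @return List with `expected`, `observed`, `ratio`.
#' @export
expected_vs_observed_stop <- function(observed_rate, codon, p = 0.3065) {
  if (observed_rate < 0 || observed_rate > 1) {
    stop("observed_rate must lie in [0, 1]", call. = FALSE)
  }
  expected <- stop_conversion(codon, p, uniform_sense_spectrum)
  list(expected = expected, observed = observed_rate,
       ratio = if (expected > 0) observed_rate / expected else NA_real_)
}
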