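#' Adenine misincorporation model
#'
#' Ground truth for the read simulators and the estimation target of the
#' context profiler. At each template adenine the error-prone reverse
#' transcriptase misincorporates with probability `p` (possibly
#' context-specific); conditional on a misincorporation, the incorporated cDNA
#' base is drawn from a spectrum over `{A, C, G}` (the cognate incorporation
#' opposite adenine is T). Reads are emitted in sense space, so an incorporated
#' base appears in the read as its complement (incorporated C -> sense G,
#' G -> sense C, A -> sense T).
#'
#' @param p Per-adenine misincorporation probability: either a single number
#'   applied to every context, or a named vector keyed by NAN context
#'   (contexts absent from the names get 0).
#' @param spectrum Conditional incorporated-base spectrum: a named numeric
#'   vector over some subset of `c("A","C","G")` (normalised to sum to 1), or
#'   a named list of such vectors keyed by context.
#' @param seq_error Per-base uniform sequencing-error probability (a wrong
#'   base is drawn uniformly from the other three).
#' @return Object of class `misincorporation_model`.
#' @examples
#' # the in-vivo profile: p = 0.3065, C:G:A = 0.593:0.264:0.143
#' misincorporation_model(0.3065, c(C = 0.593, G = 0.264, A = 0.143))
#' @export
misincorporation_model <- function(p = 0.3065,
                                   spectrum = c(A = 1, C = 1, G = 1) / 3,
                                   seq_error = 0) {
  if (any(p < 0 | p > 1) || seq_error < 0 || seq_error > 1) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (length(p) > 1 && is.null(names(p))) {
    stop("context-specific p must be a named vector", call. = FALSE)
  }
  norm_spec <- function(s) {
    if (is.null(names(s)) || !all(names(s) %in% c("A", "C", "G")) ||
        any(s < 0) || sum(s) <= 0) {
      stop("spectrum must be a non-negative named vector over {A,C,G}",
           call. = FALSE)
    }
    full <- c(A = 0, C = 0, G = 0)
    full[names(s)] <- s
    full / sum(full)
  }
  spectrum <- if (is.list(spectrum)) lapply(spectrum, norm_spec) else norm_spec(spectrum)
  structure(list(p = p, spectrum = spectrum, seq_error = seq_error),
            class = "misincorporation_model")
}

# Per-context accessors -------------------------------------------------------

model_p <- function(model, context) {
  if (length(model$p) == 1 && is.null(names(model$p))) {
    rep(unname(model$p), length(context))
  } else {
    out <- model$p[context]
    out[is.na(out)] <- 0
    unname(out)
  }
}

model_spectrum <- function(model, context) {
  if (!is.list(model$spectrum)) return(model$spectrum)
  s <- model$spectrum[[context]]
  if (is.null(s)) c(A = 0, C = 0, G = 0) + c(A = 1, C = 1, G = 1) / 3 else s
}

#' @export
print.misincorporation_model <- function(x, ...) {
  if (length(x$p) == 1 && is.null(names(x$p))) {
    cat(sprintf("misincorporation_model: p = %.4g (all contexts)", x$p))
  } else {
    cat(sprintf("misincorporation_model: context-specific p (%d contexts)",
                length(x$p)))
  }
  cat(sprintf(", seq_error = %.3g\n", x$seq_error))
  invisible(x)
}
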