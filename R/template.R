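#' Template repeat with annotated adenine contexts
#'
#' A `template_repeat` holds a reference template (TR) or variable-repeat (VR)
#' sequence in sense (coding) orientation together with the 0-based offsets of
#' its adenines and, for every *interior* adenine (one with both neighbours),
#' its NAN trinucleotide context written 5'->3'.
#'
#' The context convention follows standard DGR usage: for a triplet `XAY`
#' (5'->3'), `X` is the +1 base (immediately 5' of the adenine) and `Y` is the
#' -1 base (immediately 3'). Edge adenines carry no context and are excluded
#' from context tallies, but still appear in position probability matrices.
#'
#' @param sequence DNA string over `{A,C,G,T}`, sense orientation, length >= 3.
#' @param id Template identifier.
#' @return An object of class `template_repeat`: a list with `id`, `sequence`,
#'   `adenine_positions` (0-based offsets of every A), and `contexts` (named
#'   integer vector: context triplet per interior adenine offset).
#' @examples
#' tr <- template_repeat("GCAACG", id = "toy")
#' tr$contexts  # both interior adenines annotated
#' @export
template_repeat <- function(sequence, id = "template") {
  assert_dna(sequence)
  if (nchar(sequence) < 3) stop("sequence length must be >= 3", call. = FALSE)
  chars <- seq_chars(sequence)
  a_pos <- which(chars == "A") - 1L  # 0-based
  interior <- a_pos[a_pos >= 1L & a_pos <= nchar(sequence) - 2L]
  ctx <- vapply(interior, function(p) {
    substr(sequence, p, p + 2L)  # p is 0-based -> 1-based (p) .. (p+2)
  }, character(1))
  names(ctx) <- as.character(interior)
  structure(
    list(id = id, sequence = sequence,
         adenine_positions = a_pos, contexts = ctx),
    class = "template_repeat"
  )
}

#' @export
print.template_repeat <- function(x, ...) {
  cat(sprintf("template_repeat '%s': %d nt, %d adenines (%d with context)\n",
              x$id, nchar(x$sequence), length(x$adenine_positions),
              length(x$contexts)))
  cat(" ", x$sequence, "\n")
  invisible(x)
}

#' Census of adenine contexts in a template
#'
#' Counts how many annotated adenines fall in each NAN context.
#'
#' @param template A [template_repeat()].
#' @return Named integer vector (context -> number of occurrences), sorted by
#'   context.
#' @export
context_census <- function(template) {
  stopifnot(inherits(template, "template_repeat"))
  tab <- table(template$contexts)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out[order(names(out))]
}

#' All 16 NAN trinucleotide contexts
#'
#' @return Character vector of the 16 possible adenine contexts, sorted.
#' @export
nan_contexts <- function() {
  sort(as.vector(outer(BASES, BASES, function(x, y) paste0(x, "A", y))))
}

#' Designed signature mutation
#'
#' A designed template/target difference (canonically G-to-T a fixed distance
#' 5' of the GC14 landmark) whose co-transfer with adenine mutations
#' distinguishes DGR-mediated edits from spontaneous mutations.
#'
#' @param position 0-based offset of the signature site in the VR reference.
#' @param ref_base Reference (unedited) base at the site; default `"G"`.
#' @param alt_base Edited base co-transferred from the template; default `"T"`.
#' @param ref Optional [template_repeat()] used to validate that the reference
#'   actually carries `ref_base` at `position`.
#' @return Object of class `signature_spec`.
#' @export
signature_spec <- function(position, ref_base = "G", alt_base = "T", ref = NULL) {
  stopifnot(length(position) == 1, position >= 0,
            ref_base %in% BASES, alt_base %in% BASES, ref_base != alt_base)
  position <- as.integer(position)
  if (!is.null(ref)) {
    stopifnot(inherits(ref, "template_repeat"))
    if (position >= nchar(ref$sequence)) {
      stop("signature position lies outside the reference", call. = FALSE)
    }
    have <- substr(ref$sequence, position + 1L, position + 1L)
    if (have != ref_base) {
      stop(sprintf("reference carries %s at signature position %d, expected %s",
                   have, position, ref_base), call. = FALSE)
    }
  }
  structure(list(position = position, ref_base = ref_base, alt_base = alt_base),
            class = "signature_spec")
}
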