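# Synthetic template designers: a 16-context NAN template for error profiling
# and an AAC-rich VR-style reporter with a designed signature site.

SPACER_POLICIES <- list(
  gc = "GC",  # default: 2-bp non-A spacer between consecutive triplets
  c  = "C"    # minimal 1-bp spacer
)

#' Design a template realizing all 16 NAN adenine contexts
#'
#' Builds a synthetic template-repeat sequence containing every possible NAN
#' trinucleotide (an adenine with each combination of 5' and 3' neighbours) at
#' least once, in a seed-determined order. Triplets are separated by non-A
#' spacer bases so that no adenine outside the designed triplets is created;
#' adenines *inside* AAN/NAA triplets necessarily pick up additional contexts
#' (with the default policy these are CAA and AAG, both members of the 16-key
#' census), and are annotated and analysed like any other adenine.
#'
#' Different `order_seed`s permute the triplet order while preserving the
#' context multiset, emulating template variants that decouple local context
#' from broader positional effects.
#'
#' @param order_seed Integer seed controlling the triplet order.
#' @param spacer_policy Name of a built-in spacer policy: `"gc"` (default,
#'   2-bp `GC` spacer) or `"c"` (1-bp `C` spacer).
#' @return A [template_repeat()] whose context census covers all 16 NAN keys.
#' @examples
#' tr <- design_nan_template(order_seed = 1)
#' length(unique(tr$contexts))  # 16
#' @export
design_nan_template <- function(order_seed = 1, spacer_policy = "gc") {
  if (!spacer_policy %in% names(SPACER_POLICIES)) {
    stop("unknown spacer_policy '", spacer_policy, "'; available: ",
         paste(names(SPACER_POLICIES), collapse = ", "), call. = FALSE)
  }
  spacer <- SPACER_POLICIES[[spacer_policy]]
  triplets <- with_seed(order_seed, sample(nan_contexts()))
  seq <- paste0(spacer, paste(triplets, collapse = spacer), spacer)
  template_repeat(seq, id = sprintf("NAN16-%d-%s", order_seed, spacer_policy))
}

#' Design a synthetic AAC-rich VR reporter with a signature site
#'
#' Constructs a synthetic variable-repeat reporter for editing quantification:
#' 18 adenines arranged in highly mutable AAC-containing motifs, flanked by
#' A-free ends, plus a designed G site whose conversion to T (co-transferred
#' from the matching template) marks a read as DGR-edited. The sequence is a
#' synthetic stand-in with the same design logic as an 18-adenine reporter,
#' not a natural VR.
#'
#' @return List with `template` (a [template_repeat()], 18 adenines) and
#'   `signature` (a [signature_spec()]: G-to-T at offset 3).
#' @export
design_vr_reporter <- function() {
  seq <- paste0("GCTG", strrep("AACG", 9L), "CTGC")
  tr <- template_repeat(seq, id = "VRsyn18")
  stopifnot(length(tr$adenine_positions) == 18L)
  list(template = tr,
       signature = signature_spec(3L, ref_base = "G", alt_base = "T", ref = tr))
}
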