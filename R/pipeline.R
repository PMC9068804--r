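# Rule-based triage of an intronic variant into a splicing-event hypothesis,
# and the end-to-end annotation wrapper.

#' Hypothesize the splicing outcome of an intronic variant
#'
#' Applies the proximal-intronic prioritization rules observed for cryptic
#' splice-altering variants:
#' \enumerate{
#'   \item a variant creating an AG dinucleotide that breaks the
#'     AG-exclusion zone is predicted to act as a cryptic splice acceptor:
#'     partial retention of the intron 3' segment (equivalently, extension of
#'     the downstream exon) ending at the created AG;
#'   \item otherwise, an acceptor-side variant inside the branchpoint window
#'     (-37..-19) is predicted to impair branchpoint recognition and cause
#'     complete retention of the intron;
#'   \item anything else is predicted canonical (deep-intronic pseudo-exon
#'     activation is not discovered de novo).
#' }
#'
#' @param gene A `GeneModel`.
#' @param variant A `Variant`.
#' @return A `SpliceEvent`.
#' @export
hypothesize_event <- function(gene, variant) {
  v <- resolve_variant(gene, variant)
  off <- v$pos$offset
  if (off >= 0L) return(splice_event("canonical"))
  aez <- scan_aez(gene, v)
  if (aez$breaks_aez) {
    g <- c_to_genomic(gene, hgvs_coding_position(v$pos$anchor, aez$created_ag_offset))
    return(splice_event("pRi", aez$intron_index, cryptic_acceptor = g))
  }
  if (branch_window(v)$in_window)
    return(splice_event("cRi", aez$intron_index))
  splice_event("canonical")
}

#' Annotate an intronic variant end to end
#'
#' Runs the full interpretation pipeline: cis-element scans, splicing-event
#' hypothesis, reconstruction of the reference and aberrant transcripts, and
#' reading-frame/PTC/NMD consequence classification.
#'
#' @param gene A `GeneModel`.
#' @param variant A `Variant` or HGVS c. string.
#' @param events Optional explicit `SpliceEvent`(s) overriding the hypothesis
#'   (e.g. events established experimentally or taken from prior studies).
#' @return A `VariantAnnotation` list: `variant`, `event`, `aez`, `branch`,
#'   `reference`, `altered`, `consequence`.
#' @examples
#' g <- synth_gene(seed = 4)
#' pl <- plant_lesion(g, "aez_break", seed = 9)
#' ann <- annotate_variant(g, pl$variant)
#' ann$consequence$label
#' @export
annotate_variant <- function(gene, variant, events = NULL) {
  if (is.character(variant)) variant <- parse_hgvs_c(variant)
  v <- resolve_variant(gene, variant)
  acceptor_side <- v$pos$offset < 0L
  aez <- if (acceptor_side) scan_aez(gene, v) else NULL
  bw <- if (acceptor_side) branch_window(v) else NULL
  event <- if (is.null(events)) hypothesize_event(gene, v) else events
  reference <- reconstruct_transcript(gene)
  altered <- reconstruct_transcript(gene, event, variant = v)
  consequence <- classify_consequence(reference, altered)
  structure(list(variant = v, event = event, aez = aez, branch = bw,
                 reference = reference, altered = altered,
                 consequence = consequence),
            class = "VariantAnnotation")
}

#' @export
print.VariantAnnotation <- function(x, ...) {
  ev <- if (inherits(x$event, "SpliceEvent")) list(x$event) else x$event
  cat(sprintf("VariantAnnotation %s -> %s -> %s\n", x$variant$name,
              paste(vapply(ev, function(e) e$kind, ""), collapse = "+"),
              x$consequence$label))
  invisible(x)
}
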