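#' Classify the reading-frame consequence of an aberrant transcript
#'
#' Translates both transcripts from their initiation codons and compares the
#' open reading frames.  A stop codon appearing upstream of where the
#' reference stop maps onto the altered transcript is a premature termination
#' codon (PTC): the class is `frameshift_PTC` when the net length change is
#' not a multiple of 3, `stop_gain_PTC` when it is (a stop introduced by
#' in-frame retained/inserted sequence).  In-frame changes are sized in amino
#' acids by longest common prefix/suffix of the two proteins.  A transcript
#' whose frame reads through the natural stop is `stop_loss`.  For PTC
#' classes, nonsense-mediated decay (NMD) sensitivity is called with
#' [nmd_call()].
#'
#' @param reference,altered `MatureTranscript`s sharing the same initiation
#'   codon context (e.g. canonical vs event-bearing reconstructions of one
#'   gene).
#' @param junction_rule_nt NMD exon-junction rule distance passed to
#'   [nmd_call()].
#' @return A `ConsequenceCall`: list with `category`, `ptc_position` (first
#'   base of the new stop codon, transcript coordinate), `aa_deleted`,
#'   `aa_inserted`, `nmd_sensitive`, `junctions_downstream_of_ptc`, `label`.
#' @export
classify_consequence <- function(reference, altered, junction_rule_nt = 50L) {
  stopifnot(inherits(reference, "MatureTranscript"), inherits(altered, "MatureTranscript"))
  p_ref <- translate_orf(substr(reference$sequence, reference$cds_start,
                                nchar(reference$sequence)))
  if (is.na(attr(p_ref, "stop_codon")))
    stop_sl("sl_validation", "reference transcript has no in-frame stop codon")
  p_alt <- translate_orf(substr(altered$sequence, altered$cds_start,
                                nchar(altered$sequence)))
  delta <- nchar(altered$sequence) - nchar(reference$sequence)
  frameshift <- (delta %% 3L) != 0L

  ref_stop_t <- reference$cds_start + attr(p_ref, "stop_codon") - 1L
  mapped_stop_t <- ref_stop_t + delta      # where the natural stop maps
  alt_stop_t <- if (is.na(attr(p_alt, "stop_codon"))) NA_integer_
                else altered$cds_start + attr(p_alt, "stop_codon") - 1L

  call <- list(category = NA_character_, ptc_position = NA_integer_,
               aa_deleted = 0L, aa_inserted = 0L, nmd_sensitive = FALSE,
               junctions_downstream_of_ptc = 0L, label = NA_character_)

  if (is.na(alt_stop_t) || alt_stop_t > mapped_stop_t) {
    call$category <- "stop_loss"
    call$label <- if (frameshift) "Frameshift-stop loss" else "Stop loss"
  } else if (alt_stop_t < mapped_stop_t) {
    call$category <- if (frameshift) "frameshift_PTC" else "stop_gain_PTC"
    call$ptc_position <- alt_stop_t
    call$label <- if (frameshift) "Frameshift-PTC" else "Stop gain-PTC"
  } else if (frameshift) {
    # frame changed yet the stop lands exactly where the natural one maps:
    # the protein tail is aberrant, so treat as a frameshift PTC at that stop
    call$category <- "frameshift_PTC"
    call$ptc_position <- alt_stop_t
    call$label <- "Frameshift-PTC"
  } else if (identical(as.character(p_ref), as.character(p_alt))) {
    call$category <- "no_change"
    call$label <- "No change"
  } else {
    nr <- nchar(p_ref); na <- nchar(p_alt)
    ra <- strsplit(as.character(p_ref), "")[[1L]]
    aa <- strsplit(as.character(p_alt), "")[[1L]]
    nmin <- min(nr, na)
    pre <- 0L
    while (pre < nmin && ra[pre + 1L] == aa[pre + 1L]) pre <- pre + 1L
    suf <- 0L
    while (suf < nmin - pre && ra[nr - suf] == aa[na - suf]) suf <- suf + 1L
    call$aa_deleted <- nr - pre - suf
    call$aa_inserted <- na - pre - suf
    call$category <- if (call$aa_deleted > 0L && call$aa_inserted == 0L) "in_frame_del"
                     else if (call$aa_deleted == 0L && call$aa_inserted > 0L) "in_frame_ins"
                     else "in_frame_delins"
    call$label <- switch(call$category,
      in_frame_del    = sprintf("In-frame (del %d aa)", call$aa_deleted),
      in_frame_ins    = sprintf("In-frame (ins %d aa)", call$aa_inserted),
      in_frame_delins = sprintf("In-frame (ins %d aa, del %d aa)",
                                call$aa_inserted, call$aa_deleted))
  }

  if (!is.na(call$ptc_position)) {
    nmd <- nmd_call(altered, call$ptc_position, junction_rule_nt)
    call$nmd_sensitive <- nmd$nmd_sensitive
    call$junctions_downstream_of_ptc <- nmd$junctions_downstream
  }
  structure(call, class = "ConsequenceCall")
}

#' @export
print.ConsequenceCall <- function(x, ...) {
  cat(sprintf("ConsequenceCall: %s%s%s\n", x$label,
              if (!is.na(x$ptc_position))
                sprintf(" (PTC at %d, %d junction(s) downstream)",
                        x$ptc_position, x$junctions_downstream_of_ptc) else "",
              if (isTRUE(x$nmd_sensitive)) ", NMD-sensitive" else ""))
  invisible(x)
}

#' Exon-junction rule call for nonsense-mediated decay
#'
#' A PTC is called NMD-sensitive when its stop codon ends at least
#' `junction_rule_nt` nucleotides (default 50, the field-standard 50-55 nt
#' rule) upstream of the final exon-exon junction.  The number of junctions
#' strictly downstream of the PTC is reported alongside.
#'
#' @param transcript A `MatureTranscript`.
#' @param ptc_position Transcript coordinate of the first base of the stop
#'   codon.
#' @param junction_rule_nt Minimum distance (nt) between the end of the stop
#'   codon and the last junction.
#' @return List with `nmd_sensitive`, `junctions_downstream` and
#'   `distance_to_last_junction` (NA when no junction is downstream).
#' @export
nmd_call <- function(transcript, ptc_position, junction_rule_nt = 50L) {
  stopifnot(inherits(transcript, "MatureTranscript"))
  ptc_position <- as.integer(ptc_position)
  if (ptc_position >= nchar(transcript$sequence))
    stop_sl("sl_range", "PTC position beyond the transcript")
  ptc_end <- ptc_position + 2L
  down <- transcript$junctions[transcript$junctions >= ptc_end]
  if (!length(down))
    return(list(nmd_sensitive = FALSE, junctions_downstream = 0L,
                distance_to_last_junction = NA_integer_))
  d <- max(down) - ptc_end
  list(nmd_sensitive = d >= junction_rule_nt,
       junctions_downstream = length(down),
       distance_to_last_junction = d)
}

#' Combine ACMG/AMP evidence codes into a classification
#'
#' Applies the published combining rules for sequence-variant interpretation
#' (pathogenic / likely pathogenic / uncertain significance / likely benign /
#' benign) to a set of evidence codes such as PVS1, PS1-PS4, PM1-PM6,
#' PP1-PP5, BA1, BS1-BS4 and BP1-BP7.
#'
#' @param evidence Character vector of evidence codes (duplicates ignored).
#' @return One of `"pathogenic"`, `"likely pathogenic"`,
#'   `"uncertain significance"`, `"likely benign"`, `"benign"`.
#' @examples
#' combine_acmg(c("PS3", "PM2", "PP1"))   # "likely pathogenic"
#' @export
combine_acmg <- function(evidence) {
  evidence <- unique(toupper(as.character(evidence)))
  valid <- c("PVS1", paste0("PS", 1:4), paste0("PM", 1:6), paste0("PP", 1:5),
             "BA1", paste0("BS", 1:4), paste0("BP", 1:7))
  bad <- setdiff(evidence, valid)
  if (length(bad))
    stop_sl("sl_validation", sprintf("unknown ACMG evidence code(s): %s",
                                     paste(bad, collapse = ", ")))
  pvs <- sum(evidence == "PVS1")
  ps  <- sum(grepl("^PS", evidence))
  pm  <- sum(grepl("^PM", evidence))
  pp  <- sum(grepl("^PP", evidence))
  ba  <- sum(evidence == "BA1")
  bs  <- sum(grepl("^BS", evidence))
  bp  <- sum(grepl("^BP", evidence))

  pathogenic <-
    (pvs >= 1L && (ps >= 1L || pm >= 2L || (pm == 1L && pp == 1L) || pp >= 2L)) ||
    ps >= 2L ||
    (ps == 1L && (pm >= 3L || (pm == 2L && pp >= 2L) || (pm == 1L && pp >= 4L)))
  likely_pathogenic <-
    (pvs == 1L && pm == 1L) ||
    (ps == 1L && pm >= 1L && pm <= 2L) ||
    (ps == 1L && pp >= 2L) ||
    pm >= 3L ||
    (pm == 2L && pp >= 2L) ||
    (pm == 1L && pp >= 4L)
  benign <- ba >= 1L || bs >= 2L
  likely_benign <- (bs == 1L && bp >= 1L) || bp >= 2L

  path_side <- pathogenic || likely_pathogenic
  ben_side <- benign || likely_benign
  if (path_side && ben_side) return("uncertain significance")
  if (pathogenic) return("pathogenic")
  if (likely_pathogenic) return("likely pathogenic")
  if (benign) return("benign")
  if (likely_benign) return("likely benign")
  "uncertain significance"
}

#' Normalize a deduced-effect label to ASCII
#'
#' Published tables print these labels with typographic dashes and minus
#' signs; this maps them onto the package's ASCII vocabulary (e.g.
#' `"Frameshift—PTC"` -> `"Frameshift-PTC"`) for comparison.
#'
#' @param x Character vector of labels.
#' @export
normalize_trf_label <- function(x) {
  x <- gsub("—|–|−", "-", x)
  trimws(gsub("[ ]*-[ ]*", "-", x))
}
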