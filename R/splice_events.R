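#' Splicing-outcome events
#'
#' Constructs a `SpliceEvent` describing one splicing outcome in the standard
#' taxonomy: `canonical`, `exon_skip` (Esk), `exon_truncation` (Etr),
#' `exon_extension` (Eext), `intron_retention_complete` (cRi),
#' `intron_retention_partial` (pRi) and `cryptic_exon_insertion` (crypEins).
#' Short aliases are accepted for `kind`.
#'
#' Cryptic splice sites are given as plus-strand genomic coordinates of the
#' dinucleotide base nearest the spliced boundary: for a cryptic acceptor, the
#' G of the AG (the retained/included segment starts at the next sense
#' nucleotide); for a cryptic donor, the G of the GT (the retained/included
#' segment ends at the previous sense nucleotide).
#'
#' @param kind Event kind (full name or alias).
#' @param target_index Exon number (Esk/Etr/Eext) or intron number
#'   (cRi/pRi/crypEins), 1-based in transcript order.
#' @param cryptic_donor,cryptic_acceptor Genomic coordinates of cryptic sites,
#'   where required: pRi needs exactly one of the two; crypEins needs both;
#'   Etr/Eext need one.
#' @return A `SpliceEvent`.
#' @export
splice_event <- function(kind, target_index = NA_integer_,
                         cryptic_donor = NULL, cryptic_acceptor = NULL) {
  alias <- c(Esk = "exon_skip", Etr = "exon_truncation", Eext = "exon_extension",
             cRi = "intron_retention_complete", pRi = "intron_retention_partial",
             crypEins = "cryptic_exon_insertion")
  if (kind %in% names(alias)) kind <- alias[[kind]]
  kinds <- c("canonical", unname(alias))
  if (!kind %in% kinds)
    stop_sl("sl_validation", sprintf("unknown splice event kind '%s'", kind))
  nd <- !is.null(cryptic_donor); na <- !is.null(cryptic_acceptor)
  if (kind == "intron_retention_partial" && (nd + na) != 1L)
    stop_sl("sl_validation", "partial intron retention requires exactly one cryptic site")
  if (kind == "cryptic_exon_insertion" && !(nd && na))
    stop_sl("sl_validation", "cryptic exon insertion requires both cryptic donor and acceptor")
  if (kind %in% c("exon_truncation", "exon_extension") && (nd + na) != 1L)
    stop_sl("sl_validation", sprintf("%s requires exactly one cryptic site", kind))
  if (kind != "canonical" && !is_count(target_index))
    stop_sl("sl_validation", "target_index must be a positive integer")
  structure(list(kind = kind, target_index = as.integer(target_index),
                 cryptic_donor = if (nd) as.integer(cryptic_donor) else NULL,
                 cryptic_acceptor = if (na) as.integer(cryptic_acceptor) else NULL),
            class = "SpliceEvent")
}

#' @export
print.SpliceEvent <- function(x, ...) {
  extra <- c(if (!is.null(x$cryptic_donor)) sprintf("donor g.%d", x$cryptic_donor),
             if (!is.null(x$cryptic_acceptor)) sprintf("acceptor g.%d", x$cryptic_acceptor))
  cat(sprintf("SpliceEvent %s(%s)%s\n", x$kind,
              ifelse(is.na(x$target_index), "", x$target_index),
              if (length(extra)) paste0(" [", paste(extra, collapse = ", "), "]") else ""))
  invisible(x)
}

#' Mature transcript with junction positions
#'
#' @param sequence Nucleotide string, 5'->3' on the mRNA sense strand.
#' @param junctions Transcript coordinates of exon-exon junctions; each value
#'   is the position of the last nucleotide before the junction.
#' @param cds_start Transcript coordinate of the first base of the initiation
#'   codon.
#' @param provenance List of `SpliceEvent`s applied (informational).
#' @export
mature_transcript <- function(sequence, junctions = integer(), cds_start = 1L,
                              provenance = list()) {
  sequence <- toupper(as.character(sequence))
  junctions <- as.integer(junctions)
  if (length(junctions) && (any(diff(junctions) <= 0L) ||
                            any(junctions < 1L) || any(junctions >= nchar(sequence))))
    stop_sl("sl_validation", "junctions must be strictly increasing and < sequence length")
  if (cds_start < 1L || cds_start > nchar(sequence))
    stop_sl("sl_validation", "cds_start outside the transcript")
  structure(list(sequence = sequence, junctions = junctions,
                 cds_start = as.integer(cds_start), provenance = provenance),
            class = "MatureTranscript")
}

#' @export
print.MatureTranscript <- function(x, ...) {
  ev <- vapply(x$provenance, function(e) e$kind, "")
  cat(sprintf("MatureTranscript: %d nt, %d junction(s), CDS from %d%s\n",
              nchar(x$sequence), length(x$junctions), x$cds_start,
              if (length(ev)) paste0(" [", paste(ev, collapse = "+"), "]") else ""))
  invisible(x)
}

# sense-linear coordinate of a plus-strand genomic position (monotone along
# the transcript reading direction)
.lin <- function(gene, g) if (gene$strand == "+") g else -g

# sense position within intron k of a plus-strand genomic coordinate
.intron_sense_pos <- function(gene, k, g) {
  iv <- intron_intervals(gene)
  if (k < 1L || k > nrow(iv)) stop_sl("sl_range", sprintf("no intron %d", k))
  if (g < iv$start[k] || g > iv$end[k])
    stop_sl("sl_range", sprintf("cryptic coordinate g.%d outside intron %d (%d..%d)",
                                g, k, iv$start[k], iv$end[k]))
  if (gene$strand == "+") g - iv$start[k] + 1L else iv$end[k] - g + 1L
}

# sense position within exon k
.exon_sense_pos <- function(gene, k, g) {
  if (g < gene$exons$start[k] || g > gene$exons$end[k])
    stop_sl("sl_range", sprintf("cryptic coordinate g.%d outside exon %d", g, k))
  if (gene$strand == "+") g - gene$exons$start[k] + 1L else gene$exons$end[k] - g + 1L
}

#' Reconstruct a mature transcript under a set of splicing events
#'
#' Applies an optional variant to the genomic sequence, then splices the
#' pre-mRNA according to `events`.  Retained intronic segments contribute
#' exon-exon junctions only at boundaries that remain spliced: complete
#' retention of intron k removes the junction it spans; partial retention via
#' a cryptic acceptor at genomic position x inserts the intron segment from
#' the nucleotide after x to the intron end (the canonical donor side being
#' spliced away); a cryptic-donor partial retention keeps the 5' intron
#' segment up to the nucleotide before the GT.
#'
#' @param gene A `GeneModel`.
#' @param events A `SpliceEvent` or list of mutually compatible events (no two
#'   events may address the same exon/intron).
#' @param variant Optional `Variant` substituted into the genomic sequence
#'   before splicing, so that retained segments carry the alternate allele.
#' @return A [mature_transcript()].
#' @examples
#' g <- synth_gene(seed = 1)
#' canon <- reconstruct_transcript(g, splice_event("canonical"))
#' cri1  <- reconstruct_transcript(g, splice_event("cRi", 1))
#' nchar(cri1$sequence) - nchar(canon$sequence)  # intron 1 length
#' @export
reconstruct_transcript <- function(gene, events = splice_event("canonical"),
                                   variant = NULL) {
  if (inherits(events, "SpliceEvent")) events <- list(events)
  if (!all(vapply(events, inherits, TRUE, what = "SpliceEvent")))
    stop_sl("sl_validation", "events must be SpliceEvent objects")
  events <- Filter(function(e) e$kind != "canonical", events)
  genome <- if (is.null(variant)) gene$sequence else apply_variant(gene, variant)
  n <- n_exons(gene)
  iv <- intron_intervals(gene)

  tgt_exon <- vapply(events, function(e)
    if (e$kind %in% c("exon_skip", "exon_truncation", "exon_extension"))
      e$target_index else NA_integer_, 1L)
  tgt_intron <- vapply(events, function(e)
    if (e$kind %in% c("intron_retention_complete", "intron_retention_partial",
                      "cryptic_exon_insertion")) e$target_index else NA_integer_, 1L)
  if (anyDuplicated(stats::na.omit(tgt_exon)) || anyDuplicated(stats::na.omit(tgt_intron)))
    stop_sl("sl_conflict", "two events address the same exon or intron")

  # per-exon retained sense subinterval (NULL = skipped), per-intron inserts
  exon_keep <- lapply(seq_len(n), function(i) c(1L, exon_lengths(gene)[i]))
  intron_ins <- vector("list", max(n - 1L, 0L))   # list of c(from,to) sense pos

  for (e in events) {
    k <- e$target_index
    if (e$kind %in% c("intron_retention_complete", "intron_retention_partial",
                      "cryptic_exon_insertion") && (k < 1L || k > n - 1L))
      stop_sl("sl_range", sprintf("no intron %d", k))
    switch(e$kind,
      exon_skip = {
        if (k > n) stop_sl("sl_range", sprintf("no exon %d", k))
        exon_keep[k] <- list(NULL)
      },
      exon_truncation = {
        if (k > n) stop_sl("sl_range", sprintf("no exon %d", k))
        len <- exon_lengths(gene)[k]
        if (!is.null(e$cryptic_donor)) {
          p <- .exon_sense_pos(gene, k, e$cryptic_donor)
          exon_keep[[k]] <- c(1L, p - 1L)
        } else {
          p <- .exon_sense_pos(gene, k, e$cryptic_acceptor)
          exon_keep[[k]] <- c(p + 1L, len)
        }
        if (exon_keep[[k]][1L] > exon_keep[[k]][2L])
          stop_sl("sl_range", sprintf("truncation removes all of exon %d", k))
      },
      exon_extension = {
        if (!is.null(e$cryptic_acceptor)) {     # 5' extension into intron k-1
          if (k < 2L) stop_sl("sl_range", "no upstream intron to extend into")
          p <- .intron_sense_pos(gene, k - 1L, e$cryptic_acceptor)
          intron_ins[[k - 1L]] <- rbind(intron_ins[[k - 1L]],
                                        c(p + 1L, iv$length[k - 1L]))
        } else {                                 # 3' extension into intron k
          if (k > n - 1L) stop_sl("sl_range", "no downstream intron to extend into")
          p <- .intron_sense_pos(gene, k, e$cryptic_donor)
          intron_ins[[k]] <- rbind(intron_ins[[k]], c(1L, p - 1L))
        }
      },
      intron_retention_complete = {
        intron_ins[[k]] <- rbind(intron_ins[[k]], c(1L, iv$length[k]))
      },
      intron_retention_partial = {
        if (!is.null(e$cryptic_acceptor)) {
          p <- .intron_sense_pos(gene, k, e$cryptic_acceptor)
          intron_ins[[k]] <- rbind(intron_ins[[k]], c(p + 1L, iv$length[k]))
        } else {
          p <- .intron_sense_pos(gene, k, e$cryptic_donor)
          intron_ins[[k]] <- rbind(intron_ins[[k]], c(1L, p - 1L))
        }
      },
      cryptic_exon_insertion = {
        pa <- .intron_sense_pos(gene, k, e$cryptic_acceptor)
        pd <- .intron_sense_pos(gene, k, e$cryptic_donor)
        if (pd - pa < 2L)
          stop_sl("sl_range", "cryptic donor must lie downstream of the cryptic acceptor")
        intron_ins[[k]] <- rbind(intron_ins[[k]], c(pa + 1L, pd - 1L))
      })
  }
  for (k in seq_along(intron_ins)) {
    if (!is.null(intron_ins[[k]]) &&
        (is.null(exon_keep[[k]]) || is.null(exon_keep[[k + 1L]])))
      stop_sl("sl_conflict",
              sprintf("intron %d retention/insertion conflicts with skipping a flanking exon", k))
    if (!is.null(intron_ins[[k]]) && nrow(intron_ins[[k]]) > 1L)
      stop_sl("sl_conflict", sprintf("multiple events address intron %d", k))
    if (!is.null(intron_ins[[k]]) && intron_ins[[k]][1L] > intron_ins[[k]][2L])
      stop_sl("sl_range", sprintf("retained segment of intron %d is empty", k))
  }

  # assemble pieces in transcript order with sense-linear coordinates
  sense_sub <- function(gs, ge) {  # plus-strand interval -> sense string
    s <- substr(genome, gs, ge)
    if (gene$strand == "-") revcomp(s) else s
  }
  pieces <- list()
  add_piece <- function(lin0, from, to, gs, ge) {
    pieces[[length(pieces) + 1L]] <<- list(
      seq = sense_sub(gs, ge), lin_start = lin0 + from - 1L, len = to - from + 1L)
  }
  for (i in seq_len(n)) {
    if (!is.null(exon_keep[[i]])) {
      kp <- exon_keep[[i]]
      if (gene$strand == "+") {
        add_piece(gene$exons$start[i], kp[1L], kp[2L],
                  gene$exons$start[i] + kp[1L] - 1L, gene$exons$start[i] + kp[2L] - 1L)
      } else {
        add_piece(-gene$exons$end[i], kp[1L], kp[2L],
                  gene$exons$end[i] - kp[2L] + 1L, gene$exons$end[i] - kp[1L] + 1L)
      }
    }
    if (i <= n - 1L && !is.null(intron_ins[[i]])) {
      seg <- intron_ins[[i]][1L, ]
      if (gene$strand == "+") {
        add_piece(iv$start[i], seg[1L], seg[2L],
                  iv$start[i] + seg[1L] - 1L, iv$start[i] + seg[2L] - 1L)
      } else {
        add_piece(-iv$end[i], seg[1L], seg[2L],
                  iv$end[i] - seg[2L] + 1L, iv$end[i] - seg[1L] + 1L)
      }
    }
  }
  if (!length(pieces)) stop_sl("sl_conflict", "all exons removed; nothing to reconstruct")

  lens <- vapply(pieces, function(p) p$len, 1L)
  lin_start <- vapply(pieces, function(p) p$lin_start, 1L)
  lin_end <- lin_start + lens - 1L
  cum <- cumsum(lens)
  junctions <- if (length(pieces) > 1L)
    cum[-length(cum)][lin_start[-1L] != lin_end[-length(lin_end)] + 1L]
  else integer()

  g_cds <- transcript_to_genomic(gene, gene$cds_start)
  lin_cds <- .lin(gene, g_cds)
  hit <- which(lin_start <= lin_cds & lin_cds <= lin_end)
  if (length(hit) != 1L)
    stop_sl("sl_conflict", "events remove the translation initiation site")
  new_cds <- c(0L, cum)[hit] + (lin_cds - lin_start[hit]) + 1L

  mature_transcript(paste(vapply(pieces, function(p) p$seq, ""), collapse = ""),
                    junctions = junctions, cds_start = new_cds,
                    provenance = events)
}

#' Enumerate internal AG dinucleotides of an intron as cryptic acceptors
#'
#' Scans the sense-strand intron sequence for AG dinucleotides (excluding the
#' canonical acceptor AG at the intron 3' end) and flags pairs of closely
#' spaced AGs whose G positions lie exactly 3 nt apart — the geometry of two
#' consecutive cryptic acceptor sites whose partial-retention products differ
#' by 3 nt.
#'
#' @param gene A `GeneModel`.
#' @param intron_index Intron number (1-based, transcript order).
#' @return Data frame with one row per internal AG: `pos` (sense position of
#'   the G within the intron), `genomic` (plus-strand coordinate of the G),
#'   `offset` (position of the G relative to the acceptor; the last intron
#'   base is -1), `retained_length` (nt retained if this AG is used as a
#'   cryptic acceptor with the canonical donor), and `paired` (member of a
#'   3-nt-spaced pair).
#' @export
enumerate_consecutive_ag_acceptors <- function(gene, intron_index) {
  iv <- intron_intervals(gene)
  if (intron_index < 1L || intron_index > nrow(iv))
    stop_sl("sl_range", sprintf("no intron %d", intron_index))
  L <- iv$length[intron_index]
  if (L < 8L) stop_sl("sl_range", "intron too short to scan for internal acceptors")
  s <- intron_seq(gene, intron_index)
  hits <- gregexpr("(?=AG)", s, perl = TRUE)[[1L]]
  g_pos <- if (hits[1L] == -1L) integer() else as.integer(hits) + 1L  # pos of G
  g_pos <- g_pos[g_pos < L]                      # drop canonical acceptor AG
  if (!length(g_pos))
    return(data.frame(pos = integer(), genomic = integer(), offset = integer(),
                      retained_length = integer(), paired = logical()))
  genomic <- if (gene$strand == "+") iv$start[intron_index] + g_pos - 1L
             else                    iv$end[intron_index] - g_pos + 1L
  paired <- (g_pos + 3L) %in% g_pos | (g_pos - 3L) %in% g_pos
  data.frame(pos = g_pos, genomic = genomic, offset = g_pos - L - 1L,
             retained_length = L - g_pos, paired = paired)
}
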