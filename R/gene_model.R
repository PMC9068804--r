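#' Gene models with exon/intron structure and sequence access
#'
#' A `GeneModel` represents one transcript of a gene as an ordered list of
#' exons on a genomic reference sequence, together with the transcript
#' coordinates of the translation start and stop.  All genomic coordinates are
#' 1-based inclusive and index directly into `sequence` (the plus-strand
#' genomic sequence of the modeled region).  Exons are stored in transcript
#' order: ascending genomic coordinates on the plus strand, descending on the
#' minus strand, where each exon is read as the reverse complement.
#'
#' @param gene_id Gene symbol or identifier.
#' @param exons Two-column data frame (`start`, `end`), 1-based inclusive
#'   genomic intervals in transcript order.
#' @param sequence Plus-strand genomic sequence covering all exons and introns
#'   (coordinate 1 = first character).
#' @param cds_start,cds_end Transcript coordinates (1-based, on the spliced
#'   transcript) of the first base of the initiation codon and the last base
#'   of the stop codon.
#' @param strand `"+"` or `"-"`.
#' @param chromosome_name Reference sequence name (annotation only).
#' @param transcript_accession Transcript accession (annotation only).
#'
#' @return An object of class `GeneModel`.
#' @examples
#' seq <- paste(rep("ACGT", 250), collapse = "")
#' gm <- gene_model("toy", data.frame(start = c(11, 211), end = c(110, 310)),
#'                  sequence = seq, cds_start = 1, cds_end = 198)
#' @export
gene_model <- function(gene_id, exons, sequence, cds_start, cds_end,
                       strand = "+", chromosome_name = "chrS",
                       transcript_accession = NA_character_) {
  stopifnot(is.data.frame(exons), all(c("start", "end") %in% names(exons)))
  exons <- data.frame(start = as.integer(exons$start), end = as.integer(exons$end))
  if (!strand %in% c("+", "-")) stop_sl("sl_validation", "strand must be '+' or '-'")
  if (any(exons$end < exons$start))
    stop_sl("sl_validation", "exon end precedes exon start")
  n <- nrow(exons)
  if (n >= 2L) {
    ord <- if (strand == "+") diff(exons$start) > 0 else diff(exons$start) < 0
    if (!all(ord))
      stop_sl("sl_validation", "exons must be in transcript order for the given strand")
    gaps <- if (strand == "+") exons$start[-1L] - exons$end[-n] - 1L
            else                exons$start[-n] - exons$end[-1L] - 1L
    if (any(gaps < 4L))
      stop_sl("sl_validation", "introns must be at least 4 nt (overlapping or abutting exons?)")
  }
  sequence <- toupper(as.character(sequence))
  if (max(exons$end) > nchar(sequence))
    stop_sl("sl_validation", "exon coordinates exceed the supplied sequence")
  tx_len <- sum(exons$end - exons$start + 1L)
  cds_start <- as.integer(cds_start); cds_end <- as.integer(cds_end)
  if (!(cds_start >= 1L && cds_start < cds_end && cds_end <= tx_len))
    stop_sl("sl_validation", "require 1 <= cds_start < cds_end <= spliced transcript length")
  structure(
    list(gene_id = gene_id, transcript_accession = transcript_accession,
         strand = strand, chromosome_name = chromosome_name,
         exons = exons, cds_start = cds_start, cds_end = cds_end,
         sequence = sequence),
    class = "GeneModel")
}

#' @export
print.GeneModel <- function(x, ...) {
  cat(sprintf("GeneModel %s (%s) strand %s, %d exons, transcript %d nt, CDS %d..%d\n",
              x$gene_id,
              ifelse(is.na(x$transcript_accession), "-", x$transcript_accession),
              x$strand, nrow(x$exons), transcript_length(x), x$cds_start, x$cds_end))
  invisible(x)
}

#' Number of exons of a gene model
#' @param gene A `GeneModel`.
#' @export
n_exons <- function(gene) nrow(gene$exons)

#' Exon lengths (nt) in transcript order
#' @param gene A `GeneModel`.
#' @export
exon_lengths <- function(gene) gene$exons$end - gene$exons$start + 1L

#' Spliced transcript length (nt)
#' @param gene A `GeneModel`.
#' @export
transcript_length <- function(gene) sum(exon_lengths(gene))

#' Genomic intervals of the introns, in transcript order
#'
#' @param gene A `GeneModel`.
#' @return Data frame with columns `start`, `end` (1-based inclusive genomic,
#'   plus strand) and `length`; row `i` is the intron between exons `i` and
#'   `i + 1`.
#' @export
intron_intervals <- function(gene) {
  n <- n_exons(gene)
  if (n < 2L) return(data.frame(start = integer(), end = integer(), length = integer()))
  if (gene$strand == "+") {
    start <- gene$exons$end[-n] + 1L
    end   <- gene$exons$start[-1L] - 1L
  } else {
    start <- gene$exons$end[-1L] + 1L
    end   <- gene$exons$start[-n] - 1L
  }
  data.frame(start = start, end = end, length = end - start + 1L)
}

#' Extract plus-strand genomic sequence for an interval
#' @param gene A `GeneModel`.
#' @param start,end 1-based inclusive genomic coordinates.
#' @export
gene_seq <- function(gene, start, end) {
  if (start < 1L || end > nchar(gene$sequence) || start > end)
    stop_sl("sl_range", sprintf("interval %d..%d outside modeled sequence", start, end))
  substr(gene$sequence, start, end)
}

# Sense-strand sequence of one exon (transcript order index).
exon_seq <- function(gene, i, sequence = gene$sequence) {
  s <- substr(sequence, gene$exons$start[i], gene$exons$end[i])
  if (gene$strand == "-") revcomp(s) else s
}

# Sense-strand sequence of one intron (transcript order index).
intron_seq <- function(gene, i, sequence = gene$sequence) {
  iv <- intron_intervals(gene)
  if (i < 1L || i > nrow(iv)) stop_sl("sl_range", sprintf("no intron %d", i))
  s <- substr(sequence, iv$start[i], iv$end[i])
  if (gene$strand == "-") revcomp(s) else s
}

#' Spliced (canonical) transcript sequence of a gene model
#' @param gene A `GeneModel`.
#' @param sequence Optional replacement genomic sequence (e.g. carrying a
#'   variant allele); defaults to the gene's reference sequence.
#' @export
spliced_sequence <- function(gene, sequence = gene$sequence) {
  paste(vapply(seq_len(n_exons(gene)), exon_seq, "", gene = gene,
               sequence = sequence), collapse = "")
}

# ---- coordinate mapping ----------------------------------------------------

# transcript coordinate (1-based on spliced transcript) -> plus-strand genomic
transcript_to_genomic <- function(gene, t) {
  if (t < 1L || t > transcript_length(gene))
    stop_sl("sl_range", sprintf("transcript position %d outside transcript", t))
  cum <- cumsum(exon_lengths(gene))
  k <- which(t <= cum)[1L]
  d <- t - c(0L, cum)[k] - 1L            # 0-based offset within exon k
  if (gene$strand == "+") gene$exons$start[k] + d else gene$exons$end[k] - d
}

# plus-strand genomic -> transcript coordinate; NA when intronic/outside exons
genomic_to_transcript <- function(gene, g) {
  hit <- which(gene$exons$start <= g & g <= gene$exons$end)
  if (length(hit) != 1L) return(NA_integer_)
  cum <- c(0L, cumsum(exon_lengths(gene)))
  d <- if (gene$strand == "+") g - gene$exons$start[hit] else gene$exons$end[hit] - g
  cum[hit] + d + 1L
}

# exon index whose boundary a coding anchor sits on; internal validation
anchor_transcript_pos <- function(gene, anchor) {
  t <- gene$cds_start + anchor - 1L
  if (anchor < 1L || t > gene$cds_end)
    stop_sl("sl_validation", sprintf("coding anchor %d outside the CDS", anchor))
  t
}

#' Coding positions with intronic offsets
#'
#' Constructs an HGVS-style coding position: `anchor` is the 1-based index of
#' a coding nucleotide and `offset` a signed intronic offset (0 for exonic
#' positions; negative counts upstream from a splice acceptor, positive
#' downstream from a splice donor).
#' @param anchor Coding nucleotide index (>= 1).
#' @param offset Signed integer intronic offset.
#' @export
hgvs_coding_position <- function(anchor, offset = 0L) {
  anchor <- as.integer(anchor); offset <- as.integer(offset)
  if (is.na(anchor) || anchor < 1L) stop_sl("sl_validation", "anchor must be >= 1")
  structure(list(anchor = anchor, offset = offset), class = "HgvsCodingPosition")
}

#' Parse an HGVS coding-DNA substitution
#'
#' Accepts strings of the form `c.<anchor>[(+|-)offset]<ref>><alt>` describing
#' single-nucleotide substitutions, e.g. `"c.3331-26T>G"` or `"c.292+177C>T"`.
#' Both the ASCII hyphen and the typographic minus (U+2212) are accepted;
#' output is normalized to ASCII.  Indels and other HGVS constructs are
#' rejected.
#'
#' @param text HGVS c. string.
#' @return A `Variant` with fields `pos` (an [hgvs_coding_position()]), `ref`,
#'   `alt` and the normalized `name`.
#' @examples
#' v <- parse_hgvs_c("c.3331−26T>G")
#' v$pos$offset   # -26
#' @export
parse_hgvs_c <- function(text) {
  if (!is_scalar_chr(text)) stop_sl("sl_parse", "expected a single character string")
  s <- norm_minus(trimws(text))
  if (grepl("(del|ins|dup|inv)", s))
    stop_sl("sl_parse", sprintf("only single-nucleotide substitutions are supported: '%s'", text))
  m <- regmatches(s, regexec("^c\\.([0-9]+)([+-][0-9]+)?([ACGTacgt])>([ACGTacgt])$", s))[[1L]]
  if (length(m) == 0L)
    stop_sl("sl_parse", sprintf("malformed HGVS c. substitution: '%s'", text))
  anchor <- as.integer(m[2L])
  offset <- if (nzchar(m[3L])) as.integer(m[3L]) else 0L
  variant(hgvs_coding_position(anchor, offset), toupper(m[4L]), toupper(m[5L]))
}

#' Construct a single-nucleotide variant
#'
#' @param pos An [hgvs_coding_position()] or (genomic) integer coordinate.
#' @param ref,alt Reference and alternate alleles (single nucleotides, given on
#'   the coding strand when `pos` is a coding position, on the plus strand when
#'   genomic).
#' @export
variant <- function(pos, ref, alt) {
  if (!ref %in% DNA_BASES || !alt %in% DNA_BASES)
    stop_sl("sl_validation", sprintf("alleles must be single nucleotides, got %s>%s", ref, alt))
  if (identical(ref, alt)) stop_sl("sl_validation", "ref and alt alleles are identical")
  structure(list(pos = pos, ref = ref, alt = alt, name = NULL), class = "Variant")
}

#' Format a variant as a normalized HGVS c. string
#' @param variant A `Variant` with a coding position.
#' @export
format_hgvs_c <- function(variant) {
  p <- variant$pos
  if (!inherits(p, "HgvsCodingPosition"))
    stop_sl("sl_validation", "variant does not carry a coding position")
  off <- if (p$offset == 0L) "" else sprintf("%+d", p$offset)
  sprintf("c.%d%s%s>%s", p$anchor, off, variant$ref, variant$alt)
}

#' @export
print.Variant <- function(x, ...) {
  nm <- if (inherits(x$pos, "HgvsCodingPosition")) format_hgvs_c(x)
        else sprintf("g.%d%s>%s", x$pos, x$ref, x$alt)
  cat("Variant", nm, "\n")
  invisible(x)
}

#' Map a coding position (with intronic offset) to a genomic coordinate
#'
#' Strand-aware: on the minus strand, positive (donor-side) offsets move to
#' lower plus-strand coordinates.  The anchor of an offset position must be
#' the first (acceptor side) or last (donor side) coding nucleotide of an exon
#' adjacent to the intron, and the offset must not exceed that intron's
#' length.
#'
#' @param gene A `GeneModel`.
#' @param pos An [hgvs_coding_position()].
#' @return 1-based plus-strand genomic coordinate.
#' @export
c_to_genomic <- function(gene, pos) {
  stopifnot(inherits(pos, "HgvsCodingPosition"))
  t <- anchor_transcript_pos(gene, pos$anchor)
  if (pos$offset == 0L) return(transcript_to_genomic(gene, t))
  cum <- cumsum(exon_lengths(gene))
  iv <- intron_intervals(gene)
  if (pos$offset > 0L) {                       # downstream of a donor
    k <- match(t, cum)
    if (is.na(k) || k == n_exons(gene))
      stop_sl("sl_validation",
              sprintf("anchor %d is not the last base of an exon with a downstream intron", pos$anchor))
    if (pos$offset > iv$length[k])
      stop_sl("sl_range", sprintf("offset +%d exceeds intron %d length (%d nt)",
                                  pos$offset, k, iv$length[k]))
    if (gene$strand == "+") gene$exons$end[k] + pos$offset
    else                    gene$exons$start[k] - pos$offset
  } else {                                     # upstream of an acceptor
    k <- match(t, c(1L, cum[-n_exons(gene)] + 1L))
    if (is.na(k) || k == 1L)
      stop_sl("sl_validation",
              sprintf("anchor %d is not the first base of an exon with an upstream intron", pos$anchor))
    if (-pos$offset > iv$length[k - 1L])
      stop_sl("sl_range", sprintf("offset %d exceeds intron %d length (%d nt)",
                                  pos$offset, k - 1L, iv$length[k - 1L]))
    if (gene$strand == "+") gene$exons$start[k] + pos$offset
    else                    gene$exons$end[k] - pos$offset
  }
}

#' Name a genomic position in coding (HGVS c.) terms
#'
#' Inverse of [c_to_genomic()].  Exonic positions within the CDS map to a
#' plain anchor; intronic positions map to the nearest splice site (donor `+`
#' offsets when the position is in the 5' half of the intron, acceptor `-`
#' offsets otherwise, following HGVS convention).
#'
#' @param gene A `GeneModel`.
#' @param g 1-based plus-strand genomic coordinate.
#' @return An [hgvs_coding_position()].
#' @export
genomic_to_c <- function(gene, g) {
  t <- genomic_to_transcript(gene, g)
  cum <- cumsum(exon_lengths(gene))
  if (!is.na(t)) {
    anchor <- t - gene$cds_start + 1L
    if (anchor < 1L || t > gene$cds_end)
      stop_sl("sl_range", "exonic position outside the CDS cannot be named with a coding anchor")
    return(hgvs_coding_position(anchor, 0L))
  }
  iv <- intron_intervals(gene)
  hit <- which(iv$start <= g & g <= iv$end)
  if (length(hit) != 1L)
    stop_sl("sl_range", sprintf("genomic position %d is neither exonic nor intronic in this model", g))
  d_donor <- if (gene$strand == "+") g - iv$start[hit] + 1L else iv$end[hit] - g + 1L
  d_accep <- iv$length[hit] - d_donor + 1L
  if (d_donor <= d_accep) {
    hgvs_coding_position(cum[hit] - gene$cds_start + 1L, d_donor)
  } else {
    hgvs_coding_position(cum[hit] + 1L - gene$cds_start + 1L, -d_accep)
  }
}

#' Resolve a variant on a gene model
#'
#' Computes the genomic coordinate of a coding-position variant (or the coding
#' name of a genomic variant), checks the reference allele against the model
#' sequence, and returns the variant annotated with `genomic`, `name` and the
#' plus-strand alleles `g_ref`/`g_alt`.
#'
#' @param gene A `GeneModel`.
#' @param v A `Variant`.
#' @export
resolve_variant <- function(gene, v) {
  stopifnot(inherits(v, "Variant"))
  if (inherits(v$pos, "HgvsCodingPosition")) {
    g <- c_to_genomic(gene, v$pos)
    sense_ref <- v$ref; sense_alt <- v$alt
  } else {
    g <- as.integer(v$pos)
    if (gene$strand == "+") { sense_ref <- v$ref; sense_alt <- v$alt }
    else { sense_ref <- revcomp(v$ref); sense_alt <- revcomp(v$alt) }
    v$pos <- genomic_to_c(gene, g)
    v$ref <- sense_ref; v$alt <- sense_alt
  }
  plus_ref <- if (gene$strand == "+") sense_ref else revcomp(sense_ref)
  found <- gene_seq(gene, g, g)
  if (found != plus_ref)
    stop_sl("sl_validation",
            sprintf("reference allele mismatch at g.%d: model has %s, variant says %s (plus strand)",
                    g, found, plus_ref))
  v$genomic <- g
  v$g_ref <- plus_ref
  v$g_alt <- if (gene$strand == "+") sense_alt else revcomp(sense_alt)
  v$name <- format_hgvs_c(v)
  v
}

#' Apply a variant to the genomic sequence of a model
#'
#' @param gene A `GeneModel`.
#' @param v A `Variant` (resolved or not).
#' @return The plus-strand genomic sequence carrying the alternate allele.
#' @export
apply_variant <- function(gene, v) {
  v <- resolve_variant(gene, v)
  s <- gene$sequence
  substr(s, v$genomic, v$genomic) <- v$g_alt
  s
}

#' Locate an intronic variant: intron index and distance to nearest splice site
#'
#' @param gene A `GeneModel`.
#' @param v A `Variant` resolving to an intronic position.
#' @return List with `intron` (1-based, transcript order) and `distance`
#'   (signed nt: positive downstream of the donor, negative upstream of the
#'   acceptor; the nearer site is used).
#' @export
intron_of <- function(gene, v) {
  v <- resolve_variant(gene, v)
  if (v$pos$offset == 0L)
    stop_sl("sl_domain", sprintf("%s is exonic, not intronic", v$name))
  iv <- intron_intervals(gene)
  hit <- which(iv$start <= v$genomic & v$genomic <= iv$end)
  list(intron = hit, distance = v$pos$offset)
}
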