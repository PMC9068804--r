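# In-silico RT-PCR and minigene construct validation.  Primer binding is
# exact-match only: the analysis needs product identities and sizes, not
# annealing thermodynamics.

#' Construct a PCR primer
#'
#' @param name Primer name.
#' @param sequence 5'->3' nucleotide string (whitespace allowed and stripped;
#'   at least 15 nt).
#' @param orientation `"forward"` (binds the sense strand as written) or
#'   `"reverse"` (written as the reverse complement of the sense strand).
#' @export
primer <- function(name, sequence, orientation = c("forward", "reverse")) {
  orientation <- match.arg(orientation)
  sequence <- toupper(gsub("[[:space:]]", "", sequence))
  if (nchar(sequence) < 15L)
    stop_sl("sl_validation", sprintf("primer %s is shorter than 15 nt", name))
  if (grepl("[^ACGT]", sequence))
    stop_sl("sl_validation", sprintf("primer %s contains non-ACGT characters", name))
  structure(list(name = name, sequence = sequence, orientation = orientation),
            class = "Primer")
}

.template_string <- function(template) {
  if (inherits(template, "MatureTranscript")) template$sequence
  else toupper(as.character(template))
}

.find_all <- function(pattern, subject) {
  h <- gregexpr(pattern, subject, fixed = TRUE)[[1L]]
  if (h[1L] == -1L) integer() else as.integer(h)
}

#' Predict PCR amplicons on a template by exact primer matching
#'
#' The forward primer must match the template verbatim; the reverse primer
#' must match its reverse complement (i.e. the template contains
#' `revcomp(rev)`).  Junction-spanning primers therefore bind spliced
#' transcripts but not the unspliced pre-mRNA.  All products up to
#' `max_product` nt are returned; no binding yields an empty result, not an
#' error.
#'
#' @param template A `MatureTranscript`, or a nucleotide string (e.g. a
#'   genomic segment).
#' @param fwd,rev `Primer`s (or plain sequences, coerced).
#' @param max_product Maximum product length in nt (default 5000).
#' @param template_id Identifier recorded on the amplicons.
#' @return Data frame of amplicons: `start`, `end` (template coordinates),
#'   `length`, `sequence`, `fwd`, `rev`, `template_id`.
#' @export
insilico_pcr <- function(template, fwd, rev, max_product = 5000L,
                         template_id = "template") {
  if (!inherits(fwd, "Primer")) fwd <- primer("fwd", fwd, "forward")
  if (!inherits(rev, "Primer")) rev <- primer("rev", rev, "reverse")
  tmpl <- .template_string(template)
  f_starts <- .find_all(fwd$sequence, tmpl)
  r_rc <- revcomp(rev$sequence)
  r_starts <- .find_all(r_rc, tmpl)
  out <- data.frame(start = integer(), end = integer(), length = integer(),
                    sequence = character(), fwd = character(), rev = character(),
                    template_id = character())
  for (f in f_starts) for (rs in r_starts) {
    re <- rs + nchar(r_rc) - 1L
    if (rs < f) next
    len <- re - f + 1L
    if (len > max_product) next
    out <- rbind(out, data.frame(start = f, end = re, length = len,
                                 sequence = substr(tmpl, f, re),
                                 fwd = fwd$name, rev = rev$name,
                                 template_id = template_id))
  }
  out[order(out$length), , drop = FALSE]
}

#' Two-round (nested) PCR
#'
#' Runs `round1` primers on the template, then `round2` primers on the
#' first-round product.  The second-round primers must bind within the
#' first-round product.
#'
#' @param template Template as in [insilico_pcr()].
#' @param round1,round2 Lists/pairs of (`fwd`, `rev`) `Primer`s.
#' @param template_id Identifier recorded on the final amplicon.
#' @return Single-row amplicon data frame (the final product).
#' @export
nested_pcr <- function(template, round1, round2, template_id = "template") {
  a1 <- insilico_pcr(template, round1[[1L]], round1[[2L]], template_id = template_id)
  if (nrow(a1) == 0L)
    stop_sl("sl_domain", "first-round primers do not amplify the template")
  a2 <- insilico_pcr(a1$sequence[1L], round2[[1L]], round2[[2L]],
                     template_id = paste0(template_id, ":round1"))
  if (nrow(a2) == 0L)
    stop_sl("sl_domain", "second-round primers do not bind within the first-round product")
  a2[1L, , drop = FALSE]
}

#' Restriction enzymes known to the minigene designer
#'
#' Recognition sites with top-strand cut offsets (bases retained 5' of the
#' cut).  NotI: GC^GGCCGC; EcoRV: GAT^ATC (blunt).
#' @export
restriction_enzymes <- function() {
  list(NotI  = list(site = "GCGGCCGC", cut5 = 2L),
       EcoRV = list(site = "GATATC",   cut5 = 3L))
}

#' Specify an expression vector for dual-tagged minigene cloning
#'
#' The vector is abstracted as the fusion-ORF sequence surrounding the
#' cloning sites: `n_prefix` runs from the vector ATG (through the N-terminal
#' tag) up to and including the bases the ligated insert is joined to;
#' `c_suffix` continues from the insert 3' junction through the C-terminal
#' tag to the vector stop codon.  Tag peptides are used to test whether a
#' (mis)spliced product would be detected by anti-tag antibodies.
#'
#' @param n_prefix,c_suffix Nucleotide strings (see above); `n_prefix` must
#'   begin with ATG.
#' @param n_tag_peptide,c_tag_peptide Amino-acid strings of the epitope tags
#'   (defaults: FLAG, Myc).
#' @param enzymes Character vector of two enzyme names (5' then 3' cloning
#'   site) from [restriction_enzymes()].
#' @export
vector_spec <- function(n_prefix, c_suffix,
                        n_tag_peptide = "DYKDDDDK", c_tag_peptide = "EQKLISEEDL",
                        enzymes = c("NotI", "EcoRV")) {
  n_prefix <- toupper(gsub("[[:space:]]", "", n_prefix))
  c_suffix <- toupper(gsub("[[:space:]]", "", c_suffix))
  if (substr(n_prefix, 1L, 3L) != "ATG")
    stop_sl("sl_validation", "vector n_prefix must begin with the ATG of the fusion ORF")
  if (!all(enzymes %in% names(restriction_enzymes())))
    stop_sl("sl_validation", "unknown restriction enzyme")
  structure(list(n_prefix = n_prefix, c_suffix = c_suffix,
                 n_tag_peptide = n_tag_peptide, c_tag_peptide = c_tag_peptide,
                 enzymes = enzymes),
            class = "VectorSpec")
}

# longest suffix of `p` (>= min_len) found in `tmpl`; returns list(k, at)
.anneal_suffix <- function(p, tmpl, min_len = 12L) {
  for (k in seq(nchar(p), min_len)) {
    tail_k <- substr(p, nchar(p) - k + 1L, nchar(p))
    at <- .find_all(tail_k, tmpl)
    if (length(at)) return(list(k = k, at = at[1L]))
  }
  NULL
}

#' Design and frame-check a dual-tagged minigene construct
#'
#' Amplifies the genomic span of exons `span[1]`..`span[2]` with tailed
#' cloning primers (the 3' ends must anneal exactly; 5' tails carry the
#' restriction sites), digests the product with the vector's two enzymes,
#' and assembles the fusion gene `n_prefix + insert + c_suffix`.  The insert
#' retains the original introns, so the fusion is itself a minigene whose
#' splicing can be simulated; reading-frame bookkeeping at both junctions is
#' checked against the natural codon phase of the cloned exons.
#'
#' @param gene A `GeneModel`.
#' @param span Integer pair: first and last exon (transcript order) of the
#'   cloned fragment.
#' @param cloning_fwd,cloning_rev Tailed `Primer`s.
#' @param vector A [vector_spec()].
#' @return A `MinigeneDesign`: list with the PCR `product`, digested `insert`
#'   (+ `insert_length`), `minigene` (a `GeneModel` of the fusion with the
#'   vector ORF as flanking exon sequence), `frame_ok_n`, `frame_ok_c`, and
#'   the intron index offset `intron_offset` mapping original intron numbers
#'   to minigene intron numbers.
#' @export
build_minigene <- function(gene, span, cloning_fwd, cloning_rev, vector) {
  stopifnot(inherits(vector, "VectorSpec"))
  if (length(span) != 2L || span[2L] - span[1L] < 1L)
    stop_sl("sl_validation", "span must cover at least two exons")
  if (span[1L] < 1L || span[2L] > n_exons(gene))
    stop_sl("sl_range", "span outside the gene model")

  # sense-strand genomic region from first to last exon of the span
  if (gene$strand == "+") {
    g0 <- gene$exons$start[span[1L]]; g1 <- gene$exons$end[span[2L]]
    reg <- gene_seq(gene, g0, g1)
  } else {
    g0 <- gene$exons$start[span[2L]]; g1 <- gene$exons$end[span[1L]]
    reg <- revcomp(gene_seq(gene, g0, g1))
  }

  fa <- .anneal_suffix(cloning_fwd$sequence, reg)
  if (is.null(fa)) stop_sl("sl_domain", "forward cloning primer does not anneal in the span")
  rc <- revcomp(cloning_rev$sequence)
  # 3' anneal of the reverse primer = prefix of its reverse complement
  ra <- NULL
  for (k in seq(nchar(rc), 12L)) {
    at <- .find_all(substr(rc, 1L, k), reg)
    if (length(at)) { ra <- list(k = k, at = at[length(at)]); break }
  }
  if (is.null(ra)) stop_sl("sl_domain", "reverse cloning primer does not anneal in the span")
  r_end <- ra$at + ra$k - 1L
  if (ra$at <= fa$at) stop_sl("sl_domain", "cloning primers do not face each other")

  ftail <- nchar(cloning_fwd$sequence) - fa$k
  rtail <- nchar(cloning_rev$sequence) - ra$k
  product <- paste0(cloning_fwd$sequence,
                    substr(reg, fa$at + fa$k, ra$at - 1L),
                    rc)
  # product position p (> ftail, <= len - rtail) maps to region position
  #   reg_pos = fa$at + (p - ftail - 1)

  enz <- restriction_enzymes()[vector$enzymes]
  s1 <- .find_all(enz[[1L]]$site, product)
  s2 <- .find_all(enz[[2L]]$site, product)
  if (length(s1) != 1L || length(s2) != 1L)
    stop_sl("sl_design",
            sprintf("each cloning enzyme site must occur exactly once in the product (%s: %d, %s: %d)",
                    vector$enzymes[1L], length(s1), vector$enzymes[2L], length(s2)))
  cutA <- s1 + enz[[1L]]$cut5           # first retained insert base
  cutB <- s2 + enz[[2L]]$cut5 - 1L      # last retained insert base
  if (cutB <= cutA) stop_sl("sl_design", "restriction sites are not in cloning orientation")
  insert <- substr(product, cutA, cutB)

  # fusion pre-mRNA and its exon structure
  np <- nchar(vector$n_prefix)
  fusion <- paste0(vector$n_prefix, insert, vector$c_suffix)
  prod_to_reg <- function(p) fa$at + (p - ftail - 1L)
  # introns of the original gene lying fully inside the insert, in region coords
  iv <- intron_intervals(gene)
  intr_reg <- lapply(seq_len(nrow(iv)), function(i) {
    if (gene$strand == "+") c(iv$start[i] - g0 + 1L, iv$end[i] - g0 + 1L)
    else c(g1 - iv$end[i] + 1L, g1 - iv$start[i] + 1L)
  })
  reg_lo <- prod_to_reg(max(cutA, ftail + 1L))
  reg_hi <- prod_to_reg(min(cutB, nchar(product) - rtail))
  keep <- vapply(intr_reg, function(r) r[1L] >= reg_lo && r[2L] <= reg_hi, TRUE)
  intron_idx <- which(keep)
  reg_to_fusion <- function(rp) np + (rp - fa$at + ftail + 1L) - (cutA - 1L)
  intr_fus <- lapply(intr_reg[keep], function(r) vapply(r, reg_to_fusion, 1L))
  bounds <- c(np + 0L, unlist(intr_fus), nchar(fusion) + 1L)
  starts <- c(1L, vapply(intr_fus, function(r) r[2L] + 1L, 1L))
  ends <- c(vapply(intr_fus, function(r) r[1L] - 1L, 1L), nchar(fusion))
  mg <- gene_model(paste0(gene$gene_id, "_minigene"),
                   data.frame(start = starts, end = ends),
                   sequence = fusion, cds_start = 1L,
                   cds_end = sum(ends - starts + 1L),
                   strand = "+", chromosome_name = "minigene")

  # frame bookkeeping at the two vector/insert junctions
  phase_of <- function(g) {   # 0-based codon phase of a coding genomic base
    t <- genomic_to_transcript(gene, g)
    if (is.na(t) || t < gene$cds_start || t > gene$cds_end) return(NA_integer_)
    (t - gene$cds_start) %% 3L
  }
  first_mapped_p <- max(cutA, ftail + 1L)
  last_mapped_p <- min(cutB, nchar(product) - rtail)
  reg_to_genomic <- function(rp) if (gene$strand == "+") g0 + rp - 1L else g1 - rp + 1L
  # frame bookkeeping anchors on the first cloned base that is coding
  ph_n <- NA_integer_
  for (p in seq(first_mapped_p, last_mapped_p)) {
    ph_n <- phase_of(reg_to_genomic(prod_to_reg(p)))
    if (!is.na(ph_n)) { first_mapped_p <- p; break }
  }
  fus_pos_first <- np + (first_mapped_p - cutA + 1L)
  frame_ok_n <- !is.na(ph_n) && ((fus_pos_first - 1L) %% 3L) == ph_n
  spliced_len <- transcript_length(mg)
  ins_spliced_end <- spliced_len - nchar(vector$c_suffix)
  frame_ok_c <- (ins_spliced_end %% 3L) == 0L

  structure(list(product = product, insert = insert,
                 insert_length = nchar(insert), minigene = mg,
                 intron_index = intron_idx,
                 intron_offset = if (length(intron_idx)) intron_idx[1L] - 1L else 0L,
                 frame_ok_n = frame_ok_n, frame_ok_c = frame_ok_c,
                 vector = vector),
            class = "MinigeneDesign")
}

#' @export
print.MinigeneDesign <- function(x, ...) {
  cat(sprintf("MinigeneDesign: insert %d nt, %d intron(s); frame N %s / C %s\n",
              x$insert_length, length(x$intron_index),
              ifelse(x$frame_ok_n, "ok", "BROKEN"),
              ifelse(x$frame_ok_c, "ok", "BROKEN")))
  invisible(x)
}

#' Predict epitope-tag positivity of a minigene splicing outcome
#'
#' Splices the minigene fusion gene under the given events, translates the
#' fusion ORF from the vector ATG, and reports whether the resulting protein
#' retains the N-terminal and C-terminal tag peptides — the in-silico
#' counterpart of anti-tag Western blotting.  A PTC introduced by missplicing
#' truncates the protein before the C-terminal tag.
#'
#' @param design A `MinigeneDesign`.
#' @param events `SpliceEvent`(s) on the minigene's own intron numbering
#'   (see `design$intron_offset`).
#' @param variant Optional `Variant` with genomic position on the minigene
#'   fusion coordinates.
#' @return List with `protein`, `n_tag_positive`, `c_tag_positive`.
#' @export
minigene_tag_positive <- function(design, events = splice_event("canonical"),
                                  variant = NULL) {
  tx <- reconstruct_transcript(design$minigene, events, variant)
  prot <- translate_orf(substr(tx$sequence, tx$cds_start, nchar(tx$sequence)))
  list(protein = as.character(prot),
       n_tag_positive = grepl(design$vector$n_tag_peptide, prot, fixed = TRUE),
       c_tag_positive = grepl(design$vector$c_tag_peptide, prot, fixed = TRUE))
}

#' Average molecular mass of a peptide
#'
#' Sum of average residue masses plus one water (18.0153 Da).
#'
#' @param peptide Amino-acid string (standard 20-letter alphabet; `*` and
#'   terminal whitespace are stripped).
#' @return Mass in Daltons.
#' @examples
#' protein_mass("")                      # 18.0153 (water)
#' protein_mass(strrep("G", 10))         # ~ 588.5
#' @export
protein_mass <- function(peptide) {
  masses <- c(A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
              E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
              L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
              S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
  peptide <- gsub("[*[:space:]]", "", toupper(peptide))
  if (nchar(peptide) == 0L) return(18.0153)
  aa <- strsplit(peptide, "")[[1L]]
  if (any(!aa %in% names(masses)))
    stop_sl("sl_validation", "peptide contains non-standard residues")
  sum(masses[aa]) + 18.0153
}
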