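# Seeded generator of synthetic multi-exon gene models with planted
# spliceogenic lesions of known ground truth, and of simulated cohort
# carrier tables.  Every other module is testable against these without any
# external sequence.
#
# Generated introns have a controlled 3' architecture (offsets relative to
# the acceptor; the last intron base is -1):
#   donor GTAAGT | random interior | branch segment (-40..-21, alphabet CTA
#   with a CTAAC branchpoint-like motif at -32..-28) | polypyrimidine tract
#   (-20..-3, C/T with one planted adenine) | acceptor AG.
# No G occurs between -40 and -3, so the last 40 nt contain no AG: planted
# AG-creating substitutions are guaranteed to create the first AG upstream of
# the acceptor (an unambiguous AG-exclusion-zone break).

#' Configuration for the synthetic-data generator
#'
#' @param n_exons Range (min, max) of exon count.
#' @param exon_len Range of exon lengths (nt, uniform).
#' @param intron_len Range of intron lengths (nt, uniform; minimum 80 so the
#'   structured 3' tail fits).
#' @param gc_content Target GC fraction of intron interiors and UTRs.
#' @param lesion_mix Named proportions over the plantable lesion kinds
#'   (`aez_break`, `branch_window_sub`, `deep_cryptic_pair`, `neutral`);
#'   must sum to 1.
#' @param cohort List of cohort-simulation parameters: `n_variants`,
#'   `zero_inflation` (probability of an undetected variant),
#'   `geom_prob` (success probability of the geometric law for carrier
#'   counts beyond the first), `specificity` (expected fraction of carriers
#'   with the target phenotype).
#' @export
simulation_config <- function(n_exons = c(3L, 8L), exon_len = c(60L, 300L),
                              intron_len = c(80L, 1500L), gc_content = 0.45,
                              lesion_mix = c(aez_break = 0.4, branch_window_sub = 0.3,
                                             deep_cryptic_pair = 0.1, neutral = 0.2),
                              cohort = list(n_variants = 46L, zero_inflation = 0.45,
                                            geom_prob = 0.26, specificity = 0.946)) {
  stopifnot(n_exons[1L] >= 2L, n_exons[1L] <= n_exons[2L],
            exon_len[1L] >= 60L, exon_len[1L] <= exon_len[2L],
            intron_len[1L] >= 80L, intron_len[1L] <= intron_len[2L],
            gc_content > 0, gc_content < 1)
  if (abs(sum(lesion_mix) - 1) > 1e-8)
    stop_sl("sl_validation", "lesion_mix proportions must sum to 1")
  structure(list(n_exons = as.integer(n_exons), exon_len = as.integer(exon_len),
                 intron_len = as.integer(intron_len), gc_content = gc_content,
                 lesion_mix = lesion_mix, cohort = cohort),
            class = "SimulationConfig")
}

.rand_dna <- function(n, gc) {
  if (n <= 0L) return("")
  paste(sample(DNA_BASES, n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)), collapse = "")
}

.sense_codons <- function() {
  cods <- as.vector(outer(outer(DNA_BASES, DNA_BASES, paste0), DNA_BASES, paste0))
  setdiff(cods, c("TAA", "TAG", "TGA"))
}

# one structured intron of length L (>= 80); returns its sequence
.synth_intron <- function(L, gc, pyr_a_offset) {
  branch <- sample(c("C", "T", "A"), 20L, replace = TRUE, prob = c(0.35, 0.35, 0.3))
  branch[1L] <- sample(c("C", "T"), 1L)
  branch[9:13] <- c("C", "T", "A", "A", "C")      # offsets -32..-28
  pyr <- sample(c("C", "T"), 18L, replace = TRUE)
  pyr[pyr_a_offset + 21L] <- "A"                  # offset -20 is pyr[1]
  paste0("GTAAGT", .rand_dna(L - 46L, gc), paste(branch, collapse = ""),
         paste(pyr, collapse = ""), "AG")
}

#' Generate a synthetic gene model
#'
#' Builds a multi-exon plus-strand gene whose exons concatenate to an open
#' reading frame (ATG in exon 1, unique in-frame stop in the last exon,
#' short UTRs), with GT..AG introns whose 3' tails are free of internal AG
#' dinucleotides (see the generator notes) so that planted AG-creating
#' substitutions have unambiguous ground truth.  Deterministic per seed.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed governing all randomness.
#' @param dir Optional directory: when given, the model is also written as
#'   `gene.gff3` + `gene.fa` there.
#' @return A `GeneModel` with a `planting` data frame (per intron: the
#'   offset of the adenine planted in the polypyrimidine tract).
#' @export
synth_gene <- function(config = simulation_config(), seed = 1L, dir = NULL) {
  with_seed(seed, {
    rint <- function(lo, hi, n) lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L
    ne <- rint(config$n_exons[1L], config$n_exons[2L], 1L)
    elen <- rint(config$exon_len[1L], config$exon_len[2L], ne)
    ilen <- rint(config$intron_len[1L], config$intron_len[2L], ne - 1L)
    utr5 <- 24L
    total <- sum(elen)
    utr3 <- 27L + (total - utr5 - 27L) %% 3L      # close the reading frame
    cds_len <- total - utr5 - utr3
    n_cod <- cds_len %/% 3L - 2L                  # minus start and stop codons
    mrna <- paste0(.rand_dna(utr5, config$gc_content), "ATG",
                   paste(sample(.sense_codons(), n_cod, replace = TRUE), collapse = ""),
                   sample(c("TAA", "TAG", "TGA"), 1L),
                   .rand_dna(utr3, config$gc_content))
    pyr_a <- sample(seq(-19L, -11L), ne - 1L, replace = TRUE)
    introns <- vapply(seq_len(ne - 1L), function(i)
      .synth_intron(ilen[i], config$gc_content, pyr_a[i]), "")
    pad5 <- .rand_dna(50L, config$gc_content)
    pad3 <- .rand_dna(50L, config$gc_content)
    cume <- cumsum(elen)
    pieces <- character(2L * ne - 1L)
    pieces[seq(1L, 2L * ne - 1L, by = 2L)] <-
      substring(mrna, c(1L, cume[-ne] + 1L), cume)
    if (ne > 1L) pieces[seq(2L, 2L * ne - 2L, by = 2L)] <- introns
    genome <- paste0(pad5, paste(pieces, collapse = ""), pad3)
    starts <- 50L + c(0L, cumsum(elen[-ne] + ilen)) + 1L
    gene <- gene_model(sprintf("synthgene_s%d", seed),
                       data.frame(start = starts, end = starts + elen - 1L),
                       sequence = genome, cds_start = utr5 + 1L,
                       cds_end = utr5 + cds_len, strand = "+",
                       chromosome_name = sprintf("chrS%d", seed))
    gene$planting <- data.frame(intron = seq_len(ne - 1L), pyr_a_offset = pyr_a)
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      write_gene_model(gene, file.path(dir, "gene.gff3"), file.path(dir, "gene.fa"))
    }
    gene
  })
}

# acceptor-side coding anchor of intron i (first coding base of exon i+1);
# donor-side anchor is the last coding base of exon i
.intron_anchor <- function(gene, i, side = c("acceptor", "donor")) {
  side <- match.arg(side)
  cum <- cumsum(exon_lengths(gene))
  t <- if (side == "acceptor") cum[i] + 1L else cum[i]
  t - gene$cds_start + 1L
}

# independent label oracle: direct string slicing + frame arithmetic
.oracle_label <- function(ref_mrna, alt_mrna, cds_start) {
  pr <- translate_orf(substr(ref_mrna, cds_start, nchar(ref_mrna)))
  pa <- translate_orf(substr(alt_mrna, cds_start, nchar(alt_mrna)))
  delta <- nchar(alt_mrna) - nchar(ref_mrna)
  fs <- (delta %% 3L) != 0L
  if (identical(as.character(pr), as.character(pa)) && delta == 0L) return("No change")
  if (is.na(attr(pa, "stop_codon")))
    return(if (fs) "Frameshift-stop loss" else "Stop loss")
  alt_stop <- cds_start + attr(pa, "stop_codon") - 1L
  mapped <- cds_start + attr(pr, "stop_codon") - 1L + delta
  if (alt_stop < mapped) return(if (fs) "Frameshift-PTC" else "Stop gain-PTC")
  if (alt_stop > mapped) return(if (fs) "Frameshift-stop loss" else "Stop loss")
  if (fs) return("Frameshift-PTC")
  "in-frame"   # sized labels are left to the classifier under test
}

.pick1 <- function(x) x[sample.int(length(x), 1L)]

#' Plant a spliceogenic lesion with known ground truth
#'
#' Chooses an eligible intron and introduces a single-nucleotide substitution
#' whose splicing outcome is known by construction:
#' \describe{
#'   \item{aez_break}{a substitution to G one base after an adenine in the
#'     intron 3' tail (offset of the created AG's G in -30..-10), creating
#'     the first AG upstream of the acceptor; truth: partial intron
#'     retention / exon extension ending at the created AG.}
#'   \item{branch_window_sub}{an A>G at an adenine in the branchpoint window
#'     (-37..-19, previous base a pyrimidine so no AG is created); truth:
#'     complete retention of the intron.}
#'   \item{deep_cryptic_pair}{a substitution to T creating a GT cryptic donor
#'     at least 60 nt downstream of a preexisting deep-intronic AG; truth:
#'     cryptic-exon insertion between the AG and the created GT.}
#'   \item{neutral}{a pyrimidine substitution at offsets -60..-45 creating no
#'     AG, outside the branchpoint window; truth: canonical splicing.}
#' }
#'
#' @param gene A `GeneModel` from [synth_gene()].
#' @param lesion_kind One of the four kinds above.
#' @param seed Integer seed.
#' @return List with `variant` (coding-position `Variant`), `truth` (a
#'   `PlantedTruth`: `lesion_kind`, `expected_event`, `expected_label`,
#'   `intron`).
#' @export
plant_lesion <- function(gene, lesion_kind = c("aez_break", "branch_window_sub",
                                               "deep_cryptic_pair", "neutral"),
                         seed = 1L) {
  lesion_kind <- match.arg(lesion_kind)
  with_seed(seed, {
    iv <- intron_intervals(gene)
    n_int <- nrow(iv)
    if (n_int < 1L) stop_sl("sl_domain", "gene has no intron to plant into")
    exs <- vapply(seq_len(n_exons(gene)), exon_seq, "", gene = gene)
    cds_start <- gene$cds_start
    ref_mrna <- paste(exs, collapse = "")
    mk_var <- function(i, offset, alt, side = "acceptor") {
      anchor <- .intron_anchor(gene, i, side)
      pos <- hgvs_coding_position(anchor, offset)
      g <- c_to_genomic(gene, pos)
      variant(pos, gene_seq(gene, g, g), alt)
    }
    alt_intron <- function(i, v) intron_seq(gene, i, sequence = apply_variant(gene, v))
    splice_out <- function(i, insert) paste0(
      paste(exs[seq_len(i)], collapse = ""), insert,
      paste(exs[seq(i + 1L, length(exs))], collapse = ""))

    if (lesion_kind == "aez_break") {
      i <- .pick1(seq_len(n_int))
      s <- intron_seq(gene, i); L <- nchar(s)
      offs <- seq(-31L, -11L)
      cand <- offs[substring(s, L + 1L + offs, L + 1L + offs) == "A" & offs + 1L <= -10L]
      o <- .pick1(cand) + 1L                      # the created AG's G
      v <- mk_var(i, o, "G")
      g_cryptic <- c_to_genomic(gene, hgvs_coding_position(v$pos$anchor, o))
      ev <- splice_event("pRi", i, cryptic_acceptor = g_cryptic)
      retained <- substr(alt_intron(i, v), nchar(s) + 1L + o + 1L, nchar(s))
      label <- .oracle_label(ref_mrna, splice_out(i, retained), cds_start)
    } else if (lesion_kind == "branch_window_sub") {
      i <- .pick1(seq_len(n_int))
      s <- intron_seq(gene, i); L <- nchar(s)
      offs <- seq(-37L, -19L)
      here <- substring(s, L + 1L + offs, L + 1L + offs)
      prev <- substring(s, L + offs, L + offs)
      cand <- offs[here == "A" & prev %in% c("C", "T")]
      o <- .pick1(cand)
      v <- mk_var(i, o, "G")
      ev <- splice_event("cRi", i)
      label <- .oracle_label(ref_mrna, splice_out(i, alt_intron(i, v)), cds_start)
    } else if (lesion_kind == "deep_cryptic_pair") {
      ok <- which(iv$length >= 300L)
      if (!length(ok)) stop_sl("sl_domain", "no intron long enough for a cryptic exon")
      i <- .pick1(ok)
      s <- intron_seq(gene, i); L <- nchar(s)
      ag <- .ag_g_positions(substr(s, 1L, L - 160L))
      ag <- ag[ag >= 10L]
      found <- FALSE
      for (pga in ag[sample.int(length(ag))]) {
        dd <- seq(pga + 61L, L - 60L)
        dd <- dd[substring(s, dd, dd) == "G" &
                 substring(s, dd + 1L, dd + 1L) != "T"]
        if (length(dd)) { pd <- .pick1(dd); found <- TRUE; break }
      }
      if (!found) stop_sl("sl_domain", "no cryptic donor/acceptor geometry available")
      v <- mk_var(i, pd + 1L, "T", side = "donor")
      ga <- c_to_genomic(gene, hgvs_coding_position(.intron_anchor(gene, i, "acceptor"),
                                                    pga - L - 1L))
      gd <- c_to_genomic(gene, hgvs_coding_position(.intron_anchor(gene, i, "donor"), pd))
      ev <- splice_event("crypEins", i, cryptic_donor = gd, cryptic_acceptor = ga)
      pseudo <- substr(alt_intron(i, v), pga + 1L, pd - 1L)
      lab_mrna <- paste0(paste(exs[seq_len(i)], collapse = ""), pseudo,
                         paste(exs[seq(i + 1L, length(exs))], collapse = ""))
      label <- .oracle_label(ref_mrna, lab_mrna, cds_start)
    } else {                                      # neutral
      i <- .pick1(seq_len(n_int))
      s <- intron_seq(gene, i); L <- nchar(s)
      o <- .pick1(seq(-60L, -45L))                # interior: no AG can form
      ref <- substring(s, L + 1L + o, L + 1L + o)
      v <- mk_var(i, o, if (ref == "C") "T" else "C")
      ev <- splice_event("canonical")
      label <- "No change"
    }
    list(variant = v,
         truth = structure(list(lesion_kind = lesion_kind, expected_event = ev,
                                expected_label = label, intron = if (ev$kind == "canonical")
                                  NA_integer_ else ev$target_index),
                           class = "PlantedTruth"))
  })
}

#' Simulate a cohort carrier table
#'
#' Draws per-variant carrier counts from a zero-inflated geometric law
#' (mimicking the heavy skew of real recurrence tables: many undetected or
#' singleton variants, few recurrent ones), other-phenotype carrier counts
#' binomially against the specificity parameter, and annotation columns from
#' the splicing-defect vocabulary.  Deterministic per seed.
#'
#' @param config A [simulation_config()] (its `cohort` element is used).
#' @param seed Integer seed.
#' @param proximal_max_nt Proximal/deep boundary passed through to the
#'   derived `location_class`.
#' @return A `CohortTable` data frame (same columns as
#'   [read_cohort_table()]).
#' @export
simulate_cohort <- function(config = simulation_config(), seed = 1L,
                            proximal_max_nt = 60L) {
  p <- config$cohort
  with_seed(seed, {
    n <- p$n_variants
    detected <- stats::runif(n) >= p$zero_inflation
    n_hcm <- ifelse(detected, 1L + stats::rgeom(n, p$geom_prob), 0L)
    q <- (1 - p$specificity) / p$specificity
    if (q < 0 || q > 1)
      stop_sl("sl_validation", "cohort specificity parameter must be in (0.5, 1]")
    n_other <- stats::rbinom(n, size = n_hcm, prob = q)
    proximal <- stats::runif(n) < 0.7
    mag <- ifelse(proximal, sample(3:60, n, replace = TRUE),
                  sample(61:1500, n, replace = TRUE))
    offs <- mag * sample(c(-1L, 1L), n, replace = TRUE, prob = c(0.6, 0.4))
    anchor <- sample(100:4000, n, replace = TRUE)
    ref <- sample(DNA_BASES, n, replace = TRUE)
    alt <- vapply(ref, function(r) .pick1(setdiff(DNA_BASES, r)), "")
    intron <- sort(sample(1:33, n, replace = TRUE))
    defect <- sample(c("Esk", "Etr", "Eext", "cRi", "pRi", "crypEins"), n,
                     replace = TRUE, prob = c(0.5, 0.05, 0.1, 0.1, 0.15, 0.1))
    lab <- sample(c("Frameshift-PTC", "Stop gain-PTC", "In-frame (del 33 aa)"),
                  n, replace = TRUE, prob = c(0.75, 0.1, 0.15))
    d <- data.frame(
      vid = sprintf("s%d", seq_len(n)),
      coding_name = sprintf("c.%d%+d%s>%s", anchor, offs, ref, alt),
      intron = intron, n_hcm = n_hcm, n_other = n_other,
      spliceai_delta = round(stats::rbeta(n, 1.2, 0.8), 2L),
      defect_class = sprintf("%s%d", defect, intron),
      trf_label = lab, stringsAsFactors = FALSE)
    d$offset <- offs
    d$location_class <- ifelse(abs(offs) <= proximal_max_nt, "proximal", "deep")
    class(d) <- c("CohortTable", "data.frame")
    d
  })
}
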