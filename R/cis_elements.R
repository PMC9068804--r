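# Acceptor-side cis-element analysis: AG-exclusion zone, branchpoint window,
# position-weight-matrix acceptor scoring and SR-protein motif scanning.
#
# Offsets follow the HGVS intronic convention: the last intron base before
# the exon is -1, so the canonical acceptor AG occupies offsets -2/-1.

# G positions (sense, 1-based) of every AG dinucleotide in a string
.ag_g_positions <- function(s) {
  hits <- gregexpr("(?=AG)", s, perl = TRUE)[[1L]]
  if (hits[1L] == -1L) integer() else as.integer(hits) + 1L
}

#' Scan the AG-exclusion zone of an intron for a variant-created acceptor AG
#'
#' The AG-exclusion zone (AEZ) of an intron is the region between the splice
#' acceptor site and the first upstream AG dinucleotide — covering the
#' branchpoint sequence and the polypyrimidine tract — which is normally
#' devoid of AG dinucleotides.  A substitution that creates a new AG strictly
#' inside this zone tends to act as a cryptic splice acceptor.  This scan
#' locates the first upstream AG in the reference intron, determines whether
#' the variant creates an AG, and whether the created AG breaks the zone.
#'
#' @param gene A `GeneModel`.
#' @param variant An acceptor-side intronic `Variant` (negative offset).
#' @return An `AezReport`: list with `intron_index`, `aez_start_offset`
#'   (offset of the G of the first upstream reference AG; NA when the intron
#'   has none upstream of the acceptor), `variant_creates_ag`,
#'   `created_ag_offset`, `breaks_aez`, and `created_is_first_upstream`
#'   (whether the created AG is the first AG upstream of the canonical
#'   acceptor in the alternate sequence).
#' @export
scan_aez <- function(gene, variant) {
  v <- resolve_variant(gene, variant)
  if (v$pos$offset >= 0L)
    stop_sl("sl_domain",
            "AEZ scanning is defined for acceptor-side (negative-offset) intronic variants")
  loc <- intron_of(gene, v)
  i <- loc$intron
  ref <- intron_seq(gene, i)
  alt <- intron_seq(gene, i, sequence = apply_variant(gene, v))
  L <- nchar(ref)
  to_off <- function(p) p - L - 1L                   # sense pos -> offset

  ref_ag <- to_off(.ag_g_positions(ref))
  alt_ag <- to_off(.ag_g_positions(alt))
  ref_up <- ref_ag[ref_ag <= -3L]                    # exclude the acceptor AG
  alt_up <- alt_ag[alt_ag <= -3L]
  aez_start <- if (length(ref_up)) max(ref_up) else NA_integer_

  created <- setdiff(alt_up, ref_up)
  creates <- length(created) > 0L
  created_off <- if (creates) max(created) else NA_integer_
  breaks <- creates && (is.na(aez_start) || created_off > aez_start)
  first_up <- creates && length(alt_up) && max(alt_up) == created_off

  structure(list(intron_index = i, aez_start_offset = aez_start,
                 variant_creates_ag = creates, created_ag_offset = created_off,
                 breaks_aez = breaks, created_is_first_upstream = first_up,
                 intron_length = L),
            class = "AezReport")
}

#' @export
print.AezReport <- function(x, ...) {
  cat(sprintf("AezReport intron %d: first upstream AG at %s; variant %s%s\n",
              x$intron_index,
              ifelse(is.na(x$aez_start_offset), "none", x$aez_start_offset),
              if (x$variant_creates_ag)
                sprintf("creates AG at %d", x$created_ag_offset) else "creates no AG",
              if (isTRUE(x$breaks_aez)) " (breaks the AG-exclusion zone)" else ""))
  invisible(x)
}

#' Branchpoint-window membership of an acceptor-side intronic variant
#'
#' Most human splicing branchpoints lie upstream of the polypyrimidine tract,
#' at offsets -37 to -19 from the splice acceptor site; a variant inside this
#' window may perturb branchpoint recognition.
#'
#' @param variant A `Variant` with an acceptor-side coding position, or a
#'   plain negative offset.
#' @param window Closed offset interval, default `c(-37, -19)`.
#' @return A `BranchWindowReport`: list with `in_window`, `offset`, `window`.
#' @export
branch_window <- function(variant, window = c(-37L, -19L)) {
  off <- if (inherits(variant, "Variant")) variant$pos$offset else as.integer(variant)
  if (!(window[1L] < 0L && window[2L] < 0L && window[1L] <= window[2L]))
    stop_sl("sl_validation", "window bounds must be negative with lower <= upper")
  if (off >= 0L)
    stop_sl("sl_domain", "branchpoint window applies to acceptor-side (negative) offsets")
  structure(list(in_window = off >= window[1L] && off <= window[2L],
                 offset = off, window = as.integer(window)),
            class = "BranchWindowReport")
}

# sense-strand pre-mRNA context around a plus-strand genomic position:
# `up` bases before it and `down` after it, in the reading direction
sense_context <- function(gene, g, up, down) {
  if (gene$strand == "+") gene_seq(gene, g - up, g + down)
  else revcomp(gene_seq(gene, g - down, g + up))
}

#' Train a splice-acceptor position-frequency matrix from gene models
#'
#' Collects the acceptor context of every intron of the supplied gene models
#' over the offset window `[-14, +2]` (14 intronic positions ending at the
#' acceptor G, plus the first 2 exonic positions) and builds a log-odds
#' position weight matrix against a uniform background.  The pseudocount is a
#' fraction added to the per-column base frequencies (not to raw counts), so
#' training is scale-free: duplicating the corpus leaves the matrix — and all
#' scores — unchanged.  The observed score range of the training acceptors is
#' stored for min-max normalization.
#'
#' @param genes List of `GeneModel`s supplying at least `min_sites` canonical
#'   acceptors in total.
#' @param pseudocount Fraction added to each per-column base frequency.
#' @param min_sites Minimum number of training acceptors.
#' @return An `AcceptorPwm` object usable with [score_acceptor()].
#' @export
train_acceptor_pwm <- function(genes, pseudocount = 0.01, min_sites = 20L) {
  if (inherits(genes, "GeneModel")) genes <- list(genes)
  ctx <- unlist(lapply(genes, function(g) {
    iv <- intron_intervals(g)
    vapply(seq_len(nrow(iv)), function(i) {
      gG <- if (g$strand == "+") iv$end[i] else iv$start[i]  # the acceptor G
      sense_context(g, gG, up = 13L, down = 2L)
    }, "")
  }))
  if (length(ctx) < min_sites)
    stop_sl("sl_training",
            sprintf("need at least %d canonical acceptors to train, got %d",
                    min_sites, length(ctx)))
  m <- do.call(rbind, strsplit(ctx, ""))
  counts <- apply(m, 2L, function(col) table(factor(col, levels = DNA_BASES)))
  prop <- sweep(counts, 2L, colSums(counts), "/")
  freq <- (prop + pseudocount) / (1 + 4 * pseudocount)
  pwm <- log2(freq / 0.25)
  obj <- structure(list(pwm = pwm, window = c(-14L, 2L), n_sites = length(ctx)),
                   class = "AcceptorPwm")
  raw <- vapply(ctx, function(s) .pwm_raw_score(obj, s), 0)
  obj$score_range <- range(raw)
  obj
}

.pwm_raw_score <- function(pwm_obj, s) {
  b <- strsplit(s, "")[[1L]]
  sum(pwm_obj$pwm[cbind(match(b, DNA_BASES), seq_along(b))])
}

#' Score a candidate splice-acceptor AG against a trained corpus
#'
#' The candidate's context window is scored with the corpus position weight
#' matrix and min-max normalized against the scores of the training
#' acceptors, giving a relative strength in `[0, 1]` (clamped).  Deterministic
#' given the corpus and pseudocount.
#'
#' @param pwm An `AcceptorPwm` from [train_acceptor_pwm()], or a list of
#'   `GeneModel`s to train on the fly.
#' @param gene `GeneModel` supplying the candidate's sequence context.
#' @param candidate Plus-strand genomic coordinate of the G of the candidate
#'   AG.
#' @param context Alternatively, a raw 16-nt sense context (offsets -14..+2,
#'   the AG at positions 13-14) scored directly instead of `gene`/`candidate`.
#' @return Relative strength score in `[0, 1]`.
#' @export
score_acceptor <- function(pwm, gene = NULL, candidate = NULL, context = NULL) {
  if (!inherits(pwm, "AcceptorPwm")) pwm <- train_acceptor_pwm(pwm)
  ctx <- if (!is.null(context)) toupper(context)
         else sense_context(gene, candidate, up = 13L, down = 2L)
  if (nchar(ctx) != 16L)
    stop_sl("sl_validation", "acceptor context must be 16 nt (offsets -14..+2)")
  if (substr(ctx, 13L, 14L) != "AG")
    stop_sl("sl_validation", "candidate coordinate is not the G of an AG dinucleotide")
  raw <- .pwm_raw_score(pwm, ctx)
  rng <- pwm$score_range
  if (diff(rng) == 0) return(1)
  min(1, max(0, (raw - rng[1L]) / diff(rng)))
}

#' Default SR-protein binding-motif table
#'
#' Two experimentally assessed exon-definition motifs: AGAGG bound by SRSF5
#' (SRp40) and GGCCTCC bound by SRSF2 (SC35), each with score +5 (positive
#' scores mark target sequences that facilitate exon definition).  Motifs are
#' stored in the DNA alphabet; RNA input (U) is normalized to T.
#'
#' @export
default_sr_motifs <- function() {
  data.frame(factor = c("SRSF5 (SRp40)", "SRSF2 (SC35)"),
             motif = c("AGAGG", "GGCCTCC"),
             score = c(5L, 5L))
}

#' Scan for SR-protein binding motifs created (or kept) by a variant
#'
#' Compares the sense-strand sequence context within `flank` nt of the
#' variant between the reference and alternate alleles, and reports every
#' motif occurrence in the alternate sequence, flagging those absent from the
#' reference at the same position as created by the variant.
#'
#' @param gene A `GeneModel`.
#' @param variant A `Variant`.
#' @param motif_table Data frame with columns `factor`, `motif`, `score`
#'   (DNA or RNA alphabet); defaults to [default_sr_motifs()].
#' @param flank Context half-width in nt (default 10).
#' @return Data frame of `MotifHit` rows: `factor_name`, `motif`, `score`,
#'   `created_by_variant`, `rel_start` (motif start relative to the variant
#'   position), `offset` (motif start relative to the splice acceptor, for
#'   acceptor-side intronic variants; NA otherwise).
#' @export
scan_sr_motifs <- function(gene, variant, motif_table = default_sr_motifs(),
                           flank = 10L) {
  v <- resolve_variant(gene, variant)
  motif_table$motif <- toupper(gsub("U", "T", motif_table$motif))
  ref_ctx <- sense_context(gene, v$genomic, flank, flank)
  alt_ctx <- ref_ctx
  substr(alt_ctx, flank + 1L, flank + 1L) <- v$alt
  hits <- lapply(seq_len(nrow(motif_table)), function(r) {
    m <- motif_table$motif[r]
    a <- gregexpr(m, alt_ctx, fixed = TRUE)[[1L]]
    if (a[1L] == -1L) return(NULL)
    rf <- gregexpr(m, ref_ctx, fixed = TRUE)[[1L]]
    rf <- if (rf[1L] == -1L) integer() else as.integer(rf)
    data.frame(factor_name = motif_table$factor[r], motif = m,
               score = motif_table$score[r],
               created_by_variant = !(as.integer(a) %in% rf),
               rel_start = as.integer(a) - (flank + 1L))
  })
  out <- do.call(rbind, hits)
  if (is.null(out))
    out <- data.frame(factor_name = character(), motif = character(),
                      score = integer(), created_by_variant = logical(),
                      rel_start = integer())
  out$offset <- if (v$pos$offset < 0L) v$pos$offset + out$rel_start
                else rep(NA_integer_, nrow(out))
  out
}
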