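# Deterministic fixtures built in code.

SENSE_CODONS <- local({
  b <- c("A", "C", "G", "T")
  cods <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(cods, c("TAA", "TAG", "TGA"))
})

rand_codons <- function(n) paste(sample(SENSE_CODONS, n, replace = TRUE), collapse = "")

# Three-exon toy gene with exact, hand-checked geometry:
#   exons 90 / 99 / 120 nt; introns 100 / 81 nt; 12 nt 5'UTR, 15 nt 3'UTR,
#   CDS 282 nt (codon boundaries at both internal junctions).
# Intron 1 carries an internal consecutive AG pair ("AGCAG": G positions 38
# and 41, retained lengths 62/59).  Intron 2 (81 nt, a multiple of 3) carries
# an in-frame TAA at positions 10-12, so complete retention of intron 2 is a
# stop gain.
toy_gene <- function() {
  set.seed(4242)
  utr5 <- "CCTCTCCCTCCC"                                       # 12
  cds <- paste0("ATG", rand_codons(92L), "TAA")                # 282
  utr3 <- "CCCTTTCCCTTTCCC"                                    # 15
  mrna <- paste0(utr5, cds, utr3)                              # 309
  stopifnot(nchar(mrna) == 309L)
  exon1 <- substr(mrna, 1L, 90L)
  exon2 <- substr(mrna, 91L, 189L)
  exon3 <- substr(mrna, 190L, 309L)
  intron1 <- paste0("GTAAGT", strrep("CT", 15L), "AGCAG", strrep("TC", 19L), "T",
                    "CTTTCCTTTCCTTTCCTT", "AG")                # 100
  intron2 <- paste0("GTAAGT", "CTC", "TAA", strrep("CT", 24L), "T",
                    "CTTTCCTTTCCTTTCCTT", "AG")                # 81
  stopifnot(nchar(intron1) == 100L, nchar(intron2) == 81L)
  pad <- "ACGTACGTAC"
  genome <- paste0(pad, exon1, intron1, exon2, intron2, exon3, pad)
  starts <- c(11L, 11L + 90L + 100L, 11L + 90L + 100L + 99L + 81L)
  gene_model("toy", data.frame(start = starts, end = starts + c(90L, 99L, 120L) - 1L),
             sequence = genome, cds_start = 13L, cds_end = 294L,
             strand = "+", chromosome_name = "chrT")
}

# Plus-strand toy from the coordinate examples: exon1 = 101..200 with c.1 at
# 101 (no UTR), intron1 = 201..300, exon2 = 301..400; CDS covers everything.
coord_gene <- function() {
  set.seed(7)
  exon1 <- paste0("ATG", rand_codons(32L), "C")                # 100
  exon2 <- paste0(rand_codons(32L), "TAA", "C")                # 100
  intron <- paste0("GTAAGT", strrep("CT", 37L), "CTTTCCTTTCCTTTCCTT", "AG")  # 100
  genome <- paste0(strrep("ACGTACGTAC", 10L), exon1, intron, exon2,
                   strrep("ACGTACGTAC", 10L))
  gene_model("coordtoy", data.frame(start = c(101L, 301L), end = c(200L, 400L)),
             sequence = genome, cds_start = 1L, cds_end = 199L,
             strand = "+", chromosome_name = "chrC")
}

# Independent brute-force splicing oracle: direct string slicing on the
# sense pre-mRNA, no shared code with reconstruct_transcript().
oracle_splice <- function(gene, events, variant = NULL) {
  genome <- gene$sequence
  if (!is.null(variant)) {
    v <- resolve_variant(gene, variant)
    substr(genome, v$genomic, v$genomic) <- v$g_alt
  }
  stopifnot(gene$strand == "+")
  ex <- lapply(seq_len(n_exons(gene)), function(i)
    substr(genome, gene$exons$start[i], gene$exons$end[i]))
  iv <- intron_intervals(gene)
  intr <- lapply(seq_len(nrow(iv)), function(i) substr(genome, iv$start[i], iv$end[i]))
  if (inherits(events, "SpliceEvent")) events <- list(events)
  between <- rep("", n_exons(gene))   # material appended after exon i
  for (e in events) {
    k <- e$target_index
    if (e$kind == "exon_skip") ex[[k]] <- ""
    else if (e$kind == "intron_retention_complete") between[k] <- intr[[k]]
    else if (e$kind == "intron_retention_partial") {
      if (!is.null(e$cryptic_acceptor)) {
        p <- e$cryptic_acceptor - iv$start[k] + 1L
        between[k] <- substr(intr[[k]], p + 1L, nchar(intr[[k]]))
      } else {
        p <- e$cryptic_donor - iv$start[k] + 1L
        between[k] <- substr(intr[[k]], 1L, p - 1L)
      }
    } else if (e$kind == "cryptic_exon_insertion") {
      pa <- e$cryptic_acceptor - iv$start[k] + 1L
      pd <- e$cryptic_donor - iv$start[k] + 1L
      between[k] <- substr(intr[[k]], pa + 1L, pd - 1L)
    }
  }
  out <- ""
  for (i in seq_len(n_exons(gene))) {
    out <- paste0(out, ex[[i]])
    if (i < n_exons(gene)) out <- paste0(out, between[i])
  }
  out
}

# Independent brute-force AEZ oracle working on raw strings.
oracle_aez <- function(ref_intron, alt_intron) {
  first_up <- function(s) {
    L <- nchar(s)
    for (o in seq(-3L, -(L - 1L))) {
      if (substr(s, L + o, L + 1L + o) == "AG") return(o)
    }
    NA_integer_
  }
  L <- nchar(ref_intron)
  ags <- function(s) {
    out <- integer()
    for (o in seq(-(L - 1L), -3L))
      if (substr(s, L + o, L + 1L + o) == "AG") out <- c(out, o)
    out
  }
  r <- ags(ref_intron); a <- ags(alt_intron)
  created <- setdiff(a, r)
  fu <- first_up(ref_intron)
  creates <- length(created) > 0L
  co <- if (creates) max(created) else NA_integer_
  list(aez_start_offset = fu, variant_creates_ag = creates, created_ag_offset = co,
       breaks_aez = creates && (is.na(fu) || co > fu))
}

# Minigene test harness: vector + tailed cloning primers for a plus-strand
# gene, annealing from the first codon of the CDS to a frame-compatible
# position in the last exon.
toy_minigene_parts <- function(gene) {
  stopifnot(gene$strand == "+")
  region_start <- gene$exons$start[1L]
  region_end <- gene$exons$end[n_exons(gene)]
  region <- gene_seq(gene, region_start, region_end)
  cds_g <- gene$exons$start[1L] + gene$cds_start - 1L   # CDS start (exon 1)
  f_at <- cds_g - region_start + 1L
  introns_len <- sum(intron_intervals(gene)$length)
  # choose reverse anneal end e (in region coords, inside the last exon and
  # upstream of the natural stop codon, which must not be cloned) so that the
  # digested insert splices to a multiple of 3:
  # insert = GGCCGC (6) + region[f_at..e] minus introns + GAT (3)
  stop_region <- transcript_to_genomic(gene, gene$cds_end - 2L) - region_start + 1L
  e <- stop_region - 1L
  while ((6L + (e - f_at + 1L - introns_len) + 3L) %% 3L != 0L) e <- e - 1L
  fwd <- primer("cloneF", paste0("TATA", "GCGGCCGC", substr(region, f_at, f_at + 17L)))
  rev <- primer("cloneR", paste0("CAGC", "GATATC",
                                 revcomp(substr(region, e - 17L, e))), "reverse")
  flag <- "GATTACAAGGATGACGATGACAAG"            # DYKDDDDK
  myc <- "GAACAAAAACTCATCTCAGAAGAGGATCTG"       # EQKLISEEDL
  vec <- vector_spec(n_prefix = paste0("ATG", flag),
                     c_suffix = paste0(myc, "TAA"))
  list(fwd = fwd, rev = rev, vector = vec, anneal_end = e, anneal_start = f_at)
}
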