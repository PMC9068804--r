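# Standard-format surfaces: GFF3 + FASTA gene models, transcript FASTA,
# primer/event TSVs and minimal VCF reading for SNVs.

#' Write a gene model as GFF3 + FASTA
#'
#' Emits one mRNA with its exon and CDS features (1-based inclusive, as GFF3
#' requires) and the plus-strand genomic sequence of the modeled region.
#'
#' @param gene A `GeneModel`.
#' @param gff3_path,fasta_path Output paths.
#' @export
write_gene_model <- function(gene, gff3_path, fasta_path) {
  cum <- cumsum(exon_lengths(gene))
  blocks <- .transcript_blocks_to_genomic(gene, gene$cds_start, gene$cds_end)
  tx_id <- ifelse(is.na(gene$transcript_accession), paste0(gene$gene_id, ".t1"),
                  gene$transcript_accession)
  feat <- rbind(
    data.frame(type = "mRNA", start = min(gene$exons$start), end = max(gene$exons$end),
               attr = sprintf("ID=%s;gene_id=%s", tx_id, gene$gene_id)),
    data.frame(type = "exon", start = gene$exons$start, end = gene$exons$end,
               attr = sprintf("Parent=%s;exon_number=%d", tx_id, seq_len(n_exons(gene)))),
    data.frame(type = "CDS", start = blocks$start, end = blocks$end,
               attr = sprintf("Parent=%s", tx_id)))
  gr <- GenomicRanges::GRanges(
    seqnames = gene$chromosome_name,
    ranges = IRanges::IRanges(feat$start, feat$end),
    strand = gene$strand, type = feat$type,
    source = "spliceLesion")
  # rtracklayer carries free-form columns into column 9
  S4Vectors::mcols(gr)$ID <- sub(";.*", "", sub("^ID=", "", ifelse(feat$type == "mRNA", feat$attr, NA)))
  S4Vectors::mcols(gr)$Parent <- ifelse(feat$type == "mRNA", NA, tx_id)
  S4Vectors::mcols(gr)$gene_id <- gene$gene_id
  prior <- c(0L, cumsum(blocks$end - blocks$start + 1L))[seq_len(nrow(blocks))]
  S4Vectors::mcols(gr)$phase <- c(rep(NA_integer_, nrow(feat) - nrow(blocks)),
                                  (3L - prior %% 3L) %% 3L)
  rtracklayer::export(sort(gr, ignore.strand = TRUE), gff3_path, format = "gff3")
  seqs <- Biostrings::DNAStringSet(gene$sequence)
  names(seqs) <- gene$chromosome_name
  Biostrings::writeXStringSet(seqs, fasta_path)
  invisible(c(gff3 = gff3_path, fasta = fasta_path))
}

# genomic blocks (plus-strand intervals, transcript order) of a transcript range
.transcript_blocks_to_genomic <- function(gene, t1, t2) {
  cum <- cumsum(exon_lengths(gene)); prev <- c(0L, cum)
  out <- NULL
  for (k in seq_len(n_exons(gene))) {
    a <- max(t1, prev[k] + 1L); b <- min(t2, cum[k])
    if (a > b) next
    if (gene$strand == "+") {
      gs <- gene$exons$start[k] + (a - prev[k] - 1L)
      ge <- gene$exons$start[k] + (b - prev[k] - 1L)
    } else {
      ge <- gene$exons$end[k] - (a - prev[k] - 1L)
      gs <- gene$exons$end[k] - (b - prev[k] - 1L)
    }
    out <- rbind(out, data.frame(start = gs, end = ge))
  }
  out
}

#' Read a gene model from GFF3 + FASTA
#'
#' Accepts a GFF3 with the exon and CDS features of a single transcript and a
#' FASTA whose (first) record is the plus-strand sequence the GFF3
#' coordinates index into.
#'
#' @param gff3_path,fasta_path Input paths.
#' @return A `GeneModel`.
#' @export
read_gene_model <- function(gff3_path, fasta_path) {
  gr <- rtracklayer::import(gff3_path, format = "gff3")
  ex <- gr[gr$type == "exon"]
  cds <- gr[gr$type == "CDS"]
  if (!length(ex)) stop_sl("sl_parse", "GFF3 contains no exon features")
  if (!length(cds)) stop_sl("sl_parse", "GFF3 contains no CDS features")
  strand <- as.character(BiocGenerics::strand(ex))[1L]
  if (strand == "*") strand <- "+"
  exons <- data.frame(start = BiocGenerics::start(ex), end = BiocGenerics::end(ex))
  exons <- exons[order(exons$start, decreasing = (strand == "-")), ]
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  sequence <- as.character(seqs[[1L]])
  gid <- unlist(ex$gene_id)[1L] %||% "gene"
  mrna <- gr[gr$type == "mRNA"]
  acc <- if (length(mrna)) as.character(mrna$ID[1L]) else NA_character_
  tmp <- gene_model(gid, exons, sequence, cds_start = 1L, cds_end = 2L,
                    strand = strand)
  g_first <- if (strand == "+") min(BiocGenerics::start(cds)) else max(BiocGenerics::end(cds))
  g_last <- if (strand == "+") max(BiocGenerics::end(cds)) else min(BiocGenerics::start(cds))
  cs <- genomic_to_transcript(tmp, g_first)
  ce <- genomic_to_transcript(tmp, g_last)
  gene_model(gid, exons, sequence, cds_start = cs, cds_end = ce,
             strand = strand, chromosome_name = as.character(GenomicRanges::seqnames(ex))[1L],
             transcript_accession = acc)
}

#' Mirror a gene model onto the opposite strand
#'
#' Reverse-complements the modeled sequence and mirrors all coordinates, so
#' the returned model describes the same transcript on the other strand.
#' HGVS c. names of corresponding variants are invariant under this flip.
#'
#' @param gene A `GeneModel`.
#' @export
flip_gene_model <- function(gene) {
  N <- nchar(gene$sequence)
  gene_model(gene$gene_id,
             data.frame(start = N - gene$exons$end + 1L,
                        end = N - gene$exons$start + 1L),
             sequence = revcomp(gene$sequence),
             cds_start = gene$cds_start, cds_end = gene$cds_end,
             strand = ifelse(gene$strand == "+", "-", "+"),
             chromosome_name = gene$chromosome_name,
             transcript_accession = gene$transcript_accession)
}

#' Write transcripts as FASTA with junction annotations
#'
#' Junction positions and the CDS start are recorded in the description line.
#'
#' @param transcripts Named list of `MatureTranscript`s.
#' @param path Output FASTA path.
#' @export
write_transcript_fasta <- function(transcripts, path) {
  seqs <- Biostrings::DNAStringSet(vapply(transcripts, function(t) t$sequence, ""))
  names(seqs) <- vapply(seq_along(transcripts), function(i) {
    t <- transcripts[[i]]
    nm <- names(transcripts)[i] %||% sprintf("transcript_%d", i)
    sprintf("%s junctions=%s cds_start=%d", nm,
            paste(t$junctions, collapse = ","), t$cds_start)
  }, "")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read splice events from a TSV
#'
#' Columns: `kind`, `target` and optional `cryptic_donor`, `cryptic_acceptor`
#' (genomic coordinates; empty/NA when absent).
#'
#' @param path TSV path.
#' @return List of `SpliceEvent`s.
#' @export
read_events_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(d)), function(i) {
    cd <- d$cryptic_donor[i]; ca <- d$cryptic_acceptor[i]
    splice_event(d$kind[i], d$target[i],
                 cryptic_donor = if (!is.null(cd) && !is.na(cd)) cd else NULL,
                 cryptic_acceptor = if (!is.null(ca) && !is.na(ca)) ca else NULL)
  })
}

#' Read primers from a TSV
#'
#' Columns: `name`, `sequence`, `orientation`.
#'
#' @param path TSV path.
#' @return Named list of `Primer`s.
#' @export
read_primers_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(d)), function(i)
    primer(d$name[i], d$sequence[i], d$orientation[i]))
  names(out) <- d$name
  out
}

#' Read single-nucleotide variants from a minimal VCF
#'
#' Only CHROM/POS/REF/ALT are used; non-SNV records are rejected.
#'
#' @param path VCF path (plain text, v4).
#' @return Data frame with `chrom`, `pos`, `ref`, `alt` and a `variants`
#'   list-column of `Variant`s (genomic positions).
#' @export
read_variants_vcf <- function(path) {
  if (requireNamespace("vcfR", quietly = TRUE)) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
    d <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                    ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE)
  } else {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "#")]
    f <- do.call(rbind, strsplit(lines, "\t"))
    d <- data.frame(chrom = f[, 1L], pos = as.integer(f[, 2L]),
                    ref = f[, 4L], alt = f[, 5L], stringsAsFactors = FALSE)
  }
  if (any(nchar(d$ref) != 1L | nchar(d$alt) != 1L))
    stop_sl("sl_parse", "only single-nucleotide substitutions are supported")
  d$variants <- lapply(seq_len(nrow(d)), function(i)
    variant(d$pos[i], d$ref[i], d$alt[i]))
  d
}
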