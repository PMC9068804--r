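test_that("exact-match PCR recovers template-end products and agrees with substring arithmetic", {
  g <- toy_gene()
  tx <- reconstruct_transcript(g)
  s <- tx$sequence
  fwd <- primer("F1", substr(s, 1L, 20L))
  rev <- primer("R1", revcomp(substr(s, nchar(s) - 19L, nchar(s))), "reverse")
  amp <- insilico_pcr(tx, fwd, rev)
  expect_equal(nrow(amp), 1L)
  expect_equal(amp$length, nchar(s))
  expect_equal(amp$sequence, s)
  # internal pair: length equals rev 3' end - fwd 5' start + 1 (substring oracle)
  f2 <- primer("F2", substr(s, 31L, 52L))
  r2 <- primer("R2", revcomp(substr(s, 201L, 224L)), "reverse")
  amp2 <- insilico_pcr(tx, f2, r2)
  expect_equal(amp2$length, 224L - 31L + 1L)
  expect_equal(amp2$sequence, substr(s, 31L, 224L))
  # no binding is an empty result, not an error
  expect_equal(nrow(insilico_pcr(tx, primer("FX", strrep("ACGTT", 4L)), rev)), 0L)
})

test_that("junction-spanning primers only amplify spliced templates", {
  g <- toy_gene()
  tx <- reconstruct_transcript(g)
  s <- tx$sequence
  j <- tx$junctions[1L]
  jf <- primer("JF", substr(s, j - 9L, j + 10L))
  rev <- primer("R", revcomp(substr(s, nchar(s) - 19L, nchar(s))), "reverse")
  expect_equal(nrow(insilico_pcr(tx, jf, rev)), 1L)
  pre_mrna <- gene_seq(g, 1L, nchar(g$sequence))
  expect_equal(nrow(insilico_pcr(pre_mrna, jf, rev)), 0L)
  # the aberrant transcript retaining intron 1 also loses the junction site
  cri <- reconstruct_transcript(g, splice_event("cRi", 1L))
  expect_equal(nrow(insilico_pcr(cri, jf, rev)), 0L)
})

test_that("product-size difference between aberrant and canonical equals the retained intron", {
  # the internal consistency behind comparing minigene and blood assays:
  # with any primer pair flanking the intron, aberrant - canonical product
  # sizes equal the retained length, whatever the template ends look like
  g <- toy_gene()
  canon <- reconstruct_transcript(g)
  cri <- reconstruct_transcript(g, splice_event("cRi", 1L))
  s <- canon$sequence
  fwd <- primer("F", substr(s, 41L, 60L))                     # inside exon 1
  rev <- primer("R", revcomp(substr(s, 230L, 249L)), "reverse")  # inside exon 3
  a_can <- insilico_pcr(canon, fwd, rev)
  a_cri <- insilico_pcr(cri, fwd, rev)
  expect_equal(a_cri$length - a_can$length, 100L)
  ags <- enumerate_consecutive_ag_acceptors(g, 1L)
  for (p in which(ags$paired)) {
    pri <- reconstruct_transcript(g, splice_event("pRi", 1L,
                                                  cryptic_acceptor = ags$genomic[p]))
    a_pri <- insilico_pcr(pri, fwd, rev)
    expect_equal(a_pri$length - a_can$length, ags$retained_length[p])
  }
})

test_that("nested PCR amplifies within the first-round product", {
  g <- toy_gene()
  tx <- reconstruct_transcript(g)
  s <- tx$sequence
  f1 <- primer("601", substr(s, 1L, 22L))
  r1 <- primer("602", revcomp(substr(s, 281L, 300L)), "reverse")
  r2 <- primer("603", revcomp(substr(s, 221L, 243L)), "reverse")
  final <- nested_pcr(tx, list(f1, r1), list(f1, r2))
  expect_equal(final$length, 243L)
  # identical rounds give the same product
  same <- nested_pcr(tx, list(f1, r1), list(f1, r1))
  expect_equal(same$length, 300L)
  # a round-2 primer outside the round-1 product fails containment
  r_out <- primer("604", revcomp(substr(s, nchar(s) - 19L, nchar(s))), "reverse")
  expect_error(nested_pcr(tx, list(f1, r1), list(f1, r_out)), class = "sl_domain")
})

test_that("minigene construction digests, clones in frame and predicts tag positivity", {
  g <- toy_gene()
  parts <- toy_minigene_parts(g)
  mgd <- build_minigene(g, c(1L, 3L), parts$fwd, parts$rev, parts$vector)
  expect_true(mgd$frame_ok_n)
  expect_true(mgd$frame_ok_c)
  expect_equal(length(mgd$intron_index), 2L)       # both introns inside the insert
  # insert length: NotI leftover (6) + annealed genomic stretch + EcoRV leftover (3)
  expect_equal(mgd$insert_length,
               6L + (parts$anneal_end - parts$anneal_start + 1L) + 3L)
  canonical <- minigene_tag_positive(mgd)
  expect_true(canonical$n_tag_positive)
  expect_true(canonical$c_tag_positive)
  # complete retention of minigene intron 1 (100 nt, frameshift): C-tag lost
  mis <- minigene_tag_positive(mgd, splice_event("cRi", 1L))
  expect_true(mis$n_tag_positive)
  expect_false(mis$c_tag_positive)
  # in-frame retention with a planted stop (intron 2): C-tag also lost
  mis2 <- minigene_tag_positive(mgd, splice_event("cRi", 2L))
  expect_false(mis2$c_tag_positive)
})

test_that("frame bookkeeping detects a 1-nt slip at the 5' junction", {
  g <- toy_gene()
  parts <- toy_minigene_parts(g)
  region <- gene_seq(g, g$exons$start[1L], g$exons$end[3L])
  slipped <- primer("cloneF_slip",
                    paste0("TATA", "GCGGCCGC",
                           substr(region, parts$anneal_start + 1L, parts$anneal_start + 18L)))
  mgd <- build_minigene(g, c(1L, 3L), slipped, parts$rev, parts$vector)
  expect_false(mgd$frame_ok_n)
})

test_that("an internal restriction site is a design error", {
  g <- toy_gene()
  parts <- toy_minigene_parts(g)
  poisoned <- g
  # plant a NotI site inside intron 1 interior
  substr(poisoned$sequence, 121L, 128L) <- "GCGGCCGC"
  expect_error(build_minigene(poisoned, c(1L, 3L), parts$fwd, parts$rev, parts$vector),
               class = "sl_design")
})

test_that("average protein mass follows the residue table", {
  expect_equal(protein_mass(""), 18.0153, tolerance = 1e-6)
  expect_equal(protein_mass(strrep("G", 10L)), 10 * 57.0519 + 18.0153, tolerance = 1e-4)
  # an independently summed tripeptide: A + W + C + water
  expect_equal(protein_mass("AWC"), 71.0788 + 186.2132 + 103.1388 + 18.0153,
               tolerance = 1e-4)
  expect_error(protein_mass("AXZ"), class = "sl_validation")
  # the toy minigene's canonical fusion protein mass is consistent with its ORF
  g <- toy_gene()
  parts <- toy_minigene_parts(g)
  mgd <- build_minigene(g, c(1L, 3L), parts$fwd, parts$rev, parts$vector)
  prot <- minigene_tag_positive(mgd)$protein
  expect_gt(protein_mass(prot), 100 * nchar(prot))    # ~110 Da per residue
  expect_lt(protein_mass(prot), 140 * nchar(prot))
})

test_that("primers load from TSV and events from TSV", {
  pt <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("name\tsequence\torientation",
               "F543\tCTGCAGGTTGTTGACAAGCCAAGTC\tforward",
               "R542\tGCTCATAGGTGATGCCTGGTCTGG\treverse"), pt)
  ps <- read_primers_tsv(pt)
  expect_equal(length(ps), 2L)
  expect_equal(ps$R542$orientation, "reverse")
  et <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("kind\ttarget\tcryptic_donor\tcryptic_acceptor",
               "cRi\t1\t\t",
               "pRi\t1\t\t138"), et)
  evs <- read_events_tsv(et)
  expect_equal(evs[[1L]]$kind, "intron_retention_complete")
  expect_equal(evs[[2L]]$cryptic_acceptor, 138L)
})
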