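test_that("a planted G>A-style substitution creates the first upstream AG and breaks the AEZ", {
  g <- toy_gene()
  # intron 1 of the toy gene: last internal AG has its G at sense position 41
  # (offset -60); the AEZ spans (-60, -3].  Plant an AG at -19: position -19
  # is inside the pyrimidine tail; base before it must be made A first, so
  # instead use the tail adenine geometry of the generator genes below.
  # Here: variant at -19 on a tail "T" after "T" creates no AG.
  base <- gene_seq(g, 182L, 182L)                 # offset -19 of intron 1
  v_no <- variant(hgvs_coding_position(79L, -19L), base, "C")
  rep_no <- scan_aez(g, v_no)
  expect_equal(rep_no$aez_start_offset, -60L)
  expect_false(rep_no$variant_creates_ag)
  expect_false(rep_no$breaks_aez)

  gg <- synth_gene(seed = 21)
  pl <- plant_lesion(gg, "aez_break", seed = 3)
  rep <- scan_aez(gg, pl$variant)
  expect_true(rep$variant_creates_ag)
  expect_true(rep$breaks_aez)
  expect_true(rep$created_is_first_upstream)
  expect_equal(rep$created_ag_offset, pl$variant$pos$offset)
  expect_true(rep$created_ag_offset > rep$aez_start_offset || is.na(rep$aez_start_offset))
})

test_that("donor-side variants are outside the AEZ domain", {
  g <- toy_gene()
  b <- gene_seq(g, 103L, 103L)
  v <- variant(hgvs_coding_position(78L, 3L), b, setdiff(c("A","C","G","T"), b)[1L])
  expect_error(scan_aez(g, v), class = "sl_domain")
})

test_that("AEZ scan is invariant under intron padding beyond the first AG", {
  # lengthening the intron upstream of the first AG must not change the report
  g <- synth_gene(seed = 31)
  pl <- plant_lesion(g, "aez_break", seed = 5)
  rep1 <- scan_aez(g, pl$variant)
  i <- rep1$intron_index
  iv <- intron_intervals(g)
  ins_at <- iv$start[i] + 10L                     # deep in the intron 5' half
  padded <- paste0(substr(g$sequence, 1L, ins_at), strrep("CT", 30L),
                   substr(g$sequence, ins_at + 1L, nchar(g$sequence)))
  ex2 <- g$exons
  shift <- ifelse(ex2$start > ins_at, 60L, 0L)
  g2 <- gene_model(g$gene_id, data.frame(start = ex2$start + shift, end = ex2$end + shift),
                   padded, g$cds_start, g$cds_end)
  rep2 <- scan_aez(g2, pl$variant)
  expect_equal(rep2$aez_start_offset, rep1$aez_start_offset)
  expect_equal(rep2$created_ag_offset, rep1$created_ag_offset)
  expect_equal(rep2$breaks_aez, rep1$breaks_aez)
})

test_that("branchpoint-window membership is inclusive on the published bounds", {
  expect_true(branch_window(-26L)$in_window)
  expect_true(branch_window(-19L)$in_window)
  expect_true(branch_window(-37L)$in_window)
  expect_false(branch_window(-18L)$in_window)
  expect_false(branch_window(-38L)$in_window)
  expect_false(branch_window(-50L)$in_window)
  v <- parse_hgvs_c("c.3331-26T>G")
  expect_true(branch_window(v)$in_window)
  expect_error(branch_window(5L), class = "sl_domain")
  expect_error(branch_window(-26L, window = c(-37L, 19L)), class = "sl_validation")
})

test_that("acceptor PWM scoring is self-consistent and orders contexts sensibly", {
  corpus <- lapply(1:8, function(s) synth_gene(seed = s))
  pwm <- train_acceptor_pwm(corpus)
  expect_gte(pwm$n_sites, 20L)
  # canonical acceptors of the corpus score in the top of the normalized range
  g <- corpus[[1L]]
  iv <- intron_intervals(g)
  s_canon <- score_acceptor(pwm, g, iv$end[1L])
  expect_gte(s_canon, 0)
  expect_lte(s_canon, 1)
  # pyrimidine-rich upstream context beats purine-rich context, same AG
  s_pyr <- score_acceptor(pwm, context = paste0(strrep("CT", 6L), "AG", "GT"))
  s_pur <- score_acceptor(pwm, context = paste0(strrep("GA", 6L), "AG", "GT"))
  expect_gt(s_pyr, s_pur)
  # corpus duplication leaves scores unchanged (scale-free training)
  pwm2 <- train_acceptor_pwm(c(corpus, corpus))
  expect_equal(score_acceptor(pwm2, g, iv$end[1L]), s_canon, tolerance = 1e-12)
  expect_error(train_acceptor_pwm(corpus[1L]), class = "sl_training")
  expect_error(score_acceptor(pwm, context = paste0(strrep("CT", 7L), "TT")),
               class = "sl_validation")
})

test_that("canonical acceptors outscore deep-intronic AGs in random context", {
  corpus <- lapply(1:8, function(s) synth_gene(seed = s))
  pwm <- train_acceptor_pwm(corpus)
  canon_scores <- numeric()
  deep_scores <- numeric()
  for (g in corpus[1:4]) {
    iv <- intron_intervals(g)
    for (i in seq_len(nrow(iv))) {
      canon_scores <- c(canon_scores, score_acceptor(pwm, g, iv$end[i]))
      s <- intron_seq(g, i)
      hits <- gregexpr("(?=AG)", substr(s, 20L, nchar(s) - 60L), perl = TRUE)[[1L]]
      deep <- if (hits[1L] == -1L) integer() else as.integer(hits) + 1L + 19L
      deep <- deep[deep > 33L]    # need a full upstream context window
      if (!length(deep)) next
      deep_scores <- c(deep_scores,
                       score_acceptor(pwm, g, iv$start[i] + deep[1L] - 1L))
    }
  }
  expect_true(all(canon_scores >= 0 & canon_scores <= 1))
  expect_gte(length(deep_scores), 3L)
  # deep-intronic AGs in random (purine-containing) context fall at or below
  # the bottom of the corpus range; canonical acceptors span it
  expect_true(all(deep_scores <= 0.05))
  expect_gt(mean(canon_scores), mean(deep_scores) + 0.2)
})

test_that("SR-motif scanning reports motifs created by the variant", {
  # plant AGATG -> AGAGG (T>G at the center creates the SRp40 site)
  ex1 <- paste0("ATG", rand_codons(32L), "C")
  ex2 <- paste0(rand_codons(32L), "TAAC")
  set.seed(99)
  intron <- paste0("GT", strrep("CT", 20L), "AGATG", strrep("CT", 17L), "C",
                   "CTTTCCTTTCCTTTCCTT", "AG")
  genome <- paste0(strrep("C", 20L), ex1, intron, ex2, strrep("C", 20L))
  g <- gene_model("sr", data.frame(start = c(21L, 121L + nchar(intron)),
                                   end = c(120L, 220L + nchar(intron))),
                  genome, 1L, 199L)
  # the T of AGATG sits at intron position 46 -> genomic 120 + 46
  vpos <- 120L + 46L
  expect_equal(gene_seq(g, vpos, vpos), "T")
  off <- vpos - (120L + nchar(intron)) - 1L
  v <- variant(hgvs_coding_position(101L, off), "T", "G")
  hits <- scan_sr_motifs(g, v)
  expect_true("AGAGG" %in% hits$motif)
  expect_true(all(hits$created_by_variant[hits$motif == "AGAGG"]))
  # a variant not altering any motif
  v2 <- variant(hgvs_coding_position(101L, -30L),
                gene_seq(g, 121L + nchar(intron) - 30L, 121L + nchar(intron) - 30L), "A")
  expect_equal(nrow(scan_sr_motifs(g, v2)), 0L)
  # a motif already present in the reference is reported as not created
  rna_table <- data.frame(factor = "SC35", motif = "GGCCUCC", score = 5L)
  ex1b <- paste0("ATG", "GGCCTCC", rand_codons(30L))
  genome_b <- paste0(strrep("C", 20L), ex1b, intron, ex2, strrep("C", 20L))
  gb <- gene_model("sr2", data.frame(start = c(21L, 121L + nchar(intron)),
                                     end = c(120L, 220L + nchar(intron))),
                   genome_b, 1L, 199L)
  b <- substr(ex1b, 12L, 12L)
  vb <- variant(hgvs_coding_position(12L), b, setdiff(c("A","C","G","T"), b)[1L])
  hb <- scan_sr_motifs(gb, vb, motif_table = rna_table)
  expect_true(any(hb$rel_start == -8L))           # U>T-normalized motif found
  expect_false(any(hb$created_by_variant[hb$rel_start == -8L]))
})
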