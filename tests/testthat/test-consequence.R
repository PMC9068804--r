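test_that("in-frame exon skip of a 99-nt exon is an In-frame (del 33 aa)", {
  g <- toy_gene()
  ref <- reconstruct_transcript(g)
  alt <- reconstruct_transcript(g, splice_event("Esk", 2L))
  call <- classify_consequence(ref, alt)
  expect_equal(call$category, "in_frame_del")
  expect_equal(call$aa_deleted, 33L)
  expect_equal(call$label, "In-frame (del 33 aa)")
  expect_false(call$nmd_sensitive)
})

test_that("out-of-frame skips give frameshift calls: PTC when a stop precedes the mapped natural stop", {
  hit_ptc <- 0L
  for (seed in 6:17) {
    g <- synth_gene(simulation_config(n_exons = c(4L, 4L)), seed = seed)
    lens <- exon_lengths(g)
    for (k in 2:3) {
      if (lens[k] %% 3L == 0L) next
      ref <- reconstruct_transcript(g)
      call <- classify_consequence(ref, reconstruct_transcript(g, splice_event("Esk", k)))
      # a frameshift either terminates early (PTC) or reads through the
      # natural stop (frameshift-stop loss), never an in-frame class
      expect_true(call$category %in% c("frameshift_PTC", "stop_loss"))
      expect_match(call$label, "^Frameshift-")
      if (call$category == "frameshift_PTC") {
        hit_ptc <- hit_ptc + 1L
        expect_false(is.na(call$ptc_position))
      }
    }
  }
  expect_gte(hit_ptc, 3L)
})

test_that("complete retention of an in-frame intron with a planted TAA is a stop gain inside the intron", {
  g <- toy_gene()                       # intron 2: 81 nt, TAA at intron pos 10-12
  ref <- reconstruct_transcript(g)
  alt <- reconstruct_transcript(g, splice_event("cRi", 2L))
  call <- classify_consequence(ref, alt)
  expect_equal(call$category, "stop_gain_PTC")
  expect_equal(call$label, "Stop gain-PTC")
  # PTC at the planted TAA: exons 1+2 (189) + 9 intron bases + 1
  expect_equal(call$ptc_position, 199L)
  # retention removed the downstream junction: PTC is effectively last-exonic
  expect_false(call$nmd_sensitive)
  expect_equal(call$junctions_downstream_of_ptc, 0L)
})

test_that("a PTC inside a retained intron with three downstream junctions is NMD-sensitive", {
  g <- synth_gene(simulation_config(n_exons = c(5L, 5L)), seed = 12)
  # plant an in-frame TAA near the start of intron 1
  iv <- intron_intervals(g)
  coding_before <- exon_lengths(g)[1L] - (g$cds_start - 1L)
  j <- iv$start[1L] + (3L - coding_before %% 3L) %% 3L + 3L
  substr(g$sequence, j, j + 2L) <- "TAA"
  ref <- reconstruct_transcript(g)
  alt <- reconstruct_transcript(g, splice_event("cRi", 1L))
  call <- classify_consequence(ref, alt)
  expect_true(call$category %in% c("frameshift_PTC", "stop_gain_PTC"))
  expect_lte(call$ptc_position, exon_lengths(g)[1L] + (j - iv$start[1L]) + 1L)
  expect_equal(call$junctions_downstream_of_ptc, 3L)
  expect_true(call$nmd_sensitive)
})

test_that("classify(x, x) is no change for arbitrary transcripts", {
  for (seed in c(1, 9)) {
    g <- synth_gene(seed = seed)
    tx <- reconstruct_transcript(g)
    call <- classify_consequence(tx, tx)
    expect_equal(call$category, "no_change")
    expect_equal(call$label, "No change")
  }
})

test_that("in-frame skips delete exactly length/3 amino acids (property)", {
  n_checked <- 0L
  for (seed in 1:12) {
    g <- synth_gene(seed = seed)
    lens <- exon_lengths(g)
    ref <- reconstruct_transcript(g)
    for (k in seq(2L, n_exons(g) - 1L)) {
      if (lens[k] %% 3L != 0L) next
      call <- classify_consequence(ref, reconstruct_transcript(g, splice_event("Esk", k)))
      if (call$category %in% c("in_frame_del", "in_frame_delins")) {
        expect_equal(3L * (call$aa_deleted - call$aa_inserted), lens[k])
        n_checked <- n_checked + 1L
      } else {
        # an in-frame skip can still gain a stop at the new junction codon
        expect_equal(call$category, "stop_gain_PTC")
      }
    }
  }
  expect_gte(n_checked, 3L)
})

test_that("NMD follows the 50-nt exon-junction rule", {
  # junctions at 100, 300, 500, 700 on a 900-nt transcript
  seqs <- strrep("ACGT", 225L)
  tx <- mature_transcript(seqs, junctions = c(100L, 300L, 500L, 700L))
  # PTC far upstream of the last junction, 3 junctions downstream
  res <- nmd_call(tx, 260L)
  expect_true(res$nmd_sensitive)
  expect_equal(res$junctions_downstream, 3L)
  # PTC in the last "exon"
  res2 <- nmd_call(tx, 750L)
  expect_false(res2$nmd_sensitive)
  expect_equal(res2$junctions_downstream, 0L)
  # 10 nt upstream of the final junction: junction downstream but too close
  res3 <- nmd_call(tx, 688L)
  expect_false(res3$nmd_sensitive)
  expect_equal(res3$junctions_downstream, 1L)
  # exactly at the rule boundary
  expect_true(nmd_call(tx, 648L)$nmd_sensitive)
  expect_false(nmd_call(tx, 649L)$nmd_sensitive)
  # configurable rule distance
  expect_true(nmd_call(tx, 688L, junction_rule_nt = 10L)$nmd_sensitive)
})

test_that("stop loss is called when no stop is reached", {
  g <- toy_gene()
  ref <- reconstruct_transcript(g)
  # truncate the altered transcript right after the CDS start: no stop codon
  alt <- mature_transcript(substr(ref$sequence, 1L, 15L), cds_start = 13L)
  call <- classify_consequence(ref, alt)
  expect_equal(call$category, "stop_loss")
})

test_that("ACMG combining rules reproduce the published classification table", {
  expect_equal(combine_acmg(c("PS3", "PM2", "PP1")), "likely pathogenic")
  expect_equal(combine_acmg(character()), "uncertain significance")
  # frozen from the published combining table
  oracle <- list(
    list(c("PVS1", "PS3"), "pathogenic"),
    list(c("PVS1", "PM2", "PM4"), "pathogenic"),
    list(c("PVS1", "PM2", "PP3"), "pathogenic"),
    list(c("PS1", "PS3"), "pathogenic"),
    list(c("PS3", "PM1", "PM2", "PM4"), "pathogenic"),
    list(c("PVS1", "PM2"), "likely pathogenic"),
    list(c("PS3", "PP1", "PP3"), "likely pathogenic"),
    list(c("PM1", "PM2", "PM4"), "likely pathogenic"),
    list(c("PM1", "PM2", "PP1", "PP2"), "likely pathogenic"),
    list(c("PM2", "PP1", "PP2", "PP3", "PP4"), "likely pathogenic"),
    list(c("BA1"), "benign"),
    list(c("BS1", "BS2"), "benign"),
    list(c("BS1", "BP4"), "likely benign"),
    list(c("BP4", "BP7"), "likely benign"),
    list(c("PM2"), "uncertain significance"),
    list(c("PS3", "BS1", "BS2"), "benign"),          # pathogenic combo not met
    list(c("PVS1", "PS3", "BA1"), "uncertain significance"))  # contradictory
  for (case in oracle)
    expect_equal(combine_acmg(case[[1L]]), case[[2L]], info = paste(case[[1L]], collapse = "+"))
  expect_error(combine_acmg("PX9"), class = "sl_validation")
})

test_that("published-table label typography normalizes to the package vocabulary", {
  expect_equal(normalize_trf_label("Frameshift—PTC"), "Frameshift-PTC")
  expect_equal(normalize_trf_label("Frameshift—stop loss"), "Frameshift-stop loss")
  expect_equal(normalize_trf_label("In-frame (del 33 aa)"), "In-frame (del 33 aa)")
})
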