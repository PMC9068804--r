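# Cohort recurrence/specificity analysis over a table of splice-altering
# variants.  The packaged fixture transcribes the published 46-variant table
# of intronic cryptic splice-altering MYBPC3 variants and the carrier counts
# observed in a 9,611-proband hypertrophic cardiomyopathy (HCM) cohort (3,437
# probands with complete intronic coverage for deep-intronic variants).

#' Path of the bundled 46-variant MYBPC3 cohort table
#' @export
mybpc3_table_path <- function() {
  system.file("extdata", "mybpc3_splice_variants.tsv", package = "spliceLesion",
              mustWork = TRUE)
}

#' Load and validate a cohort table of splice-altering variants
#'
#' Reads a TSV with one row per variant: `vid`, `coding_name` (HGVS c.),
#' `intron`, `n_hcm`, `n_other`, `spliceai_delta`, `defect_class`,
#' `trf_label` (plus optional genomic-name annotation columns).  The signed
#' splice-site offset is parsed from `coding_name`, and each variant is
#' classed `proximal` (|offset| <= `proximal_max_nt`) or `deep` — proximal
#' variants fall in the intronic flanks covered by exon-targeted sequencing
#' panels, deep variants require complete intronic coverage, hence the two
#' carrier denominators.
#'
#' @param path TSV path; default the packaged table.
#' @param expected_rows Required row count (default 46, the packaged table);
#'   `NA` to skip the check.
#' @param proximal_max_nt Proximal/deep boundary on |offset| (default 60 nt).
#' @return A `CohortTable` data frame with derived `offset` and
#'   `location_class` columns.
#' @export
read_cohort_table <- function(path = mybpc3_table_path(), expected_rows = 46L,
                              proximal_max_nt = 60L) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("vid", "coding_name", "intron", "n_hcm", "n_other",
           "spliceai_delta", "defect_class", "trf_label")
  miss <- setdiff(req, names(d))
  if (length(miss))
    stop_sl("sl_parse", sprintf("cohort table lacks column(s): %s",
                                paste(miss, collapse = ", ")))
  if (!is.na(expected_rows) && nrow(d) != expected_rows)
    stop_sl("sl_parse", sprintf("expected %d rows, found %d", expected_rows, nrow(d)))
  d$offset <- vapply(d$coding_name, function(s) parse_hgvs_c(s)$pos$offset, 1L,
                     USE.NAMES = FALSE)
  for (i in seq_len(nrow(d))) {
    if (is.na(d$n_hcm[i]) || d$n_hcm[i] < 0 || is.na(d$n_other[i]) || d$n_other[i] < 0)
      stop_sl("sl_validation", sprintf("row %s: carrier counts must be non-negative",
                                       d$vid[i]))
    if (is.na(d$spliceai_delta[i]) || d$spliceai_delta[i] < 0 || d$spliceai_delta[i] > 1)
      stop_sl("sl_validation", sprintf("row %s: SpliceAI delta score must be in [0, 1]",
                                       d$vid[i]))
    if (d$offset[i] == 0L)
      stop_sl("sl_validation", sprintf("row %s: variant is not intronic", d$vid[i]))
  }
  d$location_class <- ifelse(abs(d$offset) <= proximal_max_nt, "proximal", "deep")
  class(d) <- c("CohortTable", "data.frame")
  d
}

#' Carrier percentage under the two-denominator rule
#'
#' Proximal variants are related to the cohort with intronic flanks covered;
#' deep-intronic variants to the (smaller) cohort with complete intronic
#' coverage.  Percentages are rounded half-up to 3 decimals, matching the
#' published table's formatting.
#'
#' @param rows A `CohortTable` (or subset of rows).
#' @param denominators Named or positional pair `(proximal, deep)` of cohort
#'   sizes; defaults to `c(9611, 3437)`.
#' @return Numeric vector of percentages.
#' @export
carrier_percentage <- function(rows, denominators = c(proximal = 9611L, deep = 3437L)) {
  if (any(denominators <= 0)) stop_sl("sl_validation", "denominators must be positive")
  den <- ifelse(rows$location_class == "proximal", denominators[[1L]], denominators[[2L]])
  round_half_up(100 * rows$n_hcm / den, 3L)
}

#' Summarize recurrence, specificity and in-silico prioritization of a cohort
#'
#' Counts detected variants (>= 1 HCM carrier), recurrent variants (>=
#' `recurrent_min` carriers), non-recurrent ones (1 to `recurrent_min - 1`)
#' and undetected ones; totals carriers; computes the phenotype specificity
#' `100 * hcm / (hcm + other)`; the fraction of HCM carriers explained by
#' recurrent variants; and, per SpliceAI delta-score cutoff, how many
#' variants the in-silico screen would have prioritized.
#'
#' @param rows A `CohortTable`.
#' @param recurrent_min Minimum carrier count for the recurrent class
#'   (default 5).
#' @param cutoffs SpliceAI delta-score cutoffs (default `c(0.2, 0.5)`).
#' @return A `CohortSummary` list.
#' @export
summarize_cohort <- function(rows, recurrent_min = 5L, cutoffs = c(0.2, 0.5)) {
  n <- nrow(rows)
  det <- rows$n_hcm >= 1L
  rec <- rows$n_hcm >= recurrent_min
  hcm <- sum(rows$n_hcm)
  oth <- sum(rows$n_other)
  sens <- data.frame(
    cutoff = cutoffs,
    count = vapply(cutoffs, function(ct) sum(rows$spliceai_delta >= ct), 1L))
  sens$pct <- round_half_up(100 * sens$count / n, 1L)
  structure(list(
    n_variants = n,
    n_detected = sum(det),
    n_recurrent = sum(rec),
    n_nonrecurrent = sum(det & !rec),
    n_undetected = sum(!det),
    total_hcm_carriers = hcm,
    total_other_carriers = oth,
    specificity_pct = if (hcm + oth > 0) 100 * hcm / (hcm + oth) else NA_real_,
    recurrent_carrier_fraction_pct = if (hcm > 0) 100 * sum(rows$n_hcm[rec]) / hcm
                                     else NA_real_,
    recurrent_min = recurrent_min,
    spliceai_sensitivity = sens), class = "CohortSummary")
}

#' @export
print.CohortSummary <- function(x, ...) {
  cat(sprintf("CohortSummary: %d variants; %d detected (%d recurrent >= %d carriers, %d in 1-%d), %d undetected\n",
              x$n_variants, x$n_detected, x$n_recurrent, x$recurrent_min,
              x$n_nonrecurrent, x$recurrent_min - 1L, x$n_undetected))
  cat(sprintf("  HCM carriers %d, other phenotypes %d; specificity %.1f%%\n",
              x$total_hcm_carriers, x$total_other_carriers, x$specificity_pct))
  if (!is.na(x$recurrent_carrier_fraction_pct))
    cat(sprintf("  %.0f%% of HCM carriers explained by recurrent variants\n",
                x$recurrent_carrier_fraction_pct))
  for (i in seq_len(nrow(x$spliceai_sensitivity)))
    cat(sprintf("  SpliceAI delta >= %.1f: %d/%d (%.0f%%)\n",
                x$spliceai_sensitivity$cutoff[i], x$spliceai_sensitivity$count[i],
                x$n_variants, x$spliceai_sensitivity$pct[i]))
  invisible(x)
}
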