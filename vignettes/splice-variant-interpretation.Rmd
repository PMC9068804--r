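---
title: "Interpreting cryptic splice-altering intronic variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interpreting cryptic splice-altering intronic variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spliceLesion)
```

## The model

spliceLesion treats splice-variant interpretation as deterministic sequence
arithmetic on a gene model. A `GeneModel` is one transcript: ordered exons on
a plus-strand genomic sequence, a strand, and the transcript coordinates of
the translation start and stop. Internally all interval arithmetic is done on
1-based inclusive coordinates indexed directly into the modeled sequence;
the HGVS and GFF3 surfaces use the same convention, so no off-by-one
translation layer exists between what the user names and what the code
slices.

The interpretive chain is:

1. **Coordinate resolution.** An HGVS coding-DNA substitution
   (`c.<anchor>±<offset><ref>><alt>`) resolves to a genomic position
   strand-awarely; the reference allele is checked against the model
   sequence. Only single-nucleotide substitutions are supported — the
   variant class this analysis is about — and indels are rejected
   explicitly. Both the ASCII hyphen and the typographic minus are accepted
   on input; output is normalized to ASCII.
2. **Cis-element scanning** (acceptor side). The AG-exclusion zone (AEZ) of
   an intron is the region between the splice acceptor and the first
   upstream AG dinucleotide; because acceptor selection scans for the first
   AG downstream of the branchpoint, this zone is under selection against
   AGs, and a variant-created AG strictly inside it tends to become an
   active cryptic acceptor. `scan_aez()` reports the reference zone
   boundary, whether the variant creates an AG, and whether the created AG
   breaks the zone. `branch_window()` reports membership in the
   branchpoint window, offsets −37…−19 from the acceptor, where the large
   majority of human branchpoints map. `scan_sr_motifs()` reports
   exon-definition motifs (by default AGAGG/SRSF5 and GGCCTCC/SRSF2, scores
   +5) present in the alternate but not the reference context.
3. **Event hypothesis.** `hypothesize_event()` encodes the proximal-intronic
   triage rules: AEZ break → partial intron retention ending at the created
   AG; otherwise branch-window membership → complete intron retention;
   otherwise canonical. Deep-intronic pseudo-exon activation is deliberately
   *not* discovered de novo — those structures come from experimental
   evidence and are supplied as explicit `splice_event()`s.
4. **Reconstruction.** `reconstruct_transcript()` substitutes the variant
   into the pre-mRNA, then assembles the mature transcript under the event
   set. Junction bookkeeping falls out of genomic contiguity: a boundary
   between two retained pieces is an exon–exon junction exactly when the
   pieces are not genomically adjacent. Complete retention of intron *k*
   therefore removes the junction it spans; a cryptic-acceptor partial
   retention keeps one junction (donor → created AG) and flows seamlessly
   into the downstream exon.
5. **Consequence.** `classify_consequence()` translates both ORFs. A stop
   upstream of where the reference stop maps onto the altered transcript is
   a PTC — frameshift if the net length change is not a multiple of 3,
   stop-gain otherwise; in-frame changes are sized in amino acids by longest
   common prefix/suffix of the proteins; reading through the natural stop is
   a stop-loss. PTCs arising only after out-of-frame read-through into
   downstream exons are handled by the same full-ORF translation, with no
   special casing.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `junction_rule_nt` | 50 | NMD rule: a PTC is decay-sensitive when its stop codon ends ≥ 50 nt upstream of the last exon–exon junction. 50–55 nt is the field-standard range; the downstream junction count is reported alongside so a different rule can be applied post hoc. |
| `window` (branch) | −37…−19 | Branchpoint window, inclusive on both bounds. |
| AEZ zone | (first upstream AG, −3] | The acceptor's own AG (offsets −2/−1) is excluded from the upstream-AG search on both sides of the definition. |
| `proximal_max_nt` | 60 | Proximal/deep boundary on \|offset\|. Deep variants are only ascertainable in probands with complete intronic coverage, hence the two carrier denominators (9,611 / 3,437). 60 is the unique threshold consistent with every percentage in the bundled table (−52 proximal, −80 deep). |
| `recurrent_min` | 5 | Recurrent-variant threshold on HCM carrier count. Observed classes span 1–4 and 6–15 with no count of exactly 5, so any threshold in (4, 6] gives the same partition; 5 is the documented, configurable choice. |
| PWM window | −14…+2 | Acceptor context: 14 intronic positions ending at the acceptor G plus 2 exonic ones. |
| PWM `pseudocount` | 0.01 | Added to per-column *frequencies*, not counts, so training is scale-free: duplicating the corpus changes nothing. |

Percentages in the cohort module round half away from zero to 3 decimals,
matching how such tables are printed; base `round()`'s half-to-even rule
would differ on exact .0005 boundaries.

## The bundled cohort table

`inst/extdata/mybpc3_splice_variants.tsv` transcribes a published
compilation of 46 experimentally confirmed cryptic splice-altering *MYBPC3*
intronic variants: coding name, intron, HCM carrier count, other-phenotype
carrier count (7 carriers across six variants), SpliceAI Δ score, splicing
defect class and deduced reading-frame effect; GRCh37/GRCh38 genomic names
are carried as annotation only. `summarize_cohort()` recomputes the
aggregate statistics from the row data at run time — nothing downstream is
hard-coded. One known discrepancy is reported rather than resolved: tallying
the transcribed Δ-score column at the 0.5 cutoff yields 24/46, while the
accompanying narrative total is 25/46; the package reports the tally its
data produce.

## What the synthetic generator emulates — and what it does not

`synth_gene()` builds plus-strand multi-exon genes whose exons concatenate
to an ORF (ATG in exon 1, unique in-frame stop in the last exon, short
UTRs) with GT…AG introns. Each intron's 3' tail is structured: a branch
segment (offsets −40…−21, alphabet C/T/A with a CTAAC branchpoint-like
motif around −30), a polypyrimidine tract (−20…−3, C/T with one planted
adenine), and the acceptor AG. No G occurs in offsets −40…−3, so the tail
contains no AG: a planted AG-creating substitution is guaranteed to create
the *first* AG upstream of the acceptor, making the ground truth of
`plant_lesion()` unambiguous (no planted-site collisions). A single integer
seed governs all randomness; the same seed yields byte-identical GFF3/FASTA.

Real introns are messier in every way that matters for discovery and none
that matters for bookkeeping: branchpoints are probabilistic, polypyrimidine
tracts vary in strength, AEZs contain occasional silent AGs, and splice-site
use is quantitative. Passing the planted-lesion recovery suite therefore
shows that the pipeline's *arithmetic and triage rules* are correct on
structures satisfying its assumptions; it does not show that the triage
rules have high sensitivity or specificity on real genomic sequence, where
trained models (SpliceAI, branchpoint predictors) remain the discovery
tools. This package consumes such scores as inputs; it never re-implements
them.

`simulate_cohort()` draws carrier counts from a zero-inflated geometric law
(zero-inflation 0.45, geometric success 0.26) to mimic the heavy skew of
recurrence tables — many undetected or singleton variants, few 10–15-carrier
ones — and other-phenotype counts binomially against a specificity
parameter. These are modeling choices for test realism, configurable in
`simulation_config()`, not claims about any cohort.

## Numerical and degenerate-input choices

- Intronic positions are named by the nearer splice site (HGVS convention);
  the exact midpoint ties to the donor side.
- `insilico_pcr()` is exact-match only — the analysis needs product
  identities and sizes, not annealing thermodynamics — and returns an empty
  result (not an error) when a primer fails to bind. Junction-spanning
  primers therefore distinguish spliced from unspliced templates for free.
- Minigene absolute product sizes that depend on unprinted vector-backbone
  distances are not modeled; the assay-level invariant is the *difference*
  between aberrant and canonical products, which equals the retained length
  regardless of template ends.
- `score_acceptor()` min-max normalizes against the training acceptors and
  clamps to [0, 1]; the weakest training acceptor scores exactly 0 by
  construction, so only ordinal claims should be read from the scale.
- A cohort with no carriers at all reports specificity as `NA` rather than
  dividing by zero.
- ACMG combining: "uncertain significance" is returned when both a
  pathogenic-side and a benign-side *combination* are satisfied; isolated
  contrary evidence that completes no combination does not override an
  otherwise-met classification.

## Test problem sizes

The property suites run on deliberately modest sizes chosen to exercise
every code path many times over: length conservation across ~30 synthetic
genes, 500 AEZ scans checked against a brute-force substring oracle, and
210 planted-lesion recoveries (the acceptance script re-runs 200 with
caller-supplied seeds). The reconstruction oracle is an independent
string-slicing implementation kept in the test helpers, never shared with
package code.

## Known limitations

- One transcript per gene model; no multi-isoform reasoning or liftover.
- Substitutions only; splice-relevant indels are out of scope.
- NMD is a binary rule-based call; no quantitative decay efficiency.
- Donor-side cis-element analysis is limited to event bookkeeping; the AEZ
  machinery is acceptor-side by definition.
- Exact-match primer binding ignores mismatch tolerance and melting
  temperature.
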