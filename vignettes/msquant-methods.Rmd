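---
title: "Quantitative MSI scoring: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative MSI scoring: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msquant)
```

## The measurement model

Microsatellite instability is read out here as the *density of
length-altering events in repeat tracts*, not as a repeat-length
distribution shift (the mSINGS/MANTIS family) and not as a genotype call.
The unit of observation is one aligned read fully spanning one panel
locus; the unit of inference is the sample.

For a locus with $n$ assigned reads, of which $m$ carry at least one
mutation event inside the repeat tract and which carry $e$ events in
total:

$$\mathrm{pct\_mutated\_reads} = 100\,m/n, \qquad
  \mathrm{pct\_total\_mutations} = 100\,e/n .$$

The first is a bounded per-read prevalence; the second is an event *rate*
and may exceed 100% when reads carry several events each — at heavily
unstable loci values of several hundred percent are expected and
meaningful. Locus counts are pooled per gene (summed) before forming the
gene percentages, and the sample score is the unweighted mean over genes
with coverage. Pooling weights loci by their depth within a gene, which is
appropriate for amplicon data where depth differences reflect assay
efficiency rather than biology between samples; a `locus_mean` mode is
available for panels where equal locus weighting is preferred. Genes with
zero covered loci are excluded from the mean rather than imputed; a sample
with *no* covered gene fails explicitly (the analogue of a specimen with
insufficient tumor content).

### Assumptions

* **Tumor-only amplicon data.** No matched normal is used; scores include
  any germline or FFPE-artifact events in the tracts. The method relies on
  the cutoff calibration to absorb a constant technical baseline.
* **Full-span reads.** Amplicons are designed to cover whole tracts, so a
  read is assigned to a locus only if it covers the tract plus one
  flanking base on each side. Mere overlap would systematically undercount
  events near read ends and make scores depth-profile-dependent.
* **Alignments carry MD tags.** The reference is never read from a FASTA;
  it is reconstructed from the reads themselves (below). Aligners that
  omit MD tags must be post-processed (e.g. `samtools calmd`) first.

## Read validity filters

Reads enter the analysis iff MAPQ ≥ `min_mapq` (default **60**) and none
of the FLAG bits 0x4 (unmapped), 0x100 (secondary) or 0x800
(supplementary) is set. 60 is the "maximum confidence" value emitted by
common short-read aligners, but the cap is aligner-specific, so the
threshold is a parameter rather than a constant. Duplicate (0x400) and
QC-fail (0x200) reads are *not* removed by default — amplicon libraries
are intentionally duplicate-rich, and removing duplicates would discard
most of the signal — but both are available as policy switches
(`read_filter_policy(drop_duplicates = TRUE, drop_qc_fail = TRUE)`).
Records with CIGAR `*` or missing SEQ cannot be analyzed and fail the
filter with a count.

## Reference reconstruction from CIGAR + MD

SAM records only encode *differences* from the reference. Over a read's
aligned span the reference is recoverable exactly: aligned bases are
copied from the read, mismatch positions are overwritten with the
reference letter stored in the MD tag, deleted reference bases are
restored from MD `^` tokens, and inserted or soft-clipped read bases are
dropped. A read whose MD tag holds a single match-run and whose CIGAR has
no I/D/X operations *is* the reference over its span.

Per locus, the first such mutation-free read supplies the reference
window directly (`provenance = "direct"`). If none exists, every covering
read is reconstructed and a per-position majority vote is taken
(`reconstructed_consensus`), with ties broken toward the base supported
by the highest-MAPQ read and then lexicographically — a deterministic
rule that is rarely exercised at amplicon depths, where a handful of
discordant reconstructions cannot outvote the rest. The number of
non-unanimous positions is reported (`n_ambiguous`) so downstream users
can flag suspect loci. Both conditions (no mismatches *and* no indels)
are enforced jointly for "reference read" status: an indel-bearing read
cannot be identical to the reference even if its MD tag shows no
mismatch, because MD does not encode insertions.

## Event extraction and anchoring rules

A single joint CIGAR/MD walk tracks the reference coordinate and emits
one event per contiguous insertion run, one per contiguous deletion run,
and one per substituted base. Granularity is a deliberate choice: two
separate 1-bp insertions are two events (they are independent slippage
outcomes), while one 3-bp deletion is one event. A `granularity = "base"`
switch counts indel bases individually for users who want an
edit-distance-like measure.

Window anchoring, for a tract $[w_s, w_e]$:

* substitution: in iff its position $\in [w_s, w_e]$;
* deletion: in iff *any* deleted base $\in [w_s, w_e]$ (an event that
  straddles the tract edge still shortens the tract);
* insertion (anchored to the reference base it follows): in iff the
  anchor $\in [w_s - 1, w_e]$. The $w_s - 1$ case is a repeat unit
  inserted *before the first repeat base* — indistinguishable in product
  length from any other in-tract insertion, so it must count. This is
  also why locus assignment demands one base of flank: the anchor base
  $w_s - 1$ must be part of the alignment to be observable.

Three fixed scenarios (`test_case_fixtures()`) probe exactly the failure
modes this bookkeeping can have: an upstream indel that shifts query
offsets but must produce zero tract events; three independent in-tract
indels that must be counted separately; and the $w_s - 1$ boundary
insertion that must be counted once. Each is verified in the test suite
against an independent per-base coordinate walk, not against the
production code path.

## Cutoff calibration and classification

ROC candidate thresholds are the distinct observed scores under the rule
*positive iff score ≥ t*; AUC is the trapezoid over (FPR, TPR), which
equals the fraction of correctly ordered positive–negative pairs (ties
½) — the test suite asserts this equivalence on random instances. The
operating cutoff maximizes Youden's $J$; at ties, higher specificity wins
(a false MSI call triggers needless therapy decisions; a false MSS call
is typically caught by the orthogonal assays), then the lower cutoff.
Observed-score candidates rather than midpoints are the default because
they make the chosen cutoff an actually attainable score; a `midpoint`
dialect is provided. Score = cutoff classifies as MSI so that the
calibrated cutoff — itself an observed score — keeps its own sample
positive.

Both metrics are calibrated and reported independently. No merged verdict
is computed: when the two calls disagree the result carries an explicit
`metrics_agree = FALSE` flag instead of silently preferring one metric.
Calibration labels (which reference standard defines "MSI") are a
required user input, not a package assumption.

The classical PCR rule is implemented for the reference arm: MSI-high iff
the unstable-marker fraction ≥ 0.30 (≥ 2 of 5 markers); MSI-low is
grouped with MSS.

## The synthetic-data generator

`make_read()` builds a read from an explicit reference window and a
non-overlapping event plan, emitting SEQ, CIGAR, MD and NM from first
principles (no external tool); by construction the package's walker
inverts it exactly, and NM equals the substituted + inserted + deleted
base count. `simulate_sample()` models a locus as: deterministic amplicon
reference (repeat tract filled with its unit, non-repeat flanks), a
per-read Bernoulli slippage event — one repeat-unit insertion or deletion,
equiprobable, uniformly placed in the tract — plus independent per-base
substitution noise and occasional 1–3 bp soft clips.

Generator defaults state the emulated world: **16 MSI-like / 15 MSS-like
samples** (a 32-sample cohort with one excluded), **200 reads per locus**,
per-read indel probability **0.6 (MSI) vs 0.02 (MSS)**, substitution
error **0.002/base**, soft-clip probability 0.1. The class rates were
chosen once so that MSI samples score near 60% and MSS near 5% — clearly
separated, as dMMR and pMMR tumors are in practice — and are not tuned
thereafter. Tests reduce *depth* (not rates, not composition) to stay
fast; separation at these rates does not depend on depth.

What the generator does **not** emulate: FFPE deamination artifacts, PCR
duplicate structure, stutter-noise repeat-length distributions, alignment
ambiguity in long homopolymers, tumor purity gradients, or real per-locus
mutability differences. A green simulated-cohort test therefore
establishes the *bookkeeping* (coordinates, counting, calibration
arithmetic) — it does not validate clinical performance, which requires
real cohorts.

One representability constraint is enforced: an event plan may not place
two deletions with no matched base between them, because the merged CIGAR
`D` run and the two MD `^` tokens would contradict each other. Such a
plan is equivalent to (and should be written as) one longer deletion.

## Numerical and degenerate-input choices

* Percentages are exact ratios; nothing is rounded internally (reports
  round to 2 decimals only at presentation).
* Zero-coverage loci yield `NA` percentages and are flagged, never
  silently zero — a 0 would bias sample means downward.
* Empty panel, single-class calibration labels, empty marker lists and
  zero-denominator concordance cells all raise or flag explicitly.
* CIGAR/MD contradictions (MD exhausted early, leftover tokens, deletion
  length mismatch) abort with both strings named; a malformed input read
  is never partially counted.
* `N` (skipped-region) operations are filled with `N` and flagged;
  amplicon data should not contain them.

## Known limitations

Tumor-only scoring cannot separate somatic from germline indels; scores
are panel-relative, so cutoffs calibrated on one panel do not transfer to
another; the per-gene pooling assumes loci of a gene measure the same
underlying instability; and the bundled 10-locus panel is synthetic
(invented coordinates) — it demonstrates the machinery and is not a
clinical panel.
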