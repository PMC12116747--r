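---
title: "Methods: quantifying and testing differential poly(A)-site usage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying and testing differential poly(A)-site usage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apashift)
```

## The problem

Most mammalian genes carry several polyadenylation sites (PAS) in their 3'
UTR. The choice between a proximal site (pPAS, short UTR) and a distal site
(dPAS, long UTR) — alternative polyadenylation, APA — changes transcript
stability and protein output, and is actively remodelled by signalling
(for example, CFIm-complex activity directing distal-site usage). 3'-end
sequencing protocols (PAS-seq and relatives) read out exactly this choice:
every read ends at a cleavage site, so per-position 3'-end counts are a
direct census of PAS usage.

`apashift` implements the full quantification-and-testing chain for such
data: site extraction, normalisation, clustering, a two-sample shift test,
the distal usage index (PDUI), motif annotation and a ground-truth
simulator.

## From reads to poly(A)-site clusters

1. **Site extraction** (`extract_three_prime_ends()`): one tag per primary
   alignment at the 3'-terminal *aligned* base on the transcriptional
   strand. For dUTP-style (`reverse`) libraries the transcriptional strand
   is the opposite of the alignment strand. Soft-clipped bases never count;
   alignments under MAPQ 10 are dropped by default so multi-mappers cannot
   create spurious sites. Coordinates are 0-based half-open internally,
   1-based in TSVs, 0-based in BED — one convention per format, converted
   at the boundary.
2. **Normalisation** (`compute_tpm()`): tags per million, per sample, with
   the denominator taken *before* any exclusion, so TPM sums to exactly
   10^6 per sample pre-filtering. Sites with TPM < 1 are then excluded
   per sample (`filter_low_tpm()`; the strict inequality keeps a site at
   exactly 1.0).
3. **PAC clustering** (`cluster_sites()`): single-linkage sweep; sites
   belong to one PAS cluster (PAC) when every adjacent gap is ≤ 24 nt.
   "Within 24 nt" is read as a chainable adjacent-gap rule, the standard
   tag-clustering interpretation; a seed-radius alternative was considered
   and not used because it makes cluster membership depend on seed order.
   Single-site PACs with TPM < 3 are removed (`filter_singleton_pacs()`).
4. **Consensus PACs** (`build_consensus()`): per-sample PACs with TPM
   strictly above 5 are pooled across samples and chained on
   summit-to-summit distance ≤ 500 nt. Pooling means a PAC seen in *any*
   sample can seed a consensus — a site silenced in one condition is
   precisely the interesting case (`require_all_samples = TRUE` restores
   the stricter reading). Summit distance, rather than edge distance, makes
   chaining robust to PAC width. The TPM > 5 gate is applied before
   chaining; applying it after would let sub-threshold fragments bridge
   distant clusters.

All thresholds default to the published analysis settings and are plain
function arguments; `apa_config()` collects them and `run_pipeline()`
echoes every value into `provenance.json`.

## The shift test

For each consensus PAC and a pair of samples (A = control, B = treatment),
`pac_signal_profiles()` builds the per-position signal vectors ordered
5'→3' on the transcript strand and normalised to unit mass. Three
statistics follow.

**Shifting score.** `shifting_score()` measures spatial separation of the
two profiles as

$$S = 1 - 2\sum_i \min(p_{A,i},\; p_{B,i}) \in [-1, 1].$$

$S = -1$ for identical profiles, $+1$ for disjoint support, and $S > 0$
exactly when less than half of the signal mass overlaps. For a clean
two-site gene whose distal usage moves by $\Delta$, the noiseless score is
$S = 2\Delta - 1$: the score crosses zero only at a majority (> 50%) usage
flip. It is therefore an *effect-size gate*, deliberately blind to partial
shifts, and it is symmetric in its arguments — direction is assigned
separately. The score is a plug-in (`score_fun` in `apa_shift_test()`), so
an alternative separation measure can be swapped in without touching the
rest of the machinery.

**Kolmogorov-Smirnov test.** `ks_test_pac()` compares the count-weighted
empirical cumulative distributions: $D = \max_i |F_A(i) - F_B(i)|$, with
the p-value from the asymptotic Kolmogorov tail at
$\sqrt{n_\mathrm{eff}}\,D$, $n_\mathrm{eff} = n_A n_B/(n_A+n_B)$. At
single-base resolution ties are ubiquitous; tied data make the asymptotic
tail conservative, and for small problems ($n_\mathrm{eff} < 50$) the
exact conditional permutation distribution is used instead. Counts, not
TPM, define the sample sizes.

**Calls.** Benjamini-Hochberg adjustment runs over all tested PACs of one
comparison (`call_significant()`), producing three layers:

* `detected` — q ≤ 0.01 and consensus TPM strictly above 5 in both
  samples: the statistical detection arm;
* `significant` — additionally S > 0: the published call rule, which adds
  the majority-separation effect-size gate on top of detection;
* `direction` — lengthened/shortened for detected PACs.

The two flags answer different questions. With one library per condition
and overdispersed counts, the KS test detects any composition difference
between the libraries — including overdispersion noise on null genes — so
`detected` alone over-calls biological shifts; the score gate is what makes
the published rule conservative (on null simulations it fires on
essentially nothing). Conversely, the score gate alone would never pass a
partial usage shift (Δ < 0.5), which is the biologically typical case.
Power and direction-recovery properties of the method are therefore stated
at the detection layer, while `significant` reproduces the printed rule
verbatim.

**Direction.** `classify_direction()` anchors a boundary at the
signal-weighted median of the *pooled* (both-sample average) profile and
compares the two samples' mass strictly 3' of it. Anchoring on the pooled
profile rather than on the control alone keeps the boundary identical for
both samples, which makes the call flip exactly under a label swap and
avoids a degenerate case (a distal-heavy control puts its own median at
the last position, where both distal fractions are zero). Exact ties give
`none`.

## PDUI and cohort stratification

For genes with at least two consensus PACs, `assign_proximal_distal()`
keeps the two strongest (combined TPM) and orders them by distance from
the stop codon in transcript orientation. The distal usage index is

$$\mathrm{PDUI} = \frac{\text{distal}}{\text{proximal} + \text{distal}} \in [0, 1],$$

undefined (`NA`, never 0) when both abundances vanish, and invariant under
common scaling.

`stratify_and_compare()` splits a cohort at the median expression of a
marker gene (ties to the low group, deterministically), averages PDUI
within groups and applies a two-sided Mann-Whitney U test. The default
comparison unit is the per-sample mean PDUI: samples are independent
observations, so the null calibration is exact. Comparing per-gene group
means instead (available as `units = "gene"`) mirrors gene-by-gene
averaging, but the two group means of a gene share that gene's baseline,
so the rank test runs on strongly correlated pairs and its type-I rate
collapses far below nominal — fine for description, misleading for
inference. A precomputed external PDUI matrix (genes × samples TSV) feeds
the same function directly; computing PDUI from counts is the native path.

## Motif annotation

Motifs are stated in the RNA alphabet and DNA input is transcribed
internally. `scan_pas_hexamers()` scans a window upstream of a cleavage
position — default 50 nt, since the canonical signal sits 10–30 nt
upstream — for the canonical AAUAAA, AUUAAA and the ten common single-base
variants; `scan_ugua()` does the same for the CFIm (NUDT21–CPSF6) binding
element. Offsets are those of the motif's first base relative to the
cleavage position in transcript orientation (negative = upstream); on the
minus strand the reverse complement is scanned, so hits mirror exactly.
`annotate_context()` labels PACs by precedence
3UTR > CDS-exon > intron > downstream-1kb > intergenic, and
`mutate_proximal_pas()` performs the AUUAAA→CCCCCC knockout edit used in
reporter constructs, refusing intervals that hold no recognised hexamer.

## The synthetic-data generator

`simulate_apa_dataset()` emulates the statistical structure the shift test
assumes: two-PAS genes with a condition-dependent distal usage.

* Architecture: single-exon genes on one synthetic chromosome, alternating
  strands, 300-nt CDS, pPAS 150 nt past the stop codon, dPAS
  `pas_spacing` = 300 nt further (both sites inside one 500-nt consensus
  PAC), AAUAAA planted 21 nt upstream of each cleavage site, UGUA 40 nt
  upstream of the dPAS only for half the genes.
* Usage: control distal fraction π₀ ~ Uniform(0.2, 0.8); treatment
  π₁ = π₀ ± Δ (lengthened/shortened genes, default Δ = 0.3, 70% of shifts
  lengthening) or π₀ (null), clipped to [0, 1] with a message.
* Counts: per-PAS negative binomial with mean `depth × usage`
  (depth 500/gene) and size 20 (dispersion 0.05 — between technical- and
  biological-replicate overdispersion, appropriate for a single-library
  condition comparison); Poisson is the size → ∞ limit. Read ends are
  scattered with integer-rounded Gaussian jitter (sd 8 nt), so every PAS
  yields a multi-site cluster that genuinely exercises the 24-nt rule.
* All randomness flows through one seed (`withr::with_seed`); identical
  seeds give bit-identical outputs, including files.

What it does **not** emulate: internal priming artefacts, > 2 PAS per
gene, intronic PAS, expression differences between conditions, mappability
gaps, or replicate structure. Passing tests on this generator demonstrate
that the statistical chain recovers planted usage shifts under realistic
count noise — not that any particular biological dataset is free of those
complications.

`simulate_cohort_pdui()` emulates a tumour-cohort PDUI matrix: log-normal
marker expression, per-gene baselines Uniform(0.2, 0.8), and a
logit-scale shift of `marker_effect` in samples above the median marker
expression, with per-observation logit noise (sd 0.5).

## Numerical and degenerate-input choices

* Strict inequalities exactly as printed: TPM < 1 excluded, singleton
  TPM < 3 removed, consensus entry TPM > 5, pair TPM > 5, q ≤ 0.01.
* PAC summit ties break to the leftmost position; gene-assignment ties on
  stop-codon distance are labelled `ambiguous`; PACs overlapping no
  extended UTR are `intergenic`.
* Profiles must sum to 1 within 1e-6 or `shifting_score()` refuses them;
  PACs with zero signal in either sample are skipped and logged, never
  scored.
* A fully tied Mann-Whitney comparison reports p = 1 (no evidence), not
  `NaN`.
* Duplicate reads count individually; `collapse_umi = TRUE` collapses by
  (position, UMI) when a UMI tag is present. Library orientation defaults
  to `reverse` (dUTP chemistry) and is configurable.

## Validation scale

The test-suite and acceptance-script simulations use 2,000 genes at depth
500 for null calibration, 200 shifted genes for power and direction
recovery, and 100 seeded cohort replicates for PDUI calibration — sizes at
which every Monte-Carlo bound in the checks is tight while the whole suite
runs in a couple of minutes on a single core.

## Known limitations

* Two-sample design: no replicate-aware dispersion modelling and no
  multi-condition joint test; with one library per condition, `detected`
  reflects library-composition differences, and the score gate (or
  external replication) must carry the biological burden of proof.
* The published call rule's score gate only passes majority usage flips;
  partial shifts are visible in `detected` and in the PDUI layer instead.
* No internal-priming filter is offered anywhere, so results cannot be
  silently changed by one; upstream data quality is the user's
  responsibility.
* Gene assignment trusts the annotation plus a downstream margin (default
  1 kb); unannotated distal UTR extensions beyond the margin become
  `intergenic`.
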