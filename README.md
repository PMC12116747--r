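# apashift

Differential alternative polyadenylation (APA) from 3'-end sequencing.

Most mammalian genes carry several polyadenylation sites (PAS) in their 3'
UTR; the balance between proximal (short-UTR) and distal (long-UTR) site
usage is actively remodelled in signalling and disease, and 3'-end
protocols such as PAS-seq read it out directly — every read 3' end marks a
cleavage site. `apashift` is an R package for analysts working with such
data (or with precomputed distal-usage matrices): it turns per-position
3'-end counts into poly(A)-site clusters, tests each cluster for a usage
shift between two conditions, quantifies distal usage per gene, and
annotates the sequence elements that drive site choice.

## What it computes

* **Quantification**: per-site tags-per-million
  (`TPM = count / total × 10⁶`, denominator before filtering), sites with
  TPM < 1 excluded per sample.
* **Clustering**: single-linkage PAS clusters (PACs) at adjacent gaps
  ≤ 24 nt; single-site PACs with TPM < 3 removed; cross-sample consensus
  PACs chained at summit distance ≤ 500 nt from PACs with TPM > 5.
* **Shift test**, per consensus PAC between control A and treatment B:
  * shifting score `S = 1 − 2·Σᵢ min(pAᵢ, pBᵢ) ∈ [−1, 1]` on the
    normalised per-position profiles (−1 identical, +1 disjoint, positive
    iff the majority of signal mass has moved);
  * count-weighted two-sample Kolmogorov–Smirnov statistic
    `D = maxᵢ |F_A(i) − F_B(i)|` with asymptotic p at `√n_eff·D`
    (`n_eff = n_A n_B/(n_A+n_B)`), exact conditional tail for small PACs;
  * Benjamini–Hochberg FDR over all tested PACs; `detected` at q ≤ 0.01
    with TPM > 5 in both samples, `significant` additionally requiring
    S > 0; direction (lengthened / shortened) from distal signal fractions
    around the pooled-profile median.
* **PDUI**: `distal/(proximal + distal)` per gene and sample from the two
  strongest PACs, plus median-split marker stratification compared by a
  two-sided Mann–Whitney U test.
* **Motifs**: AAUAAA-family hexamers and UGUA (CFIm) elements upstream of
  cleavage sites, genomic context annotation
  (3UTR > CDS-exon > intron > downstream-1kb > intergenic), and the
  AUUAAA→CCCCCC proximal-signal knockout edit.
* **Simulation**: a seeded generator of two-PAS genes with
  negative-binomial counts, read-end jitter and planted usage shifts,
  emitting GTF/FASTA/TSV plus ground truth, so the whole chain is testable
  without external data. A ddCt utility converts isoform-specific RT-qPCR
  Ct values into relative distal-site usage.

Inputs are standard formats: indexed BAM (or site TSVs), GTF annotation,
FASTA sequence, TSV matrices. Every user-facing function takes a data
frame first and returns a tibble, so steps chain with the pipe;
`run_pipeline()` executes the whole chain with the default thresholds
above and writes a provenance record.

## Worked example

Simulate a treated-vs-control experiment in which every gene shifts its
distal usage by 0.3 and 70% of shifts are lengthenings, then run the
pipeline:

```r
library(apashift)

sim <- simulate_apa_dataset(
  synthetic_spec(n_genes = 200, fraction_shifted = 1,
                 fraction_lengthened_among_shifted = 0.7, delta = 0.3,
                 depth = 500, seed = 42))

res <- run_pipeline(
  apa_config(sim$sites, control = "control", treatment = "treatment",
             annotation = sim$features))
res
#> apashift pipeline result
#>   28806 sites | 771 PACs | 200 consensus PACs
#>   control vs treatment: 200 tested, 200 detected (q <= 0.01), 4 significant
#>   genes: 140 lengthened / 60 shortened (70.0% lengthened)
```

Reading the output: 28,806 distinct (position, sample) sites collapse into
771 per-sample PACs and 200 consensus PACs (one per simulated gene). All
200 are `detected` — their cumulative 3'-end distributions differ at
q ≤ 0.01 with ample signal — while only 4 pass the stricter published
`significant` rule, whose score gate S > 0 demands a majority usage flip
and a Δ of 0.3 sits well below it. The per-gene summary recovers the
planted 70% lengthening shape (140/200). Per-PAC detail is a tibble:

```r
head(tidy(res$shifts)[, c("consensus_id", "gene_id", "score", "ks_d", "q", "direction")], 4)
#> # A tibble: 4 × 6
#>   consensus_id gene_id    score  ks_d        q direction
#>   <chr>        <chr>      <dbl> <dbl>    <dbl> <chr>
#> 1 cons_0145    gene0090  0.0513 0.516 1.32e-67 shortened
#> 2 cons_0126    gene0052  0.0579 0.513 5.22e-58 shortened
#> 3 cons_0157    gene0114  0.0193 0.495 4.90e-57 lengthened
#> 4 cons_0051    gene0101 -0.0236 0.477 2.89e-54 lengthened
```

and `autoplot(res$shifts)` draws the lengthened/shortened scatter of
distal signal fractions. A cohort-level check with the PDUI layer:

```r
cohort <- simulate_cohort_pdui(n_samples = 48, n_genes = 200,
                               marker_effect = 1, seed = 42)
stratify_and_compare(cohort$pdui, cohort$marker, marker = "LDHA")
#> Stratified PDUI comparison (sample-wise) on marker LDHA
#>   high (n=24) mean PDUI 0.6927 vs low (n=24) mean PDUI 0.4900
#>   Mann-Whitney U = 576.0, two-sided p = 6.2e-14
```

Samples with high marker expression carry systematically longer 3' UTRs
(mean PDUI 0.69 vs 0.49), recovered by the median-split comparison.

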