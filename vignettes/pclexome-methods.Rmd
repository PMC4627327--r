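---
title: "Methods: somatic filtering, signatures and integration in pclexome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: somatic filtering, signatures and integration in pclexome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`pclexome` implements the analysis stack of a whole-exome somatic-mutation
study of a small tumor cohort — modeled on primary plasma cell leukemia
(pPCL) — in which matched normal samples exist for only part of the
patients. This vignette documents the models and conventions behind each
stage, the parameters that matter, what the synthetic-data generator does
and does not emulate, and the design decisions taken where the underlying
methodology was genuinely open.

## The filtering model

A tumor-only (or partially paired) design cannot rely on a paired somatic
caller, so somatic status is established by elimination. The cascade runs
in a fixed order:

1. **Depth filter** — `total_depth >= min_depth`, default 10 reads,
   boundary inclusive. Ten-fold coverage is the conventional point at
   which false positive calls from shallow coverage are controlled while
   retaining most of a ~40x exome.
2. **Non-silent selection** — keeps missense, nonsense, frameshift,
   in-frame indel and splice-site consequences; synonymous and non-coding
   calls are removed. Splice-site status is taken from the annotation
   (the ±2 bp convention is used by the synthetic generator).
3. **Polymorphism filter with rescue** — any variant catalogued as a
   population polymorphism (union of dbSNP/1000 Genomes/ESP, modeled as a
   single boolean) is removed *unless* it is also present in COSMIC or
   ClinVar. The rescue exists because true somatic hotspot variants
   (e.g. in *TP53*) can be polymorphism-database members; membership in a
   cancer or clinical catalogue is treated as sufficient reason to keep
   the call for later scrutiny. All ClinVar membership rescues — no
   distinction of benign entries is made, since significance
   classifications shift between releases.
4. **Control subtraction** — a tumor variant is removed if its
   normalized (chrom, pos, ref, alt) key is called in at least one
   supplied control with depth `>= min_control_depth` (default 10): a
   shallow control cannot veto. Paired mode supplies the matched normal;
   unpaired mode supplies the pool of the other patients' normals. Indel
   keys are normalized by trimming shared padding bases (a reference-free
   parsimony normalization; full left-alignment across repeat tracts
   would require the genome sequence, which this pipeline deliberately
   does not consume).
5. **Sub-clonal labeling (paired mode only)** — see below.

Annotation flags are precomputed inputs rather than live database
queries, which removes network and database-version dependence from the
pipeline; the readers accept them as VCF INFO flags or TSV columns.

### Sub-clonal labeling

A clonal heterozygous variant in a diploid region of a tumor with purity
$\rho$ has expected variant allele fraction $0.5\rho$. We estimate the
cancer-cell fraction as $\mathrm{ccf} = 2\,\mathrm{VAF}/\rho$ and label a
call sub-clonal when both:

* a one-sided exact binomial test rejects (at level $\alpha = 0.05$) the
  clonal expectation, i.e.
  $P\!\left(X \le \text{alt} \mid X \sim \mathrm{Bin}(\text{depth}, 0.5\rho)\right) < \alpha$, and
* $\mathrm{ccf} < 0.5$.

Both thresholds are exposed as parameters. The dual condition prevents
deep-coverage samples from labeling trivially small VAF deviations as
sub-clonal: significance alone is not evidence of a sub-clone when the
implied cancer-cell fraction is near 1. This rule is a declared surrogate
for an unpublished caller-level procedure; it is deliberately simple,
transparent, and testable against the generator's truth channel.

### Carry-over audit and recurrent-variant flagging

For a tumor without a matched normal, private germline variants that are
absent from the polymorphism databases *and* from the control pool
survive the cascade. The audit runs every paired tumor both ways — paired
against its matched normal, and unpaired against the pool of the *other*
patients' normals — and reports the calls unique to the unpaired run. On
the default synthetic design this private background is a few percent of
calls, concentrated in the ~2% of germline sites simulated as absent from
databases, plus database-present sites rescued by COSMIC membership and
not carried by the other patients.

Identical variants recurring in two or more unpaired samples that are
polymorphism-database and COSMIC members but not confirmed somatic are
flagged as likely residual germline; downstream recurrence counting
counts each flagged variant set once rather than once per sample, so that
genes are not over-scored by germline leakage.

## Mutational signatures

Single-nucleotide variants are classified into 96 trinucleotide classes:
six pyrimidine-reference substitutions × 16 flank combinations, in the
conventional order (substitutions alphabetical; flanks A, C, G, T with
the 5' base cycling slowest). Purine-reference calls are
reverse-complemented before classification; the collapse is an involution
tested over all 192 strand-explicit inputs. SNVs whose context is
unresolvable are counted in a reported `n_no_context` tally and excluded
from the spectrum — a deliberate convention, since silently dropping them
would violate count conservation.

Attribution solves the non-negative least squares problem
$\min_{e \ge 0} \lVert p - M e\rVert_2$ where $p$ is the normalized
96-count vector and $M$ a 96×K signature matrix with unit column sums;
exposures are renormalized to sum to 1. A sample is called a *distinct*
signature when one exposure reaches `distinct_threshold = 0.7` — a
declared convention for an otherwise qualitative label — and an
*admixture* otherwise. The packaged default matrix contains two synthetic
profiles: an aging-like column concentrating 96% of its mass uniformly on
the four NpCpG C>T contexts, and an APOBEC-like column concentrating 96%
on the eight TpCpN C>T/C>G contexts, the remainder uniform. Canonical
published signature catalogues are *not* bundled (their versions drift);
any user 96×K matrix is accepted.

NNLS is solved by the Lawson–Hanson algorithm; tests verify agreement
with an exhaustive 0.001-grid search over the two-signature simplex to
within 0.002, and recovery of planted exposures at 1,000 SNVs per sample
to a mean absolute error below 0.05.

## Copy-number integration

Segments (0-based half-open, BED convention) are projected onto each
gene's largest transcript (ties broken by lexicographically smallest
transcript id). A gene takes the copy number of the segment with the
greatest overlap; genes overlapping segments with differing copy number
are flagged mixed; genes with no overlapping segment sit at the diploid
baseline. One exception overrides greatest-overlap: if *any* overlapping
segment has copy number 0, the gene is recorded as homozygously deleted,
because a focal deletion inside a gene destroys it regardless of how much
of the gene lies in neutral territory.

Copy-number classes on a diploid baseline are 0 = homozygous deletion,
1 = hemizygous deletion, 2 = neutral, 3–4 = gain, ≥5 = amplification; the
gain/amplification boundary is configurable. A per-sample baseline
override supports basally tetraploid samples (baseline 4 shifts every
class threshold by +2).

Two-hit (biallelic) inactivation is emitted for every sample×gene that is
homozygously deleted, and for every sample×gene with at least one
non-silent somatic call on a hemizygous background. Genes with two or
more mutations but no copy loss are *not* two-hit events — mutation phase
is unknown without loss — and are reported separately as multi-mutated.

Variant positions are 1-based (VCF convention); all comparisons against
half-open intervals go through a single conversion function
(`pos_to_zero_based`), so a variant at `pos = start + 1` overlaps a
segment and one at `pos = end + 1` does not.

## Recurrence and enrichment

Damaging-variant enrichment of a gene set uses the 2×2 table
{damaging, other} × {in set, out of set} over all non-silent calls, with
genes on a packaged, user-replaceable spurious-gene list excluded from
the universe (large/late-replicating genes and similar frequent
passengers). The one-sided Fisher exact p is computed as the exact
hypergeometric tail by direct summation of `choose()` terms in log space;
tests verify equality with the closed-form tail and with one-sided
`fisher.test` on every 2×2 table of total size up to 60. The variant
level (rather than gene level) was chosen as the enrichment universe
because the reported per-pathway quantities have the shape
damaging/total *variants*.

The resampling null draws B samples of m calls (m = the set's call
count) without replacement from the universe and reports the add-one
p-value $(1 + \#\{f_{draw} \ge f_{obs}\})/(B+1)$. Since the damaging
fraction of a draw depends only on its damaging count, draws are
generated as hypergeometric counts — distributionally identical to
resampling call identities and orders of magnitude faster, which is what
makes a $B = 10^5$ default practical. FDR control is Benjamini–Hochberg
step-up via `p.adjust`.

## Expression integration

Variable genes are those with at least one sample at or beyond
`log2(fold)` (default fold 2) from the gene's cross-sample mean — a
"2-fold-from-average" rule. Samples are clustered on a gene subset with
distance 1 − Pearson correlation and average linkage; the merge order is
deterministic. Group association uses a permutation null on the
statistic "largest number of the group's samples in one cluster"
(B = 10,000 default, seeded); a permutation test was preferred over a
Fisher test on a chosen cluster because it avoids post-hoc cluster
selection bias. The biological homogeneity index is the mean, over
clusters with ≥2 annotated members, of the fraction of ordered pairs of
distinct members sharing a class. The replication probability asks how
often a random equally-sized draw from the variable-gene list clusters
the samples as homogeneously (by BHI against translocation groups) as
the focal mutated-gene set does. Differential expression is a per-gene
Welch t-test with BH adjustment — a deliberately standard surrogate where
the underlying study's exact test was not specified; zero-variance genes
are flagged with p = 1 rather than dropped.

All permutation p-values carry the add-one lower bound $1/(B+1)$ and are
exactly reproducible under a fixed seed.

## The synthetic cohort generator

The generator emulates the study design the package targets: 12 tumors,
5 with matched normals, mean depth 42x (per-site depth Poisson, truncated
at 1 read), ~150 clonal somatic events per tumor of which 7% are indels
(calibrated so non-synonymous SNV and indel counts per sample average
near 150 and 10), 20 sub-clonal events in paired tumors at cancer-cell
fraction 0.2, and purity 0.9. Germline variation (1,500 sites per
individual) is drawn from a shared polymorphism pool three times the
per-individual count, which makes sites shared between individuals —
exactly what pooled-normal subtraction exploits — while 2% of pool sites
are simulated as absent from polymorphism databases to exercise the
carry-over audit. Somatic SNV contexts are drawn from each sample's
aging/APOBEC mixture; by default t(14;16) samples are APOBEC-dominated
(weight 0.9), one sample is aging-dominated, and the rest are
aging-leaning admixtures, mirroring the translocation-signature
association the field reports. Planted events — two-hit genes
(mutation + 1-copy loss, and pure homozygous deletions), recurrent
unconfirmed germline artifacts in unpaired tumors, differentially
expressed genes (Δ = 1.5 log2 between 21 leukemia and 55 myeloma
expression samples) and translocation-structured genes — are recorded in
a truth channel against which every stage is scored.

What the generator does **not** emulate: read-level data (no FASTQ/BAM),
linkage and haplotype structure, mutation hotspots within genes,
copy-number-dependent VAF shifts (somatic VAF is simulated diploid
regardless of local copy number), sequencing artifacts with positional
error profiles, and array normalization effects. A passing test suite
therefore demonstrates correctness of the *algorithms* under the stated
statistical model, not robustness to every artifact of real exome data.

The toy genome is 24 named chromosomes of 2 Mb with ~500 genes of 1–3
transcripts — small enough that a full cohort simulates in under a
second. Because this genome is roughly a thousand times denser in
variants than a real exome, somatic positions are redrawn if they land
exactly on a polymorphism-pool site: in real data the per-site somatic
mutation probability makes such coincidences vanishingly rare, and
without the redraw the pooled-normal subtraction would occasionally veto
a true somatic call purely as a desk-scale artifact.

## Numerical and reproducibility choices

* All randomness flows from a single integer seed per generator or test;
  identical seeds give byte-identical cohorts and pipeline bundles.
* Exact tail probabilities (binomial, hypergeometric) are computed by
  direct summation in log space, never by normal approximation.
* Tie-breaks are always documented and deterministic: largest transcript
  ties by transcript id; greatest-overlap ties by segment start;
  clustering merge order by the index-based convention of `hclust`.
* Degenerate inputs error loudly and early (empty spectra, empty control
  sets, zero-variance sample profiles, overlapping segments) rather than
  propagating silent defaults.
* Problem sizes in the test suite (50 synthetic cohorts for the cascade
  properties, 20 seeds × 3 exposure pairs at 1,000 SNVs for signature
  recovery, 200-repeat permutation calibrations, exhaustive 2×2 tables to
  n = 60) were chosen as the smallest designs whose statistical power
  makes the checks meaningful.

## Known limitations

* Unpaired-mode somatic calls are inevitably contaminated by private
  germline variants absent from databases and the control pool; the
  package quantifies (audit) and mitigates (flagging, de-duplication)
  but cannot eliminate this.
* The sub-clonal test assumes diploidy at the variant site; variants in
  CN-altered regions have biased CCF estimates.
* Signature attribution with two synthetic profiles is identifiable and
  well-conditioned; attribution against large catalogues of correlated
  signatures would need regularization that is out of scope here.
* Driver-gene discovery requiring external background mutation-rate
  catalogues is not implemented; recurrence ranking stands in for it.
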