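---
title: "Models and methods behind relapsetrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind relapsetrace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(relapsetrace)
```

relapsetrace implements the downstream computational stages of a
tumor/germline whole-genome study design in which each leukemia patient
is sampled at diagnosis, remission (the germline control) and one or two
relapses. This vignette documents the models, the tunable parameters,
the numerical choices, and what the synthetic-data generator does and
does not establish.

## Coordinates and containers

All positional data is 0-based half-open (BED convention); VCF's
1-based positions are converted on read and back on write. Variants,
intervals and structural variants are plain data frames with light S3
classes and validators, which keeps every stage pipeable and
text-serializable.

## The somatic filter cascade

Union calls from two callers pass six independent, deterministic rules.
A variant is removed iff it fails at least one; because rules never
interact, the cascade is order-free and each removed variant carries
all of its failed rule ids.

| rule | fails when | default |
|------|-----------|---------|
| `depth_anomaly` | germline depth at the site > fold x chromosomal mean germline depth | fold = 3, strict |
| `low_af` | AF < floor | 5%; 10% for samples with a prior bone-marrow transplant or > 90% dbSNP overlap |
| `repeat_overlap` | variant interval intersects an annotated repeat | — |
| `homopolymer` | interval grown by 1 bp intersects a single-base run >= 7 bp | run length 7, flank 1 bp |
| `near_indel` | SNV within 5 bp of a same-sample indel call | 5 bp, inclusive |
| `population_variant` | SNV matches a population record on position + alleles (indels: position within 1 bp) | — |

Boundary conventions are strict where the source description says
"below"/"higher than" (AF exactly at the floor passes; germline depth
exactly 3x the mean passes). The flagged-sample exception is
grammatically ambiguous in its source; we implement it as a switched
floor (0.10) and expose both floors in `filter_config()`.

Homopolymer runs are found by run-length encoding of the reference;
"flanked" is operationalized as a 1 bp expansion of the variant
interval, configurable via `homopolymer_flank_bp`.

Structural variants are filtered by reciprocal overlap (>= 50%,
`min(ov/len_a, ov/len_b)`, same SV type) with a population panel, by
overlap with low-coverage windows (10 kb, < 10 reads) or assembly gaps,
by same-sample DEL-over-DUP overlap (only the deletion is removed), and
by an excluded-gene list (T-cell receptor / HLA / immunoglobulin loci);
a whitelist of known driver and fusion genes overrides all removals.

## Mutational signatures

Catalogs are 96-channel trinucleotide counts (pyrimidine-centric,
`A[C>A]A` ... `T[T>G]T`, substitution class slowest). De novo
extraction is non-negative matrix factorization with multiplicative
updates under the generalized Kullback-Leibler (Poisson) objective,
which is the natural likelihood for count catalogs; the best of
`n_restarts` seeded restarts is kept per rank.

**Rank selection.** We surveyed both Frobenius and KL objectives on
simulated cohorts (67 samples, burdens 150-3000, three planted
signatures). Under Frobenius loss each extra rank beyond the truth
still absorbs ~20% of the residual sum of squares — multinomial noise
is heteroscedastic and high-burden samples dominate — so no fixed
relative-improvement cutoff can find the elbow. Under the KL deviance
the noise plateau is a few percent and well-separated from signal
ranks, which improve the deviance an order of magnitude more. The rule:
compute the relative deviance improvement of each rank over its
predecessor, estimate the noise plateau as the smallest surveyed
improvement, and select the largest rank whose improvement is at least
`max(elbow_threshold, 3 x plateau)` with `elbow_threshold = 0.05`.
The factor 3 sits between observed plateau fluctuation (~1.4x) and
signal ratios (>= 10x); it is a structural constant, not a fitted one.
Per-rank RSS is reported alongside for scree plots.

**Matching and parsimonious selection.** De novo signatures are matched
to a reference catalog by cosine similarity with a deliberately relaxed
threshold (> 0.65) because small-cohort de novo signatures are mixtures.
The staged reduction then refits the catalog by per-sample non-negative
least squares (exact Lawson-Hanson active set) on growing candidate
sets: stage 1 is the best match per de novo signature; later stages add,
per de novo signature, its next-best candidate preferring the same
branch of the average-linkage dendrogram (distance 1 - cosine) of all
candidates, until each de novo signature has two representatives. After
each stage, per-sample reconstruction cosines are compared with the de
novo baseline by a paired two-sided t-test; the first stage with
p > alpha (default 0.05) is accepted. Zero paired differences count as
perfect equivalence (p = 1), and `alpha = 1` accepts stage 1 by
definition. NNLS refitting guarantees reconstruction cosines are
monotone non-decreasing as the signature set grows; the test suite
asserts this invariant throughout.

**Reference signatures.** The package does not ship the COSMIC catalog.
`make_reference_signatures()` builds a deterministic, synthetic
ten-signature stand-in with familiar labels and qualitative shapes (CpG
clock, APOBEC pair, mismatch-repair, flat signatures). Results against
it validate the machinery, not any biological attribution; real COSMIC
TSVs load via `read_signatures()`.

## Non-coding hotspots

Non-coding SNVs are gated on overlap with labeled regulatory intervals
(H3K4me3, H3K4me1/H3K27ac, DNase1 hypersensitivity, TF binding sites)
and absence from a population panel; conservation overlap is recorded
but never filters. Gated variants are clustered per chromosome by
complete-linkage agglomeration on genomic distance with a strict cut:
clusters merge while the merged diameter stays < 100 bp. Complete
linkage is the only standard linkage whose merge height *is* the
cluster diameter, so the cut enforces the definition exactly; in 1-D
the closest pair under this criterion is always adjacent, which the
implementation exploits (the tests compare it against a naive O(n^3)
agglomerator and check diameter and pairwise non-mergeability).
Clusters with fewer than 2 distinct patients are discarded. A gene
counts as expressed when log2(FPKM) > 1, i.e. FPKM > 2, strict.

## Driver rules

A gene is called a driver when (1) an external significance tool
reports p <= 0.05, (2) non-silent hits recur in >= 2 distinct patients,
(3) hits are non-silent, (4) some carrier has AF >= 0.25, and (5) the
mutant allele is seen in RNA in >= 1 carrier sample. Genes on the
configurable known-driver list skip (1)-(2) and a single patient
suffices. The verdict is monotone in satisfied criteria. Criterion 4 is
evaluated in any carrier sample (whether it must coincide with the RNA
evidence sample is unstated in the source; we chose the permissive
reading). External tools are consumed as tables, never invoked.

## Subclonal reconstruction and trajectories

Per patient, SNVs observed at all timepoints are clustered on their
joint read counts by a finite binomial mixture fit with EM; the
component count is chosen by BIC over 1..10 and clusters below 5
variants are merged into their nearest centroid. This deliberately
replaces Dirichlet-process clustering: at ~90x depth with hundreds of
variants the finite mixture recovers the same cluster structure and is
deterministic under a seed. Cluster AF centroids convert to cancer cell
fractions by the diploid copy-neutral rule CCF = min(1, 2AF/purity);
variants in copy-altered regions should be excluded upstream.

Clone trees are enumerated exhaustively over the clusters: the root is
the cluster with maximal CCF, and a tree is accepted iff at every node
and timepoint the children's CCFs sum to at most the parent's within
eps = 0.05 (the pigeonhole/sum rule; the slack absorbs binomial
sampling noise at 90x). The search prunes on the pairwise condition but
allows any acyclic parent choice, so it is complete — the tests verify
exact agreement with brute-force enumeration up to 5 clusters. Among
consistent trees the "best" minimizes total parent-child CCF slack
(tightest nesting), ties broken lexicographically. Stability is
assessed by bootstrap: variants are resampled, cluster CCFs recomputed,
and the consensus topology is the candidate consistent with the most
resamples; the probability score is the fraction of resamples whose own
best tree matches the consensus. This score is *not* the ClonEvol
consensus probability; published scores are parsed as data and never
recomputed.

Trajectory classification for an interval (baseline -> relapse): let
M_D and M_R be the major clones (highest clone-exclusive prevalence
among clones with CCF >= 0.05) at baseline and relapse, and A the
nearest ancestor-or-self of M_R present at baseline. The label is
**persistent** if A = M_D (including the override where the founding
clone itself is the baseline major), **rising** if A is a present
non-major baseline subclone, **founding** if A is the founding clone,
and **undetermined** when relapse purity < 0.2 or no consistent tree
exists. The same rules applied with r1 as baseline give
relapse-to-relapse calls. A founding call can be revised to rising when
deep targeted resequencing detects a relapse-lineage variant at
baseline with AF >= 0.01.

## The synthetic world

The generator emulates the statistical structure the pipeline assumes,
at the published scales: burdens uniform in 152-1343 per diagnostic
sample, ~90x Poisson depth, purity 0.7-0.95 (the blast-count range),
2-4 clones per patient, and 96-channel catalogs drawn multinomially
from signature mixtures. Per-sample signature weights are
Dirichlet-distributed around the configured cohort means
(concentration `weight_alpha = 0.8`): real cohorts are strongly
heterogeneous (APOBEC and mismatch-repair signatures concentrate in a
few samples), and that heterogeneity is also what makes NMF
identifiable — with identical mixing in every sample the expected
catalog is rank one regardless of the number of signatures. Clone
trees are constructed to satisfy the sum rule exactly and, on request,
to realize a target trajectory; expected AFs follow purity x CCF / 2,
which yields the clonal AF peak at 0.35-0.50 and the subclonal peak at
0.10-0.25 under defaults. Artifact variants violating exactly one
filter rule each are planted against a ~100 kb two-chromosome toy
reference whose background is generated with homopolymer runs capped
at three bases, so the only >= 7 bp runs are the planted ones.

What a green test establishes: the algorithms recover planted
structure under the model they assume. What it does not: performance
on real genomes — no sequencing-error model, no mapping artifacts, no
copy-number variation, no sample contamination, and synthetic (not
COSMIC) signature profiles.

## Cohort fixtures

Two transcribed clinical tables ship with the package (29 patients;
trajectory labels, consensus-model probability scores, critical genes
per timepoint). Tallies computed from them — the trajectory split
12/11/3/3, 26 consensus models, 20 scores strictly above 0.8, 4 below
0.65, the CDKN2A counts 8/1/1, the 96/67 genome inventory, and the
Fisher exact p = 0.06 on the driver-count table — are asserted in the
acceptance tests. Probability scores are reported "as published".
`fisher_exact_two_sided()` uses the standard convention (sum of
hypergeometric outcomes no more probable than observed, with a 1e-7
relative tolerance against floating-point ties) and is tested against
full enumeration and `stats::fisher.test`.

## Known limitations

- Copy-number aware CCFs are out of scope; the diploid rule is wrong in
  CNA regions and such variants must be excluded by the caller.
- Tree enumeration is exponential in the worst case; it is capped at
  20000 trees (a warning-level situation that real cluster counts,
  <= 11, do not reach in practice).
- The synthetic reference signatures are stand-ins; attribution results
  on real data require the real COSMIC catalog.
- The binomial mixture ignores overdispersion; at much higher depths a
  beta-binomial would be needed.
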