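---
title: "Methods: guide–target motif discovery from two-orientation chimeric reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: guide-target motif discovery from two-orientation chimeric reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trfclash)
```

This vignette documents the models, estimators and numerical choices behind
`trfclash`, and what the synthetic-data validation does and does not
establish.

## Chimera decomposition

A chimeric read is modelled as an exact concatenation of a guide (tRF) arm
and a target arm. The guide arm is the **longest exact substring match**
anchored at the read's 5' end (forward pairs) or 3' end (reverse pairs)
against each tRNA gene in its mature coordinate spaces: the gene body with
appended CCA, and — where a trailer is annotated — the body plus genomic 3'
flank. Matching is exact by design: the analysis targets fragments that map
perfectly to tRNAs, and sequencing-error tolerance is deliberately out of
scope. Because any substring of a match is itself a match, matchability is
monotone in arm length and the longest anchor is found by bisection.

Reads whose arm covers at least `trna_fraction_max` (default 0.80) of the
read are discarded as tRNA-dominated. The remainder of the read is the
target arm, annotated by exact substring match to the transcript reference;
for mRNA the region label (5'UTR / CDS / 3'UTR / intron) is assigned by
majority overlap, with ties broken 3'UTR > CDS > 5'UTR > intron so each
target gets a single label. Reads with qualifying guide arms on **both**
ends are guide–guide chimeras — classified `same_gene_disjoint` when both
arms place on one gene at non-overlapping intervals, `different_gene_pair`
otherwise — and are removed from the guide–target stream. Since the greedy
anchored arm can overrun the second arm by a few chance-matching bases, the
classifier trims one arm back to the partition point when both remain at
least `min_trf_arm` long.

Two thresholds the source analysis leaves unstated are fixed here and
exposed in `trf_thresholds()`: the minimum guide arm (16 nt, adopted from
the PAR-CLIP fragment filter for consistency) and the minimum target arm
(10 nt, below which exact annotation is unreliable). Ambiguous guide arms
shared by several isodecoders record all gene ids and use the
lexicographically smallest as canonical — deterministic and auditable.

## Fragment taxonomy

With gene length $L$ and anticodon loop $[\ell_s, \ell_e]$, a fragment
$[s, e]$ is typed in the precedence

1. `3t` if it ends at least 3 nt into the trailer (trailer-only fragments,
   often called tRF-1, fold in here);
2. `5p` if $s \le 5$ and $e < \ell_s$; `5i` ("tRNA half") if $s \le 5$ and
   $\ell_s \le e \le \ell_e$;
3. `3p` if $e \ge L - 1$ (the last 5 positions of the CCA-extended gene,
   CCA occupying the final 3) and $s > \ell_e$; `3i` likewise with
   $s \in [\ell_s, \ell_e]$;
4. `i` otherwise.

The precedence makes the map total; near-full-length fragments that could
satisfy several anchored rules are removed upstream by the 80% rule anyway.
An end inside $(L, L+3]$ is ambiguous between CCA and trailer space, so the
classifier takes an explicit space argument and the parser passes the space
the arm actually matched, preferring CCA. Canonical names are
`host_gene-origin-type-start-end` and parse back losslessly.

Orientation comparisons convert counts to within-orientation relative
frequencies over the union of items before computing Pearson correlation.
Fold changes use the exact frequency ratio when both counts are positive;
when an item is absent on one side, 0.5 is added to both of that item's
counts so the ratio stays finite without perturbing the common case.

## polyT artifacts and composition

Dinucleotide vectors count all overlapping dinucleotides (denominator
length − 1; ambiguity characters contribute to no window and break T-runs).
PCA is column-centred, unscaled, with a deterministic sign convention (the
largest-magnitude loading of each component is made positive) so scores are
reproducible across runs and row orders. Rather than separating the
polyT-enriched region of PC space by an operator-drawn boundary, the package
uses the explicit flags — longest T-run, run ≥ 5 nt
(`polyt_min_run`), run intersecting the last 10 nt of the target — and
reports how flagged points distribute over PC space, a reproducible,
data-independent definition. Targets flagged polyT are removed before motif
discovery; the partition into clean and polyT sets is exact.

## Motif model, discovery and significance

Per guide, the unique polyT-filtered target sequences (duplicates collapsed,
read support kept as weights; at least `min_motif_targets = 10` required for
EM stability) are fit with a **ZOOPS mixture**: each sequence contains at
most one motif occurrence; with probability $\lambda$ it carries a site at a
uniformly chosen position, else it is pure background (a 0-order model
estimated from the target set). EM alternates site-posterior computation
with PWM/$\lambda$ updates (pseudocount 0.25 per cell, at most 40
iterations, relative tolerance $10^{-5}$), from 3 starts seeded at observed
windows. Because EM can converge to a site alignment shifted by a column or
two, the winning fit is phase-polished from ±1/±2-shifted copies of its PWM;
the pre-polish score is kept for significance so observed and decoy fits are
compared under an identical protocol.

Significance per width: the observed ZOOPS log-likelihood-ratio score is
compared with scores from 20 **dinucleotide-shuffled decoy** target sets
(exact shuffles via rejection-sampled Eulerian walks on the dinucleotide
multigraph). The decoy scores calibrate a Gumbel null by method of moments
— a counting estimate with 20 decoys cannot resolve tail probabilities near
the 0.01 significance threshold, whereas the extreme-value form matches the
max-like construction of a best-motif score and is conservative relative to
a Gaussian tail — and the E-value is that upper-tail probability times the
number of widths tested (default 6–12). A motif is reported when
E < `motif_evalue_max` (0.01). On 50 uniform-random 40-mers this procedure
reports no motif in ≥ 95% of seeds.

**Match-back.** The motif's log-odds matrix (uniform background by default)
scans the reverse complement of the guide; the best window maps back to
5'→3' guide coordinates, and its p-value is the exact probability that a
random width-mer under the background scores at least as high, computed by
convolving per-column score distributions. For widths ≤ 10 the convolution
enumerates every achievable floating-point partial sum (identical to full
enumeration); wider matrices use an integer lattice at $10^{-4}$ granularity
with the threshold rounded conservatively. Matches at p < 0.001 are
significant.

Forward and reverse motifs of one guide are compared on guide coordinates:
`identical` requires equal intervals and mean per-column Pearson correlation
≥ 0.95 ("identical" has no canonical operational definition; this
criterion is the package's and is recorded in output), `overlap_ge4` at
least 4 nt of shared interval, then `minimal_overlap` / `disjoint` /
`one_missing`. The upstream–downstream test counts guides whose forward
motif starts 5' of the reverse motif (ties excluded) against an exact
two-sided binomial at even odds — at probability one half the doubled
smaller tail equals the standard exact two-sided test, so `stats::binom.test`
is used directly; for example it gives
(60/85 → 1.87·10⁻⁴; 53/73 → 1.42·10⁻⁴). Ranking flags, per quality
parameter (unique targets, read support, E-value, match-back p-value), the
top third of the cohort with ties sharing the better rank; motifs in the top
tercile of all four are high-confidence.

## PAR-CLIP conversion profiling

Reads of at least 16 nt are aligned end-to-end to the CCA- and
trailer-extended gene sequences: perfect placements are preferred anywhere;
otherwise exactly one mismatch is accepted and only where the reference base
is T and the read base is C. Ambiguous placements count once, against the
lexicographically smallest gene at the 5'-most offset. Each conversion event
contributes $10^6 / N_s$ reads-per-million ($N_s$ = the sample's aligned
read total; because the denominator convention varies — all aligned reads
versus tRNA-aligned reads — the package takes the totals as an explicit
argument). Samples are normalised separately and summed; the top
conversion site per gene is the maximal combined frequency, ties broken
5'-most and flagged. Cross-species mapping translates conversion positions
through full-length exact matches only.

For the structural picture, each motif-bearing guide is aligned so its top
conversion site sits at offset 0 and the per-column information content
(logo bitscore, $2 + \sum_b f_b \log_2 f_b$, no small-sample correction — the
simplest definition consistent with logo heights) accumulates at guide
position minus site. Each guide votes for the side (5' vs 3') carrying more
bitscore mass; the side-bias test is the same exact binomial as above.

## Reactivity classification

Scores over a target site and 20 nt flanks (the flank length is not stated
in the source; 20 nt is the default and configurable) are collected from the
track without imputation; sites with no valid score in the motif region are
`no_data` and excluded. A site is single-stranded when its motif-region mean
is ≥ 0.5, double-stranded below. The significance statistic per site is mean
motif-region score minus mean flank score; the null is built from random
12-mers drawn uniformly over the track's transcript positions (not matched
for region composition — documented choice), and the group mean is z-tested
against the null mean and s.d. scaled by the group size. One subtlety: the
DS/SS call itself conditions on the motif-region mean, so the per-class
z-tests are *not* null-calibrated even on random sites — they are reported
because they are the quantities of interest when a real effect exists — and
the pooled `all` row is the unconditioned test, which is calibrated
(≈ 5% rejections at α = 0.05 on null sites). A per-position variant of the
same z-test over the first motif offsets is available through the aligned
profile table.

## The synthetic-data generator

The generator emulates the full input suite with planted truth. Its
defaults encode the conditions the analysis is designed around: 3'-end
fragments with an 18 nt length mode, 5' halves of 33–36 nt ending in the
anticodon loop (loops are positioned to make that possible), crosslinking
hotspots at guide positions 8–12 whose reference base is forced to T,
conversion rate 0.3 against a 0.01 background, a DS probability of 0.983
with reactivity shift Δ = 0.3, and a polyT artifact rate of 0.1.

The orientation mechanism is a two-parameter generative reading of the
verbal model connecting binding side to ligation: each guide's motif is
placed 5' (upstream) of its hotspot with probability β (default 0.8);
upstream binders emit forward chimeras with probability 0.8 (downstream,
0.2); and 5' halves have their forward **odds** multiplied by 1 − γ
(default γ = 0.5), the cyclic-phosphate ligation penalty — odds scaling
makes the forward:reverse ratio of 5i fragments exactly (1 − γ) times that
of other types, the cleanest quantitative form of the verbal mechanism.
polyT artifacts are planted as T-runs written into the transcript
immediately 3' of a site, and artifact reads are emitted forward-only with
the run at the target arm's 3' end.

Two idealisations matter for interpreting green tests. First, transcript
backgrounds are post-processed to break chance T-runs of ≥ 5 nt, so the
planted artifact count is exactly recoverable; real libraries contain
genuine T-rich targets and the partition there is a filter, not an oracle.
Second, reads are exact concatenations — no sequencing error, adapters, or
UMI structure — and target flanks are chosen so the greedy anchored arm
cannot extend past the planted guide by a chance base match; recovery rates
on this generator are therefore upper bounds on real-data behaviour, and
the tests validate the *machinery* (filters, estimators, statistics), not
real-data effect sizes. Headline counts estimated from real libraries
(motif totals, orientation-specific read counts, the exact DS percentage)
are properties of those datasets and are not targets of the synthetic
validation.

## Problem sizes and determinism

The validation suite runs at desk scale, chosen as the package's own
defaults: hundreds to a few thousand simulated chimeras per scenario, 10,000
PAR-CLIP reads per hotspot-recovery replicate (20 replicates), 50-target
motif-recovery sets, 20-decoy E-value calibration, and 50-replicate null
calibrations. Every stochastic operation takes an explicit seed; the
pipeline writes a manifest of md5 sums and is byte-identical across runs at
a fixed seed. Degenerate inputs are handled explicitly: empty orientations
error in comparisons, all-missing reactivity sites are excluded rather than
imputed, zero-variance PWM columns compare as equal in motif identity, and
top-site ties break 5'-most with a flag.

## Known limitations

Exact-match arm detection misses chimeras with sequencing errors or
post-transcriptional edits; the E-value is an empirical calibration, not an
analytic expectation, and its resolution is bounded by the decoy count and
the Gumbel approximation; guide-arm ambiguity across isodecoders is resolved
canonically rather than probabilistically; hybrid free-energy modelling and
target-repression prediction are out of scope.
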