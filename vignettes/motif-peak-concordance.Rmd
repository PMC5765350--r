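---
title: "Comparing binding motifs and ChIP peaks across datasets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing binding motifs and ChIP peaks across datasets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

When two laboratories assay the genomic binding of the same DNA-binding
protein — say a KRAB zinc finger protein (KZNF) profiled once by ChIP-seq
and once by ChIP-exo — the peak lists rarely coincide: each experiment
samples, under noise, a subset of a much larger pool of bona fide binding
sites. Peak-level overlap therefore understates agreement. Two coarser
statistics are far more robust:

* **Which endogenous retroelement (ERE) classes are bound.** KZNFs
  preferentially bind transposon and retroelement families whose genomic
  copies descend from a common ancestor. The fingerprint "fraction of top
  peaks overlapping each ERE class" is stable across noisy replicates.
* **Which sequence motif is enriched.** Even when individual peaks differ,
  both experiments should be enriched for the protein's intrinsic
  recognition motif.

`motifconcord` implements both comparisons, an AUROC-based measure of motif
enrichment, and a rule-based procedure (classes A–F) that picks one
reference motif per protein from candidates of varying provenance — plus a
seeded synthetic-data generator reproducing exactly the statistical
structure these analyses assume, so the whole pipeline is testable without
any external download.

## Models and procedures

### PWM scoring

A motif is a position weight matrix (PWM): per position, a probability
distribution over A, C, G, T. Two scores are used:

* **Max log-odds match.** The score matrix is
  $S_{ib} = \log_2\frac{p_{ib} + c\,q_b}{(1+c)\,q_b}$ with background $q$
  (uniform by default) and pseudocount $c$ (default 0.01). A sequence's
  score is the maximum window sum over all offsets on both strands. This is
  the statistic used for AUROC evaluation: one number per 501-base summit
  window. `N` bases contribute 0 — the background-equivalent choice.
* **Summed affinity.** The sum over all windows (both strands) of
  $\prod_i p_{i,s_i}$, a Boltzmann-like predicted occupancy. `N` counts as
  0.25. Affinity is kept on its raw scale (a `log_affinity` toggle exists,
  off by default) because the closed form for a uniform motif,
  $2(l-w+1)\,0.25^w$, then holds exactly and the "affinity" semantics is
  preserved.

The source of the scanned sequence is a *summit window*: the interval
$[s-f,\ s+f+1)$ around summit $s$ with flank $f = 250$, i.e. 501 bases,
clipped at chromosome ends.

### The AUROC statistic

For a motif and a peak set, positives are the max log-odds scores of the
top-500 (by enrichment score) summit windows; negatives are the same
statistic on one dinucleotide-preserving shuffle of each window (1:1).
AUROC is computed exactly by the Mann–Whitney midrank formula
$(\#\{p>n\} + \tfrac12\#\{p=n\})/(|P||N|)$, so all-tied scores give exactly
0.5 and the value is invariant under monotone transforms. No normal
approximation and no p-values: the AUROC itself is the quality metric, with
0.6 used as the enrichment quality bar.

The shuffle is the Altschul–Erickson Euler-path construction: the exact
multiset of overlapping dinucleotides (hence length, endpoints, and base
composition) is preserved while higher-order arrangement is randomized.
Runs of `N` are frozen in place and the ACGT segments between them are
shuffled independently, preserving masked-region structure without
inventing bases. One shuffle per window is the default; when a grid of
motifs is evaluated on one peak set they share a single shuffled null so
that all motifs face identical negatives.

### Motif similarity

Similarity between two motifs is the Pearson correlation of their affinity
scores over one shared background of $n = 100{,}000$ random uniform
sequences of length $l = 100$ (both parameters configurable). Because both
strands are scanned, a motif and its reverse complement have identical
affinity vectors and similarity exactly 1. Interpretation bands: $r > 0.5$
is the level typically seen between experiments on the same transcription
factor; $r > 0.2$ related; below that, dissimilar. The raw correlation is
reported without further transformation.

### ERE profiles and the matched-vs-unmatched null

A peak set's ERE profile is the vector, over all annotated repeat classes,
of the fraction of top-500 summit windows overlapping at least one instance
of that class (a window spanning several classes counts in each, so the
vector may sum to more than 1). Agreement between two datasets covering the
same $k$ proteins is judged against an internal null: all $\binom{2k}{2}$
pairwise Pearson correlations among the pooled $2k$ profiles are split into
$k$ matched (same protein, different dataset) and $\binom{2k}{2} - k$
unmatched comparisons — the pooled definition is the one consistent with a
39-protein cohort producing 2,964 unmatched pairs. A threshold then
summarizes separation as the fraction of each group *strictly* above it;
it can be fixed or chosen to maximize matched-minus-unmatched separation
(ties resolved to the lowest threshold; whether a by-eye or best-separation
rule was used historically is not recoverable, so both are provided).
Constant profile vectors have no defined correlation and are reported as
missing rather than coerced to a number.

### Reference-motif selection (classes A–F)

Given per-protein candidate motifs — each annotated with derivation method
(recognition-code-assisted, general motif discovery, or external), in vitro
status, recognition-code support, and its training peak set if ChIP-derived
— the rules are evaluated in order; a candidate's *test score* is its best
AUROC on peak sets it was not trained on:

* **A** — some candidate's test score beats every other test-scored
  candidate's by ≥ 0.1;
* **B** — no A, and the best in vitro candidate is within 0.1 of (or above)
  the best ChIP candidate on test data;
* **C** — no A/B, and a recognition-code-supported ChIP candidate exists
  (highest test score wins; training score is the fallback when a candidate
  has no test set);
* **D** — some ChIP candidate's AUROC on its own training set beats all
  other candidates' training scores by ≥ 0.1;
* **E** — the best-vs-second-best test margin lies in [0.01, 0.09];
* **F** — everything else, reported as co-equal motifs.

Boundary semantics follow the rule text literally: class A needs margin
≥ 0.1, class B needs a gap strictly < 0.1, class E is the closed interval
[0.01, 0.09], so margins in (0.09, 0.1) fall to F. Rules A, D and E need at
least one other scored candidate to compare against, so a single-candidate
protein falls to F unless rule C applies. Within-class ties break by higher
test score, then method (recognition-code-assisted over general discovery
over external), then motif name — a deterministic policy chosen here, since
none is prescribed. Cross-dataset disagreement flags use strict cutoffs:
ERE-profile $r < 0.3$, motif similarity $r < 0.2$.

## The synthetic-data generator

The generator's defaults are the study conditions under which the package
validates itself:

| parameter | default | meaning |
|---|---|---|
| `n_proteins` | 10 | proteins with paired datasets |
| `genome_length` | 2 Mb | one background chromosome |
| `n_ere_classes` × `ere_copies_per_class` | 10 × 30 | ERE families and genomic copies |
| `ere_length` | 300 bp | family consensus length |
| `copy_mutation_rate` | 0.10 | per-base divergence of each copy |
| `motif_width` | 8 | planted PWM width |
| `true_site_pool_size` | 200 | shared pool of bona fide sites |
| `peaks_per_dataset` | 150 | peaks per protein per dataset |
| `false_peak_fraction` | 0.30 | noise peaks per dataset |
| `summit_jitter_sd` | 20 bp | Gaussian summit error |
| `score_noise_sd` | 2 | enrichment-score noise (true base 10, false 6) |
| `ere_site_fraction` | 0.60 | true sites placed inside assigned ERE classes |
| `corruption_fraction` | 0.75 | decoy columns replaced by uniform |

These sizes are desk-scale by design — large enough for stable AUROCs and
profile correlations, small enough that the full pipeline runs in about two
minutes on one core; they are the problem sizes used by the test suite and
the acceptance script. Key consequences of the defaults:

* Each dataset draws $0.7 \times 150 = 105$ true peaks without replacement
  from the 200-site pool, so two datasets share $105^2/200 \approx 55$ true
  sites — peak overlap near 40%, the partial-overlap regime.
* With 30% of evaluated windows carrying no planted site, the expected
  AUROC of the true motif is about $0.7 + 0.3/2 = 0.85$: comfortably above
  the 0.6 bar, deliberately below perfection.
* Each protein's 1–3 assigned ERE classes give matched profile pairs high
  correlation while unmatched pairs agree only by chance class sharing.
* Candidate motifs per protein are the true PWM
  (recognition-code-supported, trained on dataset 1), a corrupted decoy
  (75% uniform columns, trained on dataset 2), and another protein's PWM as
  an unrelated external candidate — an AUROC gap large enough that class A
  should recover the true motif. An optional near-true "in vitro" candidate
  (small Dirichlet perturbation) exists for exercising class B and is off
  by default, since a near-equal competitor by construction removes class-A
  margins.

What the generator does *not* emulate: insertion/deletion divergence of
ERE copies (substitution-only keeps coordinates simple), repeat phylogenies
within a class beyond a star tree, fragment-size or read-level artifacts,
chromatin context, indirect (cofactor-mediated) binding, and motif
misestimation by discovery algorithms (candidates are perturbations of the
truth, not rediscoveries). Passing tests therefore demonstrate that the
statistics behave as designed under their own assumptions — not that real
ChIP data meets those assumptions.

## Numerical and design choices

* Coordinates are 0-based half-open (BED convention) throughout; summits
  are absolute 0-based positions. Summit offsets in the peak dialect use
  −1 as the "interval midpoint" sentinel.
* "Two peaks overlap within ±250 bp of the summits" is read as: their
  501-base summit windows intersect (summit distance ≤ 500). The stricter
  reading — one summit inside the other's window (distance ≤ 250) — is
  available via `mode = "summit_in_window"`. Window intersection was chosen
  because it matches how the scanned sequences themselves are defined.
* Peak merging (gap ≤ 50 bp) keeps the maximum member score and the
  highest-scoring member's summit, ties to the leftmost start; merging is
  idempotent. Whether overlap should be computed on merged or raw peaks is
  not prescribed; the pipeline merges first.
* Top-N selection breaks score ties by (chrom, start) so results are
  deterministic; with fewer than N peaks, all are used.
* The log-odds scanner's pseudocount (0.01), uniform background, and
  both-strand policy are assumptions, configurable per call; ChIP peaks are
  strandless, so both strands is the default everywhere.
* Every stochastic operation takes an explicit seed; sub-streams are
  derived arithmetically (never from global state), so whole studies are
  byte-reproducible and one shuffled null can be shared across a grid
  column.
* Degenerate inputs yield explicit signals, not silent numbers: empty peak
  sets (undefined overlap/profile), constant vectors (missing correlation),
  windows shorter than the motif (dropped symmetrically from positives and
  negatives; an error only if none remain).

## Known limitations

* The affinity-correlation similarity is this package's fixed definition;
  other tools' internal normalizations of "energy scores" may differ by a
  monotone transform, which Pearson correlation does not fully absorb.
* The matched-vs-unmatched census mixes within- and cross-dataset pairs by
  design (the pooled definition); users wanting a cross-dataset-only null
  can compute it from the returned correlation lists.
* At desk scale the separation statistics are coarse (10 matched pairs);
  fractions move in steps of 0.1.
* The selection rules inherit the literal boundary gap between classes E
  and A: margins in (0.09, 0.1) are class F.
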