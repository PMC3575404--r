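---
title: "Scoring gene neighborhoods: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring gene neighborhoods: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genehoods)
```

## The problem and the model

In every genome studied so far, co-expressed genes are not placed at random:
they form *gene neighborhoods* — runs of consecutive genes with correlated
expression whose physical linkage is often also conserved across species.
Defining such neighborhoods by fixed rules (adjacency only, a minimum gene
count, a fixed window width) forces an arbitrary choice of scale. genehoods
instead scores *every* candidate window of consecutive genes across the whole
requested size range simultaneously and lets the score, not a size rule, pick
out the interesting loci.

Each candidate window (2 or more consecutive genes of the non-redundant gene
set on one chromosome) receives three quantities:

* **ANC** (Average Neighborhood Correlation): the mean of all
  $\binom{W}{2}$ pairwise Spearman correlations among the $W$ members'
  expression profiles. For members $A, B, C$:
  $\mathrm{ANC} = [\rho(A,B) + \rho(B,C) + \rho(A,C)]/3$.
* **p**: an empirical upper-tail p-value for the observed ANC under a
  position-preserving permutation null (below).
* **SS** (Synteny Score): the fraction of comparison species in which the
  window's base-pair span lies entirely within a single unbroken syntenic
  block. With 9 comparison species and the span conserved in 7 of them,
  $\mathrm{SS} = 7/9 \approx 0.78$.

These combine into the **Total Neighborhood Score**:

$$
\mathrm{TNS} =
\begin{cases}
\mathrm{SS} \times \mathrm{ANC} & p \le \alpha \\
0 & \text{otherwise,}
\end{cases}
\qquad \alpha = 0.05 \text{ by default, gate inclusive.}
$$

TNS is a *ranking* score, not a calibrated probability: $|\mathrm{TNS}| \le
\mathrm{SS} \le 1$, and anything that fails the significance gate is exactly
0. Because silent genes (below) have their correlations zeroed, windows
containing non-expressed genes are demoted automatically; with this
definition no non-expressed gene can anchor a high-scoring neighborhood.

## Preprocessing assumptions

**Non-redundant gene set.** Transcripts with overlapping coordinates would
let one locus masquerade as a multi-gene neighborhood, so overlapping
records are reduced first: within each connected component of the
interval-overlap graph the survivor is the record with the highest maximum
expression, ties broken by length (longest wins), then by id. The rule is
applied greedily and recursively, so one component can keep several mutually
non-overlapping records. Strand is ignored for overlap detection. Overlap
is defined pairwise; treating components rather than pairs is our
resolution of the (underdetermined) chained-overlap case, chosen because it
is deterministic and keeps the top-scoring representatives.

**Silent genes.** Non-expressed transcripts can still have beautifully
correlated (noise) profiles, and dropping them would make distant genes
adjacent. They are therefore *kept* in the gene set but flagged, and every
pairwise correlation touching them is set to exactly 0. Two policies are
provided, matching the two typical input kinds:

| policy | rule | default |
|---|---|---|
| `detection_calls` | fewer than `min_present_calls` "P" calls across samples | 12 calls |
| `expression_threshold` | max expression over samples strictly `<` threshold | 0.2 (RPKM, linear scale) |

The threshold comparison is strict, so a gene peaking at exactly 0.2 is not
silent.

## Correlation and numerical choices

Spearman's rho is used throughout (monotone-invariant, robust to the
platform-dependent scale of expression values). Ties get average ranks. A
constant profile has no defined rank correlation; it is assigned rho 0 with
every partner — the same convention as silencing, and for the same reason: a
flat profile carries no co-expression evidence. Correlation matrices are
stored per chromosome by default, since windows never span chromosomes and
the between-chromosome entries are never consumed; a genome-wide scope
exists for diagnostics.

ANC values are computed incrementally: the window of size $W$ at start $i$
reuses the pair-sum of the size $W-1$ window at the same start and adds only
the $W-1$ new pairs. The suite verifies equality with the brute-force mean
to 1e-12.

## The permutation null

To judge an observed ANC, gene *positions are kept fixed* and expression
profiles are shuffled uniformly across genes. This preserves the gene
density and regional structure of the genome, and the entire window
enumeration is identical between observed and null — only the profiles
move. Silent flags travel with their profiles, and zeroing is re-applied
after the shuffle. Null ANCs are pooled across shuffles *per window-size
stratum* (gene count, or requested bp budget), and

$$ p = \frac{\#\{\text{null ANCs at that size} > \text{observed ANC}\}}
           {\#\{\text{null ANCs at that size}\}} . $$

Counting is strictly-greater with no add-one correction; an optional
pseudo-count mode reports $(k+1)/(n+1)$ for users who need $p > 0$
guaranteed. Ten shuffles are the default: pooling across all same-size
windows genome-wide already gives thousands of null draws per stratum, and
the calibration test below shows that is sufficient. p-values are reported
unadjusted — the intent is ranking, neighborhoods overlap heavily (the
observed ANCs are strongly dependent across starts and sizes), and true
neighborhoods are not rare, all of which break the assumptions of the usual
multiplicity corrections. A Benjamini–Hochberg column can be emitted on
request but never feeds the TNS gate.

A single integer seed drives one reproducible stream: per-shuffle seeds are
drawn once from it, so runs are bitwise reproducible end to end.

## Synteny

A window's span (smallest member start to largest member end) is *conserved*
in a species iff it is contained in a single block's reference interval —
containment, not overlap, because a span crossing a block boundary does not
map to an unbroken segment in the other genome. Block orientation is
deliberately ignored: a locally inverted but contiguous segment still keeps
the neighborhood intact.

Users will usually supply precomputed block tables (one TSV per species).
For completeness a simplified anchor-chaining builder is included:
consecutive anchors (sorted by reference position) chain while they share
both chromosomes and both the reference and target gaps stay within
`max_gap`; chains need at least `num_mark` anchors and a reference span of
at least `min_blk`. Defaults are `max_gap` = 1 Mb, `min_blk` = 100 kb,
`num_mark` = 2 — at neighborhood resolution the gap parameter dominates
accuracy, while the other two are nearly inconsequential, hence permissive
defaults. Applying the gap test to both genomes (not just the reference) is
the stricter of the two possible readings and is our choice. Surviving
chains whose reference intervals still overlap (possible when chains to
different target chromosomes interleave) are merged so the builder's output
always satisfies the same non-overlap invariant the reader enforces.

## Window sizes

Gene-count windows (default 2–5 here; 2–50 is a realistic analysis range)
are exhaustive: every run of $W$ consecutive genes, for every $W$ in range,
clipped at each chromosome's gene count. Base-pair windows are less
canonical; we anchor them per start gene and take the *maximal* run fitting
the budget, which yields a deterministic nested family comparable across
budgets. (Enumerating every sub-run instead would only add windows that the
gene-count mode already covers.) bp-wise results tend to be biased toward
gene-poor regions, so gene-count windows are the primary mode.

## The synthetic-data generator

`generate_dataset()` emulates a small expression atlas: evenly spaced
2 kb genes on a 5 kb pitch, 20 samples, background profiles i.i.d. normal,
and planted clusters that share a latent factor. The factor loading is
calibrated via $r = 2\sin(\pi\rho_S/6)$ so the *Spearman* correlation hits
the requested target (0.9 by default, a strong co-regulated cluster);
values are then mapped through an increasing function onto a positive
linear scale, which leaves every rank statistic untouched while making the
silence thresholds and Tau directly applicable. Silent genes get
sub-threshold uniform values and all-"A" calls, so both silence policies
agree on them by construction. Per species, block tables contain each
planted cluster's (padded) span whole when that species is flagged as
conserving it, and split it at the cluster midpoint otherwise; background
segments are covered with probability 0.7, a moderate conservation level
that keeps background windows from being systematically unconservable.

What the generator does *not* emulate: probe effects, platform noise
structure, heteroscedasticity, gene-length and GC biases, overlapping
transcript models, or realistic synteny breakpoint distributions. Passing
tests therefore demonstrate the *algorithmic* correctness and calibration of
the scoring machinery, not performance on any real atlas.

## What the tests establish (sizes used)

* Null calibration: on a structure-free genome of 6 chromosomes × 200 genes
  (4740 windows, sizes 2–5) with 10 shuffles, the fraction of windows with
  $p \le 0.05$ lies within 3 binomial SEs of 0.05 and the Kolmogorov
  distance of the p-value ECDF from uniform stays below 0.05. Overlapping
  windows are positively dependent, which is why a comfortably large window
  count is used for this check.
* Planted recovery: across 50 seeded replicates of the default generator
  (3-gene cluster, Spearman 0.9, fully conserved, 20 samples, 10 shuffles),
  the planted cluster attains the top TNS rank on its chromosome in at
  least 95% of replicates; setting its conservation to 0 species forces its
  TNS to exactly 0 while its ANC stays high — SS and ANC are independently
  assertable.
* Oracles: window enumeration against brute-force run enumeration;
  ANC against brute-force rank-and-Pearson Spearman (tolerance 1e-12).

## Annotations

**Tau tissue specificity.** $\tau = \sum_{i=1}^{N} (1 - x_i / \max_j x_j)$
over a gene's $N$ sample values: 0 for uniform expression, $N-1$ when
exactly one sample is nonzero. Note this is the *unnormalized* form with
range $[0, N-1]$ — the index is often divided by $N-1$ elsewhere; we keep
the unnormalized range and document it prominently. Tau expects linear,
non-negative expression; the appropriate scale for log-transformed
intensities is a judgment call we resolve by requiring callers to de-log
first (ranks are unaffected elsewhere in the package, so this is the only
scale-sensitive statistic).

**Orientation.** Adjacent non-overlapping pairs are `co_oriented` (same
strand), `divergent` (head-to-head: upstream gene on `-`, downstream on
`+`) or `convergent` (tail-to-tail). The three classes partition all
adjacent pairs.

**Duplicates.** A pair is a (tandem) duplicate iff any protein-level BLAST
hit in either direction has e-value strictly below 1e-07; self-hits are
ignored. Duplicate-free gene sets drop the lower-expressed member of each
pair (ties: shorter, then lexicographically later id), iterating until no
flagged pair is intact — mirroring the overlap filter's keep-the-strongest
philosophy, since only "one of the two is removed" is inherent to the
definition.

## Degenerate inputs and edge behavior

* Chromosomes with fewer genes than the smallest window contribute no
  windows (not an error); single-gene chromosomes contribute none in any
  mode, and such genes report a best TNS of 0.
* An all-silent (or all-constant) chromosome yields ANC 0 everywhere and,
  under any null with positive mass above 0, gated TNS 0.
* Missing expression values are an error everywhere — no imputation.
* An empty per-species block file is a *valid* empty set: the species
  simply contributes 0 to every SS numerator.
* Expression-only mode (`no_synteny = TRUE`) sets SS = 1 for every window,
  reducing TNS to the gated ANC. This is an explicit extension for users
  without conservation data, not the standard scoring mode.

## Known limitations

* The block builder is a deliberately simplified chaining heuristic, not a
  replacement for a full synteny pipeline; supply curated block tables for
  real analyses.
* Large windows inherit significance from strong sub-windows ("shadows");
  use the non-redundant selection (`select_nonredundant()`) and the
  TNS-by-size matrix to identify the core of a hit rather than trusting the
  largest significant window.
* Chromosome names are compared verbatim between location and block files;
  a `chr1`/`1` mismatch silently yields SS = 0, so the inputs must agree.
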