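---
title: "Methods: splicing reprogramming and subgenome bias"
author: "splicebias"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: splicing reprogramming and subgenome bias}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicebias)
```

`splicebias` analyses two regulatory layers of an allopolyploid
transcriptome across condition groups — alternative splicing and homoeolog
(subgenome) expression bias — and integrates them. This vignette is the
package's own account of the models, the parameters that matter, the
numerical choices made where the design was genuinely open, and what the
bundled synthetic generator does and does not emulate.

## Event model

Transcript exon chains are held in 0-based half-open coordinates (GTF is
converted at I/O), so junction and containment arithmetic needs no
off-by-one corrections. Four local event types are enumerated from pairs
of isoform structures within a gene:

* **ES** — a cassette exon `(as, ae)` with flanking junctions `c1e->as`
  and `ae->c2s` in one isoform versus the direct junction `c1e->c2s` in
  another; anchor `(c1e, as, ae, c2s)`.
* **IR** — an intron `(c1e, c2s)` spliced in one isoform and covered by a
  single exon in another. The retained exon must span *exactly* the two
  flanking exons' outer boundaries (strict rule); a relaxed mode
  (`strict_ir = FALSE`) accepts any covering exon. The strict rule avoids
  ambiguous multi-intron retention calls; the retaining isoform is the
  inclusion form.
* **A5 / A3** — two introns sharing one boundary and differing at the
  other. Donor and acceptor are resolved by strand (the donor is the
  transcription-proximal intron end). One non-obvious constraint is
  essential: the region between the two alternative boundaries must be
  exonic in the shorter-intron (inclusion) isoform. Without it, every
  cassette exon would also fire a spurious donor and a spurious acceptor
  event, because its skip junction shares one boundary with each flanking
  intron. The shorter intron retains more exonic sequence and is therefore
  the inclusion form.

Multi-way alternative boundaries are emitted as all pairwise events
sharing the common boundary; events are deduplicated by `(gene, type,
anchor)`; structurally identical transcripts are collapsed for enumeration
but all their ids are reported in the inclusion/exclusion sets. The whole
enumeration is validated in the test suite against an independent
brute-force oracle that checks every ordered transcript pair against the
definitions above (1000 random genes, both strands, set equality of
`(gene, type, anchor)` triples).

A note on symmetry: reflecting all coordinates *and* flipping the strand
label is an isometry of an annotation — transcription direction is
unchanged relative to the gene — so it preserves every event type.
Reflecting coordinates while *keeping* the strand swaps donor and acceptor
roles and hence maps A5 to A3 and back. The suite asserts both forms.

## PSI and differential splicing

PSI is the inclusion share of the event's isoform abundance (TPM); the
value is missing when the event's total abundance falls below `1e-9` TPM
(so 0/0 never silently becomes a number). A count-based path
`inc / (inc + exc)` exists alongside, because the significance test runs
on reads. Both paths are kept because abundance-based PSI is the standard
quantification while read counts carry the sampling noise the test needs.

Support filters mirror a two-stage screen:

* transcripts are retained iff they have >= 3 supporting reads in every
  replicate of **at least one** group. The all-groups reading is available
  (`scope = "all_groups"`); the per-group reading is the default because
  it is the one stated explicitly for events, and a transcript genuinely
  expressed in only the diseased tissue should survive the filter.
* events are discarded iff some group has <= 3 total reads in every
  replicate (note the asymmetry: a transcript at exactly 3 passes, an
  event at exactly 3 is discarded — both follow the respective rule's
  wording).

For a contrast (always `TREATvsCTRL`; delta PSI and log2FC are treatment
minus / over control), group PSI is the replicate mean, requiring >= 2
defined replicates per side. Significance: an exact two-sided binomial
test of the pooled treatment inclusion count against the pooled control
PSI as null proportion, clipped to [0.01, 0.99]. Two-sided means summing
the probabilities of all outcomes at most as likely as the observed one
(the standard construction, with the usual 1e-7 relative guard against
floating-point ties). Pooling replicates is this package's arrangement:
per-replicate tests would need an extra combination rule, and pooling
matches the test's read-count framing. No multiple-testing correction is
applied to event p-values by default (`adjust = TRUE` enables BH), since
the classification thresholds are stated on raw p.

Classification of significant events (|dPSI| > `dpsi_min` = 0.20, p <
`alpha` = 0.05): **gained** if the control PSI is outside
[`psi_low`, `psi_high`] = [0.05, 0.95] while the treatment PSI is inside;
**lost** mirrored; **DAS** otherwise. Group-mean PSI is used for the
extremity checks, not per-replicate unanimity. A 0.10 threshold variant
is occasionally quoted for this family of analyses; 0.20 is the default
here and the parameter is exposed, so either convention is one argument
away.

One calibration subtlety: the test treats the control PSI as a *fixed*
null proportion. Its false-positive rate is nominal (the suite checks
5% +/- 2 points over 2500 null events) when the null proportion is known;
if the control proportion were itself re-estimated from control reads of
similar depth, the implied variance would double and any exact binomial
test would reject far above nominal. At the default event depth
(~180 pooled reads per side) this inflation is material, so discovery
p-values from the pipeline should be read as comparative scores under the
stated null construction, not as calibrated against control resampling.

## Differential expression

The DE module is a deliberately transparent negative-binomial test rather
than a wrapper around a heavyweight framework: median-of-ratios size
factors (geometric-mean reference over genes expressed in all samples),
per-gene method-of-moments dispersion `alpha = (var - mu) / mu^2` averaged
over groups and clamped to [1e-8, 10], and a Wald statistic on the log2
fold change of normalized group means with pseudocount 0.5, using the
delta-method variance of a log mean under `var = mu + alpha mu^2`.
q-values are BH across all tested genes; DEGs need |log2FC| >= 2 and
q < 0.05. With three replicates the moment dispersion estimate is noisy
and the Wald p anti-conservative in the tail; the fold-change gate keeps
the realized false discovery rate low (the suite checks sensitivity >= 0.9
and empirical FDR <= 0.1 on 2000 genes with 100 planted at |log2FC| = 3,
and <= 7% BH calls under the null over 20 seeds). Shrinkage estimators,
GLM covariates and outlier handling are deliberately out of scope.

"Expressed" for subgenome summaries means mean normalized count >= 1
across all samples — a conventional floor; the published gene totals this
feeds imply some such unstated filter, and the threshold is exposed.

## Homoeolog pairing and bias

Pairs come from reciprocal best hits on a 12-column BLAST tabular table:
best cross-subgenome hit per gene by bitscore (ties: higher identity, then
lexicographically smaller subject), kept iff mutual with identity >= 90%
both ways; the result is 1:1 by construction. Sequence similarity is taken
as the hit table's percent-identity column; alignment itself is upstream
of this package.

Bias class per condition is determined solely by
`r = log2((mean_A + 1) / (mean_B + 1))` and an expression floor:
`low-expression` if both means < 1, else `A-bias` (r >= 1), `B-bias`
(r <= -1), or `balanced`. The cutoff |r| >= 1 (two-fold), floor 1 and
pseudocount 1 are this package's choices — the ratio itself is standard
but no canonical thresholds exist — and all three are parameters.
Transitions between two conditions are cross-tabulated over a gene subset
(by default pairs with a DEG member in the matching contrast, each pair
counted once even if both members are DEGs); `low-expression` pairs are
excluded from the table and reported separately, and percentages are over
the subset total, which is what makes printed `count/total` percentages
directly recomputable.

Subgenome DEG asymmetry uses a 2x2 chi-square (DEG vs non-DEG by subgenome
A vs B) *with* Yates continuity correction: the corrected statistic is the
one that reproduces published worked values from their printed counts,
which the acceptance suite verifies to +/- 0.01. Magnitude comparisons use
a Mann-Whitney U with average ranks; p is exact by enumeration for
n1 + n2 <= 20 (valid under ties) and a tie-corrected,
continuity-corrected normal approximation otherwise, two-sided as
`2 min(P(U <= u), P(U >= u))`.

## Integration

Spearman rank correlation (average ranks; p via the t transform, which is
approximate at small n — the suite cross-checks it against exact
permutation at n = 5 only loosely, while r itself must match brute-force
rank arithmetic to 1e-12) relates per-event dPSI to the host gene's
log2FC, per event type, requiring >= 10 pairs. Set overlaps report all
intersection and exclusive (Venn-region) cardinalities for up to four
gene sets. Term enrichment is the hypergeometric upper tail P(X >= k)
(over-representation convention) with BH across tested terms; terms with
fewer than 3 background genes or zero overlap are excluded from testing to
avoid diluting the correction, and GeneRatio is k/M (term-relative), not
k/n — worth noting when comparing to tools that report the latter.

## The synthetic generator

The generator emulates the *structure* of a two-subgenome disease
transcriptome at desk scale, with defaults chosen as the package's
standard study conditions:

* 120 genes per subgenome B, 10% surplus on A (`a_surplus`), 3
  chromosomes per subgenome, three groups (healthy AG, lesion-adjacent
  BG, lesion-core CG) x 3 replicates;
* 92 planted events, 23 per type: 20 gained, 20 lost, 32 DAS at
  |dPSI| = 0.4, 20 stable. Gained events sit at control PSI 0.98/0.02 and
  treatment 0.5; DAS events at (1 +/- 0.4)/2, keeping both sides inside
  (0.05, 0.95);
* 40 DEGs at |log2FC| = 3 (sign random), planted in the last group;
* 23 homoeolog pairs with planted bias transitions, dominated by gains of
  B-bias (8 balanced->B-bias vs 5 balanced->A-bias), planted at 4:1
  expression splits (|log2 ratio| = 2, comfortably past the classifier
  cutoff of 1);
* negative-binomial counts at dispersion 0.05 around group means from a
  log-normal baseline (meanlog log 300, sdlog 1), scaled to an expected
  library of 5e5 reads per sample; event read depths Poisson around 60
  (>= 30 with overwhelming probability), inclusion reads binomial at the
  planted PSI; transcript abundances split by the *realized* PSI so the
  abundance and count paths agree by construction.

All randomness derives from the config seed (annotation and expression use
distinct derived seeds), so a fixed config reproduces the bundle
byte-for-byte. Effects are planted only in the last group: the first two
groups share means, making `BGvsAG` a built-in negative control. The
truth ledger's pair classes are recomputed from the realized group means
rather than from the transition labels alone, because a planted DEG
inside an unplanted pair legitimately shifts that pair's class in the
shifted group — the ledger must stay truthful to the emitted data.

What the generator does **not** emulate: read-level artifacts (FASTQ,
alignment, positional bias), sequence content, batch effects, correlated
dispersion, isoform-length effects on TPM, partially paralogous
many-to-many homoeology, and annotation incompleteness. Passing recovery
tests therefore demonstrates the pipeline's correctness on data satisfying
its model assumptions, not robustness to the full mess of real RNA-seq.

Noise-free mode replaces every draw by its mean; it exists so that
classifier round-trips (bias classes, transitions, gained/lost/DAS in the
antisymmetry test) can be asserted *exactly* rather than within tolerance.

## Numerical choices and degenerate inputs

* PSI missing below 1e-9 total TPM; events need >= 2 defined replicate
  PSIs per side or are skipped for the contrast.
* Sample correlation uses pairwise-complete events, requiring >= 3
  complete pairs per cell (else the cell is NA).
* Binomial p0 clipped to [0.01, 0.99]; n = 0 yields an undefined p and the
  event is excluded.
* RBH ties broken by identity then lexicographic subject id, making the
  pairing deterministic.
* Chi-square with a zero marginal, Mann-Whitney with an empty sample, KS
  with < 10 defined PSI per group, and size factors with no
  always-expressed gene all raise explicit errors rather than returning
  NaN.
* Degenerate rank variance (constant isoform counts) flags the
  correlation result rather than erroring, since it arises naturally on
  small fixtures.

## Problem sizes used by the test suite

The suite validates enumeration on 1000 random genes against the
brute-force oracle, calibration on 2500 null binomial events and 20 null
DE seeds of 500 genes, DEG recovery on 2000 genes, and everything else on
the default 252-gene fixture; the full suite runs in well under a minute
on one core. These sizes were chosen to make sampling-based bounds (e.g.
5% +/- 2 points) statistically meaningful while keeping the suite quick.

## Pipeline and reports

`run_pipeline()` executes: support filters -> event catalog -> PSI ->
differential splicing -> differential expression -> pairing / bias /
transitions -> integration / enrichment, writing one TSV per report plus
`manifest.json` recording input MD5 hashes, thresholds, seed and package
version — and no timestamps, so a rerun on identical inputs is
byte-identical. Stage-level functions are all exported; the pipeline is a
thin, auditable composition of them.
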