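---
title: "Methods: TF peak enrichment around lncRNA transcription start sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TF peak enrichment around lncRNA transcription start sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question the package answers

Expression profiling (microarray, RNA-Seq) routinely produces sets of
co-expressed long noncoding RNAs (lncRNAs), and the natural follow-up question
is which transcription factors (TFs) could be driving that shared expression.
`lnctf` answers it by crossing ChIP-Seq peak lists — one per TF experiment,
tagged with TF name, cell line, species and dataset ID — with the promoter
windows of an annotated lncRNA universe, and asking, per experiment, whether
the user's lncRNA set contains significantly more TF-targeted members than a
random set of the same size would.

## Targeting model

A lncRNA feature (gene or transcript) counts as **targeted** by a dataset when
at least one peak overlaps its **regulatory region** by at least 1 bp. The
regulatory region is a strand-aware window around the transcription start site
(TSS): for an upstream extent $u$ and downstream extent $d$, the window covers
$[t-u,\; t+d]$ on the plus strand and $[t-d,\; t+u]$ on the minus strand
(1-based, inclusive), where $t$ is the TSS. Five presets are provided
(`2k1k`, `10k1k`, `20k1k`, `30k2k`, `50k5k`), with `2k1k`
($-2\,\mathrm{kb}/+1\,\mathrm{kb}$) the default working window.

Conventions worth making explicit, because they are where off-by-one bugs
live:

* GTF is parsed as 1-based inclusive (its native convention); all internal
  interval work, peak coordinates included, is 0-based half-open
  (BED-compatible). Overlap is `max(starts) < min(ends)`; an abutting peak
  does not target.
* The window includes the TSS base itself, so an unclamped window has length
  $u + d + 1$. Windows are clamped at chromosome position 1 on the left and
  never clamped on the right (GTF carries no chromosome lengths; running past
  the end is harmless for overlap).
* Peak strand is ignored: TF binding is double-stranded and ENCODE peaks carry
  `"."`. Only the lncRNA's strand matters, to orient the window.
* Any positive overlap counts — no containment requirement, no
  distance weighting, no nearest-gene assignment.
* Chromosome names match by exact string equality; peaks on chromosomes
  absent from the annotation silently contribute nothing.

**Gene-level targeting uses the "any transcript" union rule.** Annotated genes
have several transcripts and hence several TSSs; a gene is targeted when any
member transcript's window is hit. This is the permissive reading — the
gene-level result is a superset of each single transcript's — and it avoids
having to nominate a canonical TSS. Users who want per-TSS resolution run at
`level = "transcript"`.

## The enrichment statistic

For one dataset let $N$ be the universe size (all annotated lncRNA features,
or the user's reference set), $M$ the universe members targeted by the TF,
$n$ the validated input-set size, and $m$ the input members targeted. The
p-value is the upper tail of the hypergeometric distribution:

$$
P \;=\; \sum_{i=m}^{\min(n,M)}
\frac{\binom{M}{i}\binom{N-M}{n-i}}{\binom{N}{n}},
$$

the probability of seeing $m$ or more targeted input members if the input
were drawn at random, without replacement, from the universe. The
implementation sums term-by-term in log space (`lchoose` plus log-sum-exp),
so deep tails do not underflow; $m=0$ returns exactly 1, and $P=0$ cannot
occur (the sum always contains its leading positive term), so no epsilon
flooring is applied.

Alongside $P$ each output row carries the expected hit count
$\mathrm{Expected\_H} = n \cdot M / N$ and the odds ratio

$$
\mathrm{OR} \;=\; \frac{m/(n-m)}{M'/(N-M')}, \qquad M' = M,
$$

read as a ratio of odds (input odds of being targeted over background odds).
Degenerate cases map to sentinels rather than errors: $m=n$ with an
informative background gives $\infty$ (printed `Inf`), $m=0$ gives 0, and a
degenerate background ($M=0$ or $M=N$) gives `NA`.

**Multiple testing.** Raw p-values are adjusted by the Benjamini–Hochberg
step-up procedure across *all datasets scored in one run* — that run is the
family. Nothing else is defensible for an interactive query: the set of
experiments the user scores (one cell line, or everything in the manifest) is
exactly the set of hypotheses entertained. A dataset is flagged a **common
TF** of the input set when its adjusted p-value is at or below the threshold
(default 0.05).

**Reference sets.** When the measurable universe is smaller than the
annotation — say, the lncRNAs detectable on one array — the user supplies it
as a reference set, and every count ($N$, $M$, $n$, $m$) is taken within it.
Input IDs outside the reference are intersected away with a warning rather
than an error, since the reference defines what could have been observed.

**ID handling.** Input resolution tries exact IDs first, then names;
ambiguous names (one name, several IDs) are an error that lists the
candidates. Ensembl-style version suffixes (`.7`) are stripped on both sides
by default. Duplicate inputs are deduplicated with a message; unknown inputs
are dropped with a warning, and the run aborts only when nothing remains.

## Retrieval panels

`lncrnas_targeted_by()` (TF → lncRNAs) and `tfs_targeting()` (lncRNA → TFs)
are both computed from the same target map as the enrichment, so the two
panels are exact transposes by construction; the test suite verifies the
transpose property exhaustively on fixtures.

## What the synthetic fixtures emulate

`fixture_spec()`/`generate_fixture()` build a toy genome with known ground
truth, deterministically from a seed:

* Genes occupy non-overlapping slots spaced further apart than any window
  extent plus one peak width, so every peak's targeting status is
  unambiguous and the generator can compute the truth table by direct
  arithmetic, independent of the overlap machinery it is used to test.
* All transcripts of a gene share the gene's TSS (3' ends vary), so truth is
  consistent across gene and transcript level. The union rule for genuinely
  multi-TSS genes is exercised by hand-built annotations in the unit tests
  instead.
* Null datasets place fixed-width peaks (default 200 bp) uniformly over the
  chromosomes. A planted dataset places one peak inside the window of each
  selected gene: foreground genes with probability 0.8, background genes with
  probability 0.1 by default, mirroring a TF that genuinely co-regulates the
  foreground.

The fixtures deliberately do **not** emulate realistic ChIP-Seq signal:
peak-width and signal distributions, GC and mappability bias, clustered
binding, promoter CpG structure, or correlated TF occupancy. Passing tests
therefore demonstrate correctness of the counting, overlap and inference
machinery under the stated model — not robustness of the biology to those
real-data complications.

## Calibration and power checks: the problem sizes used

Two statistical properties are verified on synthetic studies:

* **Null calibration** runs at the scale of the human lncRNA annotation —
  13,249 genes — with 20 null datasets of 12,000 uniform peaks (about 25%
  promoter coverage, comparable to a promiscuous ENCODE factor) and random
  input sets of 800–1,200 genes, 50 per batch, 10 seeded batches. The
  hypergeometric p-value is discrete and strictly super-uniform under the
  null, so "approximately uniform raw p-values" is only a meaningful check
  when the hit-count support is fine; at annotation scale the input hit count
  has standard deviation ≈ 13 and the largest pmf atom is ≈ 0.03, small
  enough for a pooled Kolmogorov–Smirnov check at $\alpha = 0.01$. At toy
  scale (a 1,000-gene universe) the same check fails for *any* correct
  implementation, purely from discreteness — we verified that the empirical
  p-value distribution matches the exact discrete null CDF there. The flagged
  fraction under the null is also required to stay at or below the nominal
  0.05 (it is far below, since discrete super-uniformity makes BH
  conservative).
* **Planted-signal recovery** uses the small-study setting: a 1,000-gene
  universe, five null datasets, and a planted dataset hitting 80% of a
  50-gene foreground versus 10% of the background. Across 200 seeded
  replicates the planted dataset must rank first and be flagged common in at
  least 95% (observed: 100%; the planted p-values are astronomically small,
  median BH p ≈ 1e-27).

These sizes keep the full test suite and the acceptance script within a few
minutes on one CPU while leaving the checks statistically sharp.

## Numerical and design choices

* `bh_adjust()` delegates to `stats::p.adjust(method = "BH")`; the test suite
  holds it against an independently hand-written step-up.
* Interval overlap delegates to `GenomicRanges::findOverlaps()` behind the
  package's index API; tests hold it against a naive all-pairs scan,
  including engineered abutting-boundary cases.
* Enrichment rows are sorted by adjusted p, then raw p, then dataset ID — a
  total, deterministic order; two identical runs produce byte-identical
  output TSVs.
* Output formatting: 6 significant digits, `Inf` for infinite odds ratios,
  `NA` for undefined ones.
* The GTF reader is trusting about biotypes by default (the supplied GTF
  defines the universe) and strict about structure: malformed lines are
  errors naming the line, and a transcript or gene spread across chromosomes
  or strands is a parse error, not a silent repair.

## Known limitations

* No peak calling, replicate merging or IDR — peak lists are taken as given.
* No GFF3 dialect, no FASTA/sequence handling.
* Gene-level input assumes the union-over-transcripts reading of "the" TSS;
  the original interactive tool's behaviour for multi-TSS genes is not
  documented, so results at gene level may be more permissive than a
  canonical-TSS convention.
* The BH family is the single run; scoring the same input repeatedly against
  many manifests and cherry-picking is the user's multiplicity to own.
* Enrichment against a background of uniformly placed peaks is a weak null
  for real data, where promoter regions are peak-dense; the reference-set
  mechanism (e.g. all expressed lncRNAs) is the supported mitigation, not a
  matched-background correction.
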