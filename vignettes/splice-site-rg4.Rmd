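---
title: "Scoring RNA G-quadruplex propensity around cassette-exon splice sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring RNA G-quadruplex propensity around cassette-exon splice sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question and the model

Mammalian cells modulate alternative splicing within the physiological
temperature range, and RNA G-quadruplexes (rG4s) — four-stranded structures
built from stacked guanine tetrads — are plausible sequence-encoded
thermosensors: they fold more stably at lower temperature, and a folded rG4
sitting on or next to a splice site can limit its accessibility. If that
mechanism is widespread, exons that are *repressed* in the cold should carry
more rG4-forming sequence around their splice sites than exons that are
cold-*induced* or temperature-insensitive.

`rg4splice` implements the sequence-level side of that question as a
reusable pipeline:

1. **Classification.** For a cold/warm contrast, each skipped-exon event is
   summarised by $\Delta\mathrm{PSI} = \overline{\mathrm{PSI}}_{cold} -
   \overline{\mathrm{PSI}}_{warm}$. Events are filtered to mean
   $\mathrm{PSI} \in (0.05, 0.95)$ and cassette length $> 20$ bp, tested
   per event, BH-adjusted within the contrast, and called cold-repressed
   (CRE, $\Delta\mathrm{PSI} \le -0.1$, adjusted $p < 0.05$), cold-induced
   (CIE, $\Delta\mathrm{PSI} \ge +0.1$, adjusted $p < 0.05$) or
   non-temperature-sensitive (NT). Filter failures are `excluded`, so the
   four labels partition every event.
2. **Windows.** Each event defines four splice-site anchors in transcript
   orientation — USS5 (upstream donor), SS3 (cassette acceptor), SS5
   (cassette donor), DSS3 (downstream acceptor). Composition and motif
   statistics use the 50-base $-25..+25$ window at each anchor; G4Hunter
   scanning uses $\pm 200$ base flanks.
3. **Scoring.** Three complementary scores: G content; presence of the
   canonical quadruplex motif $(\mathrm{G}_{\ge 3}\,\mathrm{loop}_{1-7})_3\,
   \mathrm{G}_{\ge 3}$; and G4Hunter, where a base in a run of $k$ G scores
   $+\min(k,4)$, a base in a run of $k$ C scores $-\min(k,4)$, others 0,
   averaged over 25-base sliding windows.
4. **Statistics.** G content is compared between categories by two-sided
   Wilcoxon rank-sum tests; motif proportions by one-sided hypergeometric
   over-representation tests; both families are BH-adjusted. Per-position
   window scores are correlated with $\Delta\mathrm{PSI}$ across events
   (Spearman by default), and per-event maxima over the SS3/SS5 flanks
   yield the "predicted rG4" call (max window score strictly $> 1$).
5. **rG4-seq profiles.** Independent experimental support comes from
   reverse-transcriptase-stalling (RTS) peaks: per junction-relative
   position from $-200$ to $+200$ the pipeline counts events overlapping
   at least one peak (smoothed with a 30-nt window) and accumulates RTS
   values per category.

## Conventions and tunable parameters

| parameter | default | meaning |
|---|---|---|
| `delta_threshold` | 0.1 | inclusive $|\Delta\mathrm{PSI}|$ call threshold |
| `alpha` | 0.05 | strict BH-adjusted p threshold |
| `psi_min`, `psi_max` | 0.05, 0.95 | open bounds on mean PSI |
| `min_length` | 20 bp | strict lower bound on cassette length |
| `window` | 25 bp | half-width of composition/motif windows |
| `flank` | 200 bp | half-width of scanning flanks |
| `w` | 25 bp | G4Hunter window width |
| `g4_threshold` | 1 | strict threshold for the rG4 call |
| `smooth` | 30 nt | RTS metaprofile smoothing window |

Coordinates are 0-based half-open (BED convention) throughout. A window's
relative coordinates run $-h..-1$ then $+1..+h$ with no position 0: the
anchor of a half-open exon boundary sits *between* two bases, which makes
the $-25..+25$ window exactly 50 bases. For a plus-strand SS5, position
$+1$ is the first intronic base. Minus-strand events are reverse
complemented into transcript orientation before any scoring, so all
downstream code is strand-blind.

Decisions taken where conventions were genuinely open:

* **PSI filter on the mean.** The $(0.05, 0.95)$ filter is applied to the
  mean PSI over all samples of the contrast (a `psi_filter = "per_sample"`
  switch applies it to every sample instead).
* **Inclusive ΔPSI boundary.** Thresholds are inclusive
  ($\le -0.1$, $\ge +0.1$); because condition means are computed in
  floating point, the comparison carries a $10^{-9}$ tolerance so an exact
  boundary case (e.g. $0.4 - 0.5$) is not lost to representation error.
* **Per-event test.** The natural per-event test is the splicing caller's
  likelihood-ratio test, consumed via `method = "external"` (an
  rMATS-style SE table is parsed by `read_rmats_se()`). When only
  replicate PSI values are available, Welch's t test (default) or an exact
  Mann-Whitney test substitutes — a deliberate, documented substitution,
  not a re-implementation of the caller.
* **Motif loops are G-free.** The canonical motif's loops are restricted
  to 1–7 *non-G* bases. This makes the left-greedy longest match at a
  position unique and lets the scanner be verified against exhaustive
  substring enumeration; the `g4_motif()` definition (run length, loop
  bounds, run count) is fully configurable so an alternative catalogue can
  be swapped in.
* **Window-score anchoring.** The G4Hunter window score is assigned to the
  window *start* ("searched starting at each base"); `assign = "center"`
  is available for plotting.
* **Hypergeometric population.** Motif enrichment is tested pairwise (CRE
  vs NT, CRE vs CIE) with the union of the two groups as the population,
  mirroring the two reported contrasts; sidedness is one-sided
  over-representation.
* **Correlation flavour.** Spearman by default — window scores are
  heavily skewed and zero-inflated — with Pearson by flag. Zero-variance
  positions return `NA` ("undefined"), never 0.
* **Smoothing edge rule.** The 30-nt moving average shrinks its window at
  the profile edges rather than zero-padding, avoiding artificial decay at
  $\pm 200$; `w = 1` is the identity.
* **Out-of-bounds windows are dropped,** never N-padded, so composition
  statistics are not diluted; every drop is counted and reported.

## The synthetic-data generator

Real inputs to this analysis are alignment-scale (RNA-seq, a splicing
caller, rG4-seq peak calls), so the package ships a generator that
emulates the *statistical structure* those inputs deliver, with full truth
labels:

* an i.i.d. background genome at a configurable GC fraction (default 0.4);
* sequentially placed exon trios on both strands, with intron lengths
  $\ge 2 \times$ flank so the $\pm 200$ windows of distinct events never
  collide (enforced by construction, not rejection sampling);
* replicate PSI values from a clamped Gaussian around planted condition
  means — warm mean `psi_base` (0.5), cold mean shifted by
  `delta_effect` (0.3, the conventional magnitude of a clear splicing
  switch) for CRE/CIE, replicate noise sd 0.05, 4 replicates per
  condition, 100 events per category;
* canonical G4 elements overwritten into the $-25..+25$ windows of the
  cassette splice sites at category-dependent rates (default CRE: 0.6 at
  SS5, 0.3 at SS3; CIE/NT: 0.05), written on the sense strand and
  reverse-complemented into genome coordinates for minus-strand events;
* RTS peaks of 15–40 bases placed in CRE cassette flanks with probability
  0.8, log-normal RTS values, plus a uniform background of 0.05 peaks/kb.

Everything derives deterministically from one seed, and identical
configurations produce byte-identical files.

What the generator does **not** emulate — and therefore what passing tests
do not show about real data: realistic splice-site consensus sequences and
base composition gradients, expression-dependent PSI estimation noise
(noise here is homoscedastic), correlated events on shared genes,
multi-exon splice graphs, and rG4-seq artefacts such as coverage bias.
Recovering planted effects demonstrates that the machinery measures what
it claims to measure, not that any particular biological effect exists.

## Numerical and degenerate-input behaviour

Base scores are integers, so the running-sum window mean is exactly equal
to the direct per-window mean (no floating-point drift; the test suite
asserts identity, not tolerance). Sequences shorter than the window are
scored as a single whole-sequence window — needed for short
oligonucleotide controls such as the 22-nt G-rich hairpin used for
in-vitro structure work. `N` bases score 0, break G/C runs, count in the
G-content denominator, and propagate through extraction unchanged. Welch's
test with zero variance on both sides returns $p = 1$ for equal means and
$p = 0$ otherwise. Empty PSI tables, unknown condition labels,
out-of-range probabilities and inconsistent hypergeometric counts all fail
fast with typed messages ("input error", "configuration error", "sizing
error"), which the command-line wrapper maps to exit code 2.

## Problem sizes and verification

The test suite verifies each scoring primitive against an independent
oracle (brute-force window means over 1000 random sequences of length
1–500; motif matches against regex and exhaustive substring enumeration;
exact rank-permutation and draw-enumeration p-values at $n = 3,3$ and
$N = 10$), checks strand symmetry on mirrored fixtures, and runs the
end-to-end pipeline on generated datasets of 100 events per category —
large enough for planted effects of the configured size to be recovered
reliably, small enough that a full run takes seconds. Null-fixture runs
(equal planting rates everywhere) over 20 seeds check that enrichment
p-values are calibrated. `scripts/acceptance.R` regenerates the headline
numbers of such a run from scratch.

## Limitations

The package scores sequence propensity; it does not predict folding
thermodynamics, model probing chemistry, or call RTS peaks from reads.
Events and peaks must share one genome assembly. Only single skipped-exon
events are modelled; other event classes (A5SS, A3SS, MXE, RI) are out of
scope. The canonical motif stands in for any richer curated catalogue;
swap in an alternative via `g4_motif()` if one is available.
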