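# rg4splice

Sequence-level analysis of RNA G-quadruplex (rG4) propensity around the
splice sites of temperature-sensitive cassette exons.

## The problem

Small, physiological temperature shifts change alternative splicing.
rG4s — four-stranded structures of stacked guanine tetrads — fold more
stably in the cold and can occlude a splice site, making them candidate
sequence-encoded thermosensors. The testable sequence-level prediction: if
rG4s repress exons at low temperature, **cold-repressed exons (CREs)
should carry more rG4-forming sequence around their splice sites** than
cold-induced (CIE) or non-temperature-sensitive (NT) exons.

`rg4splice` is for transcriptomics analysts who have (a) a genome FASTA,
(b) skipped-exon event coordinates, (c) a per-replicate PSI table for a
cold/warm contrast (an rMATS-style SE table is parsed directly), and
optionally (d) rG4-seq reverse-transcriptase-stalling (RTS) peaks — and
want the full chain from exon classification to enrichment statistics and
metaprofiles.

## What it computes

* **Classification** — per event, ΔPSI = mean PSI(cold) − mean PSI(warm);
  after filtering to mean PSI ∈ (0.05, 0.95) and cassette length > 20 bp,
  events with BH-adjusted p < 0.05 are called CRE (ΔPSI ≤ −0.1) or CIE
  (ΔPSI ≥ +0.1); the rest are NT.
* **Windows** — strand-aware −25..+25 windows at the four splice-site
  anchors of each exon trio (USS5, SS3, SS5, DSS3) and ±200 scanning
  flanks, in transcript orientation.
* **Scores** — G content; canonical G4 motif
  `(G≥3 loop1–7)×3 G≥3`; G4Hunter (bases in runs of k G score +min(k,4),
  C runs −min(k,4), others 0; 25-bp sliding-window means).
* **Statistics** — two-sided Wilcoxon tests on G content, one-sided
  hypergeometric motif over-representation, BH adjustment; per-position
  Spearman correlation of window scores with ΔPSI; fraction of events with
  max SS3/SS5 window score > 1 ("predicted rG4"); RTS overlap counts
  (30-nt smoothed) and cumulative RTS per category.
* **Synthetic data** — a seeded generator producing genome, events, PSI
  and peaks with planted, truth-labelled effects, so the whole pipeline is
  testable offline.

## Worked example

```r
library(rg4splice)

cfg <- synth_config(seed = 42,
                    n_events_per_category = c(CRE = 40, CIE = 40, NT = 40))
fx  <- synth_fixture(cfg, "demo_fixture")          # writes FASTA/TSV/BED
run <- run_pipeline(run_config(fx$genome, fx$events, fx$psi, fx$peaks,
                               seed = 42))
run
```

```
Splice-site rG4 analysis run
  events: 120 in, 0 excluded | CRE 40, CIE 40, NT 40
  CRE with predicted rG4 (max SS3/5 score > 1): 20/40 (50.0%)
  config hash: c868d08cf5f7ea8c3808a6f49212cfcb
```

The planted categories are recovered (40/40/40), and half of the CREs get
a predicted-rG4 call — the generator plants canonical G4 elements at 60%
of CRE cassette donors versus a 5% background. `summary(run)` shows where
the signal sits; the SS5 rows carry it, the control regions do not:

```
 region   contrast           test statistic  p_value effect n1 n2    p_adj
   SS5   CRE vs NT        wilcoxon      1118 2.20e-03  0.070 40 40 0.017631
   SS5   CRE vs NT  hypergeometric        16 2.56e-05  0.188 40 80 0.000103
   USS5  CRE vs NT  hypergeometric         0 1.00e+00  0.000 40 80 1.000000
   DSS3  CRE vs NT        wilcoxon       799 9.96e-01  0.000 40 40 0.996141
```

Here `effect` is the median G-content difference (Wilcoxon rows) or the
motif-proportion difference (hypergeometric rows). `plot(run, region =
"SS5")` draws the category-mean G4Hunter profile around the cassette
donor; `run$correlation` holds the per-position score–ΔPSI correlations
(negative near the SS5 junction when planted G4s force cold exclusion),
and `run$rts` the RTS metaprofiles.

A thin command-line wrapper covers the same stages
(`fixture`, `classify`, `extract`, `score`, `enrich`, `rts`, `run-all`):

```sh
Rscript $(Rscript -e 'cat(system.file("cli/rg4splice.R", package="rg4splice"))') \
    run-all --genome demo_fixture/genome.fa --events demo_fixture/events.tsv \
    --psi demo_fixture/psi.tsv --peaks demo_fixture/peaks.bed --out-dir out
```

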