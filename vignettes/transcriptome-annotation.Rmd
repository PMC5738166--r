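---
title: "Annotating a noncoding transcriptome from binned coverage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating a noncoding transcriptome from binned coverage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncunits)
```

## The problem

Compact fungal genomes transcribe far more than their annotated
protein-coding genes: long intergenic noncoding RNAs (lincRNAs) and natural
antisense transcripts (NATs) are abundant, short, weakly expressed and
mostly absent from reference annotations. `lncunits` detects and classifies
these transcripts from coverage data alone — pooled RNA-seq, RNA polymerase
II (RNAPII) ChIP-seq, polysome-fractionation RNA-seq and strand-specific
RNA-seq — without any read alignment of its own, and validates every stage
against synthetic genomes with planted truth.

## The transcription model

The genome is tiled with non-overlapping 50 bp bins. For bin $i$ the binary
response $\pi_i$ ("coding indication") is modeled as
$\mathrm{Binomial}(n_i, \pi_i)$ with $n_i = 1$ and

$$\mathrm{logit}(\pi_i) = \beta_0 + \beta_1\,t(x_{i,\mathrm{rna}}) +
  \beta_2\,t(x_{i,\mathrm{Pol}})$$

fitted by `stats::glm` (binomial family, IRLS, convergence tolerance
$10^{-8}$, at most 50 iterations) on a uniformly random, seeded 60% of the
genome's bins. Perfect separation is tolerated: the capped fit is returned
with a `separation` flag. Aliased covariates (e.g. a constant track) get
coefficient 0, matching `predict.glm`.

Modeling choices worth stating explicitly:

* **Response labeling.** A bin is labeled 1 when it overlaps an annotated
  exon by at least 1 bp. Exon coverage is what RNA-seq measures; introns
  are short here (median 69 bp), so gene-body labeling would differ little.
  Per-strand fits label against genes of one strand only.
* **Covariate transform.** Default `log1p_cpm`,
  $t(x) = \ln(1 + 10^6 x/N)$ with $N$ the library size. Raw bin counts are
  heavy-tailed across four orders of magnitude; a log-scale covariate keeps
  the linear predictor well-conditioned, and the transform is recorded in
  the fitted object (`identity` and `log1p` are available).
* **Cutoff semantics.** The ln-ratio cutoff 1.5 is a threshold on the
  fitted linear predictor — the log-odds *is* the natural-log ratio
  $\pi/(1-\pi)$. The inequality is strict; a bin scoring exactly 1.5 is
  sub-threshold. The error term in the printed formula is the implicit
  Bernoulli noise; no extra dispersion parameter is estimated.
* **The additive stranded floor.** For strand-specific calls a bin must
  also carry at least 10 raw reads in the 50 bp bin, which suppresses
  spurious antisense from the per-strand background.

Maximal runs of super-threshold bins become transcription units; unit
counts are the sums over member bins, normalized to counts-per-million and
per kilobase of unit length (the scale constant $10^6$ is a package
convention; only ratios of normalized values matter downstream).

## Classification stages and their thresholds

| Parameter | Default | Meaning |
|---|---|---|
| bin width | 50 bp | classification element |
| cutoff | 1.5 | log-odds threshold, strict `>` |
| training fraction | 0.6 | random bins used in the GLM fit |
| intergenic distance | 500 bp | minimum gap from a gene for a lincRNA candidate |
| merge gap | 100 bp | lincRNA segments closer than this are merged |
| stranded read floor | 10 reads/bin | eligibility for per-strand calls |
| antisense-only rule | sense < 1, antisense > 1 reads/bin | in every dataset |
| fold-change threshold | 2.0 | light induction, strict `>`, any time point, all datasets |
| junction cutoff | 25% quantile | of annotated-intron read support |
| spliced-read floor | 10 | junction-in-feature counting |

Distance between a unit and a gene is the gap between closest boundaries
(adjacent intervals have gap 0), so "at least 500 bp distant" means gap
$\ge 500$. The polysome threshold is the median (even-sized sets: mean of
the central pair) of length-normalized polysome coverage over coding units;
candidates strictly above it are set aside as possibly translated, and an
external per-record coding-potential flag (the assessment itself is out of
scope) decides whether they are recovered into the catalog or reported as
possibly coding. Junction classification precedence is perfect >
alternative > weak > novel, each junction compared against *all* annotated
introns; "weak" means both ends within ±10 bp of one intron with neither
end exact (the tolerance is configurable — the boundary between weak and
novel has no canonical value). Quantiles interpolate linearly between order
statistics (R's default type 7). Reported percentages round half away from
zero to the printed precision.

The antisense 5′ start is the unit boundary that is 5′ on the antisense
strand; offsets to the sense TSS/TTS are signed positive downstream in the
sense gene's orientation. The neighbor-distance filter removes an antisense
call when its span overlaps or lies within 500 bp of a *different* gene on
the antisense strand — that gene's own transcription explains the signal.
The filter deliberately ignores neighbors on the sense strand, whose
transcription cannot masquerade as antisense signal in a stranded library.

For the rank-index profiles, the smoothing window is chosen from the curve
of the total variation (sum of absolute successive differences, SAD) of the
smoothed series: the smallest candidate window whose relative SAD decrease
to the next candidate falls below 5% (an elbow rule; the curve itself is
always returned). Edge windows truncate to the available neighbors. Note a
consequence of truncation: smoothing monotone data no longer preserves SAD
exactly (the first and last smoothed values move toward the interior mean),
so the guaranteed invariant is $\mathrm{SAD}(\mathrm{smoothed}) \le
\mathrm{SAD}(\mathrm{raw})$, which the tests assert.

Liftover between assembly versions supports identity, whole-chromosome
reverse complement ($s,e \mapsto L-e+1, L-s+1$) and segment reverse
complement ($s,e \mapsto a+b-e, a+b-s$ inside $[a,b]$). Both operations are
involutions, flip strands and preserve lengths; an interval straddling a
segment boundary has no well-defined image and errors rather than splits.
The default map (`nc10_to_nc12_map()`) encodes chromosomes 1–5 identical,
the chromosome 6 segment 1,847,027–2,788,223 reverse complemented, and
chromosome 7 (4,255,303 bp, recovered from the conversion endpoint equations)
reverse complemented as a whole.

## What the synthetic generator emulates — and what it does not

`sim_config()` defaults describe a ~2 Mb, 4-chromosome genome with 200
coding genes (length median 1782 bp, 80% spliced, intron median 69 bp), 40
planted lincRNAs (median 551 bp, 1.6% spliced), 30 planted antisense
transcripts (median 251 bp, 2.5% spliced, 5′ starts jittered around the
sense TTS) plus 10 antisense-only hosts, a light time course at 0/30/60/120
min with ~30% of noncoding features induced 3–8×, polysome signal over
coding features only, and negative-binomial bin counts.

The expression structure deserves its own explanation, because it is where
naive choices fail. The logistic classifier is trained with annotated exons
as the positive class, which makes every *planted noncoding feature a
mislabeled negative*. Two consequences follow:

1. The fitted 1.5-log-odds crossing sits at roughly
   $\mathrm{bg}^{1/4}\,m^{3/4}$ reads per bin, where $\mathrm{bg}$ is the
   background mean and $m$ the coding expression median — i.e. the
   detection floor is anchored between background and typical coding
   levels, pulled down by the weakly expressed genes in the training set.
2. If the noncoding features all sit in a narrow expression band, their
   concentrated label-0 density locally outweighs the coding density and
   the fitted boundary moves *onto the band*: the classifier carves out
   exactly the features one hopes to detect, at any sequencing depth.

Real transcriptomes do not have this pathology because noncoding expression
is spread over the same broad range as coding expression. The generator
therefore gives coding genes a lognormal spread over orders of magnitude
(sdlog 1.0, median 60 reads/bin; 5% of genes silent), and noncoding
features a broad lognormal (sdlog 0.6) truncated below at 40 (lincRNA) or
50 (antisense) reads/bin over backgrounds of 0.5 (unstranded) and 0.25 per
strand — above the detection floor, but diluted enough that no band forms.
Antisense features get the slightly higher floor because at 50 bp
resolution a 5-bin feature tolerates no fragmentation under the
reciprocal-overlap recovery criterion. Paired antisense is planted only on
hosts expressed above the stranded detection floor, since a sense/antisense
pair is only defined where the sense partner is itself detected; silent
hosts are exercised separately through the antisense-only path. Bin-level
dispersion is mild (NB size 50) because feature-to-feature variability is
modeled separately by the expression distributions — stacking strong
overdispersion on top of it would double-count biological variance.

What passing tests on this generator do show: the pipeline's rules are
implemented correctly, the stages compose, and planted features in the
detectable regime are recovered with precision and recall ≥ 0.9 at
reciprocal overlap 0.5. What they do not show: performance on real data
with mappability artifacts, transcript-boundary ambiguity, overlapping gene
models, or noncoding features below the detection floor — the generator
plants none of these, by construction.

## Numerical and degenerate-input conventions

* Strict inequalities at every threshold (cutoff, polysome filter,
  fold change); ties stay on the conservative side.
* Read placements are assigned to exactly one bin — the one containing the
  5′-most mapped base (the `end` coordinate on the minus strand) — so
  boundary-spanning reads are never double-counted and bin counts are
  conserved.
* Coordinates are 1-based inclusive internally; BED I/O converts to 0-based
  half-open at the boundary.
* Induction timing is the argmax over the time course, ties broken toward
  the earlier time point; "early" means peak at 30 min.
* Empty inputs return empty, typed results (no calls, NA precision) rather
  than errors; genuinely undefined requests (polysome threshold with no
  coding units, junction cutoff with no annotated match, liftover across a
  segment boundary) error with a message naming the problem.
* Chromosomes without genes classify their units as intergenic candidates
  (there is no neighbor to measure a distance to).

## Problem sizes used by the test suite

The suite fits the classifier on 40,000-bin genomes (2 Mb at 50 bp),
checks coefficient recovery on 50,000 simulated bins against 3 standard
errors, verifies the junction classifier against a brute-force all-pairs
oracle on 200-junction instances, and round-trips 10,000 random intervals
through the liftover. These sizes were chosen so that each statistical
check has enough resolution to fail informatively while the whole suite
stays interactive.

## Known limitations

* The classifier inherits the annotation's biases: unannotated *coding*
  genes are scored like lincRNAs, and mislabeled training bins flatten the
  logistic transition (see above). Any detector trained on
  annotation-derived labels shares this property.
* The polysome filter is a median-threshold heuristic; no false-discovery
  control is attempted for it.
* Coding-potential assessment, homology search and read alignment are
  consumed as external inputs, never computed.
* The 500 bp neighbor filter is binary; a probabilistic deconvolution of
  overlapping transcription would be strictly more powerful.
* The liftover handles exactly the three relation types above; it is
  not a general chain-file engine.
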