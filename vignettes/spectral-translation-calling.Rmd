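---
title: "Calling active translation by spectral coherence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling active translation by spectral coherence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribospec)
```

## The signal and the model

Elongating ribosomes step codon by codon, so the P-sites of
ribosome-protected fragments aligned to an actively translated region pile
up with a period of exactly three nucleotides. Untranslated RNA that is
merely bound or degraded shows no such phasing. `ribospec` quantifies the
strength of this tri-nucleotide periodicity as the *spectral coherence*
between the observed coverage and an idealized period-3 reference, and
turns it into an FDR-calibrated translation call.

For a region with coordinate set $C$ (built from the transcript's exon
structure; for coding transcripts the CDS, anchored at the start codon),
P-site-adjusted read positions are tallied into a count vector, then
normalized by the position of highest coverage so values run from 0 to 1.
The normalized coverage $R$ is scanned in sliding windows of $N$
nucleotides (default 30) advanced by $L$ nucleotides (default 3). For each
window starting at $m$ the magnitude-squared coherence

$$\mathrm{Coh}(j) \;=\; \frac{|\bar P_{xy}(j)|^2}{\bar P_{xx}(j)\,\bar P_{yy}(j)}$$

is evaluated at the codon frequency $j = 1/3$ cycles per nucleotide
between the windowed coverage and an idealized $(1,0,0,1,0,0,\dots)$
signal $S$ of the same length, and the region's score is the mean over the
$M = \lfloor(|C|-N)/L\rfloor + 1$ windows:

$$\mathrm{Spec}_{RS,j} \;=\; \frac{1}{M}\sum_{m} \mathrm{Coh}_{R_{m,m+N}S_N,\,j}.$$

Spectral powers are estimated by Welch's method *within* each window:
overlapping mean-subtracted segments (default 12 nt, overlap 6 nt, so four
segments per default window), DFT per segment, cross- and auto-power
averaged across segments. This nesting is deliberate: the coherence of two
deterministic sequences estimated from a single unsegmented window is
identically 1 and carries no information, whereas averaging over segments
measures the *phase consistency* of the codon-frequency component across
the window — translated coverage keeps a stable phase, noise does not.
Because two deterministic pure signals are mutually coherent at any
relative phase, a window's coherence responds to the regularity of the
phasing rather than to which frame carries it; frame identity is still
tracked by anchoring the reference to the region's first coordinate (the
annotated start codon for CDS regions) and advancing its phase with $m$,
so all windows probe one absolute frame.

Numerical choices worth knowing:

* Window and segment lengths must be divisible by 3, so the codon
  frequency falls exactly on DFT bin `segment_length/3` — no
  interpolation, no leakage correction needed.
* Segments are mean-subtracted and untapered (rectangular). The target is
  a single known frequency; at any nonzero bin the DFT is invariant to the
  segment mean, and tapering would only trade resolution the method does
  not need.
* Coherences are clamped to $[0,1]$ against round-off; windows whose
  coverage has numerically zero power at the codon bin (e.g. empty or
  constant coverage) contribute coherence 0 and are flagged degenerate.
  A region shorter than one window, or with no coverage at all, is
  reported unscorable with a reason rather than a number.
* A vectorized path computes all window/segment DFTs in one matrix
  product; an independent straight-line reimplementation in the test suite
  pins both to $10^{-9}$ agreement.

## From scores to calls

Scores from one library are calibrated against themselves, stratified by
abundance: protein-coding regions at or above an FPKM cutoff (default 5)
form the "active" sample, regions below it (or, optionally, annotated
non-coding regions) the empirical null. The translation threshold is the
empirical $(1-\mathrm{fdr})$ quantile of the null scores — per-comparison
false-positive control on the empirical null, with a Benjamini-Hochberg
variant deliberately left out of scope of the default path because the
threshold line drawn on score tracks is the quantity users act on. The
boundary is inclusive: a score exactly at the threshold is called
translated.

The posterior probability that a region is translated is the two-class
Bayes rule $f_a(s)\pi / (f_a(s)\pi + f_n(s)(1-\pi))$ with $\pi$ the
empirical active fraction and $f_a, f_n$ Gaussian kernel density estimates
fit on the logit of the scores (scores are bounded in $[0,1]$; the logit
transform with a Jacobian correction avoids boundary bias). Bandwidths use
the Sheather-Jones plug-in, falling back to Silverman's rule for
degenerate samples; densities are floored at $10^{-10}$ so a score outside
both supports returns the prior rather than 0/0. Kernel densities were
chosen over binned histograms for smoothness of the per-window posterior
track; far outside the data's support the posterior therefore relaxes to
the prior — a property to keep in mind when reading tracks over very
extreme scores.

## Comparators

Two published alternatives are bundled for benchmarking. **FLOSS** scores
a region by the total-variation distance between its fragment-length
distribution (default range 20-40 nt) and a reference pooled from
annotated coding CDS regions; extreme outliers are flagged per read-depth
bin by a Tukey fence ($Q_3 + 3\,\mathrm{IQR}$, monotonized across bins).
**ORFscore** is the signed $\log_2$-scaled chi-square statistic of P-site
counts across the three codon frames, negated when an off-frame count
exceeds the annotated frame; the first and last codons are excluded by
default because initiating and terminating ribosomes accumulate there.
Both metrics are benchmarked by ROC/AUC (midrank Mann-Whitney statistic)
over a series of FPKM cutoffs, or against simulator truth labels.

## What the simulator emulates — and what it does not

The synthetic-data generator defines the conditions every statistical
claim in the test suite is made under. Translated regions place each
P-site by drawing a codon uniformly and a frame from
$(p, (1-p)/2, (1-p)/2)$; untranslated regions place P-sites uniformly over
positions. Defaults: $p = 0.9$, the phasing strength of a good
cycloheximide library; footprint lengths massed on 28-30 nt; log-normal
abundances with median 20 FPKM against a nominal 20 M-read library
(a few hundred P-sites on a typical CDS); 40 coding plus 40 non-coding
transcripts over two chromosomes, roughly 40% multi-exon. Reads are
emitted as unspliced alignments placed so the +12 nt P-site offset
recovers the drawn position exactly, which keeps the truth table exact;
junction-straddling footprints are not generated.

The generator deliberately omits several features of real libraries:
position-level heaping (RNase and ligation bias), 5' ramp effects,
overlapping ORFs, frame-shifted or truncated ORFs, multimapping, and
sequence content. Two consequences matter for interpreting the test
suite. First, passing accuracy tests here show that the estimator detects
phasing at realistic depth — not that it inherits the published real-data
rankings. Second, under exactly-uniform untranslated occupancy the pooled
frame chi-square (ORFscore) is close to a sufficient statistic and
classifies synthetic fixtures essentially perfectly, so on these fixtures
the coherence score matches it on well-covered transcripts but does not
beat it; the real-data pathologies that degrade ORFscore are precisely the
ones the generator leaves out. The accuracy ordering reported on real
libraries should not be expected to reproduce under this clean simulator,
and the test suite documents this honestly rather than adjusting the
generator post hoc.

The biased length-resampling utility reweights reads by
$\exp(b\,|\ell - 28.5|)$ — an invented, clearly non-canonical stand-in
that reproduces the qualitative behavior of interest (progressive
flattening of the 28-30 nt enrichment toward a uniform length
distribution). At moderate bias the resampled distribution flattens
monotonically; at extreme bias it overshoots toward the rare tail
lengths. Because the generator places positions independently of length,
periodicity scores are expected to be robust under this resampling, and
the robustness check (1,000 trials of 10,000 reads on one high-coverage
synthetic gene, strongest bias vs. unbiased Tukey fence) confirms it at
desk scale.

## Tunables at a glance

| parameter | default | meaning |
|---|---|---|
| `window_length` | 30 nt | coherence window $N$; divisible by 3 |
| `step` | 3 nt | window step $L$ |
| `segment_length` / `segment_overlap` | 12 / 6 nt | Welch segments per window (4 at defaults) |
| P-site offset | +12 nt for 26-32 nt reads | 5' end to P-site; per-length table, configurable A-site shift |
| `fpkm_cutoff` | 5 | active/null stratification for calibration |
| `fdr` | 0.05 | null-quantile threshold level |
| `floss_lengths` | 20-40 nt | FLOSS distribution support |
| fence multiplier | 3 | Tukey "extreme outlier" fence for FLOSS |

Problem sizes used by the test suite and the acceptance script — 80
transcripts per simulated library, three replicate libraries, 2,000-null
calibration samples over ten seeds, 1,000 resampling trials of 10,000
reads — were chosen as the smallest sizes at which the Monte-Carlo
standard errors are comfortably below the margins being asserted.

## Known limitations

* Calibration needs both strata populated (default floor 50 per side);
  shallow libraries or all-coding annotations need `null_mode = "biotype"`
  or a different cutoff.
* The empirical-quantile threshold controls the per-comparison false call
  rate on the null stratum, not a studywise FDR.
* uORF and other sub-region scoring is supported by scoring user-specified
  regions; there is no exhaustive de-novo ORF enumeration across frames.
* Reads are assigned by P-site only; junction-straddling P-sites are
  resolved by the alignment's reference coordinates, and UMIs are not
  handled.
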