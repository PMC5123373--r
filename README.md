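# ribospec

Ribosome profiling sequences ~28–30 nt mRNA footprints protected by
translating ribosomes. Because elongation advances codon by codon, the
P-sites of footprints over an actively translated region are phased with a
period of exactly three nucleotides, while untranslated RNA shows no such
phasing. `ribospec` classifies transcripts (or any sub-transcript region,
e.g. a candidate uORF) as actively translated from this signal alone — no
matched mRNA-seq library required. It is aimed at anyone analysing
ribo-seq alignments: a BAM plus a GENCODE-style GTF in, calibrated
translation calls and browser tracks out.

## The score

For a region with coordinate set *C*, P-site-adjusted counts are
normalized to the position of highest coverage, giving *R* with values in
[0, 1]. The score is the mean Welch spectral coherence between *R* and an
idealized period-3 signal *S* = (1,0,0,1,0,0,…) at the codon frequency
*j* = 1/3 cycles/nt, over sliding windows of *N* nt (default 30) stepped
by *L* nt (default 3):

    Spec_RS,j = (1/M) Σ_m Coh(R[m, m+N), S_N; j),   M = floor((|C|−N)/L) + 1

with Coh = |P̄xy|² / (P̄xx · P̄yy) estimated within each window from
overlapping 12 nt Welch segments. Scores in [0, 1] are calibrated against
FPKM-stratified score distributions: the translation threshold is the
(1 − FDR) quantile of the empirical null stratum, and each region gets a
kernel-density Bayes posterior probability of translation. FLOSS
(fragment-length distance to a coding reference, with a Tukey-fence
outlier rule) and ORFscore (signed frame-enrichment chi-square) are
included as comparators, plus ROC/AUC benchmarking over abundance cutoffs.
A seeded simulator generates annotation + alignment fixtures with exact
ground truth. Details and design rationale are in the vignette
(`vignettes/spectral-translation-calling.Rmd`).

## Worked example

Simulate a small library with known truth, then run the full pipeline:

```r
library(ribospec)
cfg   <- sim_config(n_coding = 20, n_noncoding = 20,
                    library_size = 1e7, seed = 101)
txome <- simulate_transcriptome(cfg, "demo.gtf")
sim   <- simulate_ribo_reads(cfg, txome, sam_path = "demo.sam", bam = TRUE)

run <- run_pipeline(run_config(bam = sim$bam_path, gtf = txome$gtf_path,
                               outdir = "demo_out", fpkm_cutoff = 1,
                               null_mode = "biotype",
                               min_calibration_n = 10))
#> [calibration] threshold 0.441282 at FDR 0.05 (FPKM cutoff 1)
head(run$results[, c("transcript_id", "region", "read_count",
                     "spectre_score", "posterior", "translated")])
#>        transcript_id region read_count spectre_score posterior translated
#> TX0001        TX0001    CDS        147        0.7971    1.0000       TRUE
#> TX0003        TX0003    CDS         28        0.4789    0.9422       TRUE
#> TX0005        TX0005    CDS        522        0.9084    1.0000       TRUE
```

Coding transcripts score high (0.48–0.92 here, rising with coverage
depth) and land above the FDR-0.05 threshold of 0.441 derived from the
non-coding null stratum; their posteriors are near 1. Benchmarking
against the simulator's truth labels:

```r
tbl <- run$results
tbl$truth <- sim$truth$translated[match(tbl$transcript_id,
                                        sim$truth$transcript_id)]
benchmark_over_cutoffs(tbl, label_col = "truth")
#>          metric cutoff    auc n_pos n_neg
#> 1 spectre_score     NA 0.9125    20    20
#> 2      orfscore     NA 1.0000    20    20
#> 3         floss     NA 0.5050    20    20
```

On this deliberately clean simulation the coherence score separates the
classes well; FLOSS is uninformative here because both classes share one
fragment-length mixture (see the vignette for what the simulator does and
does not emulate). `demo_out/` also contains per-window coherence and
posterior bedGraph tracks (0-based half-open), a calibration JSON sidecar
and a run manifest.

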