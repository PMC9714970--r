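# bundlequant

Quantitative analysis of sensory hair-cell membrane biology: confocal z-stack
segmentation and fluorescence quantification, lysosome and hair-bundle
morphometry, auditory-evoked-potential (AEP) threshold estimation, and
cholesterol-recognition sequence-motif scanning — with a synthetic-data module
so that every stage is verifiable against known ground truth without any raw
microscopy or electrophysiology data.

## Who this is for

Researchers quantifying fluorescence in hair cells (zebrafish inner ear and
lateral-line neuromasts, or analogous systems) who need reproducible,
scriptable versions of the measurements that are usually done with ad-hoc
image-analysis scripts: compartment enrichment of membrane probes,
"total vs recruited" signal, enlarged-lysosome calls, bundle morphometry,
cell counts, AEP thresholds, and conserved-pattern / CRAC-CARC motif searches
in protein sequences.

## The quantities at the core

**Compartment enrichment (ratio of ratios).** For a probe channel *P* and a
uniform reference membrane probe *R*, with stereocilium mask *S* and
basolateral mask *B*:

    r_P = mean_S(P) / mean_B(P),    r_R = mean_S(R) / mean_B(R)
    fold = r_P / r_R

`r` is reported in percent; `fold` is the enrichment of the probe of interest
over what membrane density alone explains. Because both channels share the
same geometry, voxelization and PSF attenuation largely cancel in `fold`.

**Enlarged-lysosome rule.** Connected components (6-connectivity) of a
lysosome-marker mask are measured; the equivalent diameter is
`(6V/pi)^(1/3)` from the component volume `V`, and a component is *enlarged*
iff the equivalent diameter is strictly greater than 2 um. A cell is flagged
iff an enlarged component's centroid lies in its mask; flagged/unflagged
counts per group form a 2x2 table tested with a Fisher exact test implemented
from first principles (two-sided, sum of all hypergeometric tables no more
probable than the observed one).

**AEP thresholds.** Stimuli are Blackman-windowed tone pips (10 ms,
100-1000 Hz) presented at descending levels. Epochs are averaged per
(frequency, level); a response is detected iff the post-stimulus peak-to-peak
amplitude is at least `k` times the raw per-epoch pre-stimulus RMS (default
`k = 2`); the threshold is the lowest level detected contiguously from the
top. The phantom generator drives responses with a logistic level-amplitude
curve, `A(L) = A_max * logistic((L - theta)/s)`, so recovery of `theta` is
testable.

**Sequence patterns.** Alignment columns are classified into literals,
explicit residue sets, or physicochemical classes (Omega aromatic, Psi
aliphatic, pi small, zeta hydrophilic, Phi hydrophobic), yielding PROSITE-like
patterns such as `[pi]-[ST]-[Omega]-[ST]-[Psi]-[zeta]-[zeta]-[Omega]`;
a scanner reports all (overlapping) matches, and dedicated definitions find
CRAC `(L/V)-x(1,5)-Y-x(1,5)-(K/R)` and CARC `(K/R)-x(1,5)-(Y/F/W)-x(1,5)-(L/V)`
cholesterol-recognition motifs.

## Worked example

Render a two-channel phantom (a uniform membrane probe `PM` and a probe `D4H`
with 8-fold stereocilia enrichment, default photon/read noise and PSF),
segment it adaptively, and measure enrichment:

```r
library(bundlequant)
spec <- phantom_spec(seed = 1)          # E = 8 for the D4H channel
sim  <- simulate_stack(spec)
sim$stack
#> volume_stack: 96 x 80 x 80 voxels (z,y,x), 2 channel(s)
#>   voxel size (um): z=0.15 y=0.1 x=0.1
#>   channels: PM, D4H

mask  <- segment_adaptive(sim$stack, "PM", window_um = 5, offset_frac = 0.1)
parts <- split_mask_at_z(unclass(mask), sim$stack$voxel_size,
                         sim$truth$cells[[1]]$apex_um, exclude_um = 0.9)
compartment_enrichment(sim$stack, parts$above, parts$below, c("D4H", "PM"))
#> probe     channel D4H    stereocilia/basolateral = 200.2%
#> reference channel PM     stereocilia/basolateral = 31.4%
#> ratio of ratios: 6.4-fold
```

The 6.4-fold readout recovers the generative 8-fold enrichment to within the
pipeline's documented noise tolerance (the noise-free pipeline recovers it
exactly); the within-channel percentages are diluted by blurred halo voxels,
which cancel between channels in the fold change.

Group statistics on published-style counts, and motif scanning:

```r
fisher_exact_2x2(rbind(c(39, 145), c(134, 102)))
#> Fisher exact (two-sided, sum of no-more-probable tables)
#>   statistic: 0.2047349
#>   p-value: 8.842e-14

fa <- system.file("extdata", "minar2_synthetic.fasta", package = "bundlequant")
scan_crac_carc(read_fasta(fa))[, c("start", "end", "match", "kind")]
#>   start end   match kind
#> 1    31  35   VAYAK CRAC
#> 2    76  80   KAFAL CARC
#> 3   121 127 LAAYAAR CRAC
```

(The bundled FASTA is a labelled synthetic stand-in carrying three engineered
motifs, not the real protein sequence.)

A configuration-driven run (phantom -> quantify -> vesicles -> Fisher) is
available via `run_config(system.file("extdata", "demo_config.yaml",
package = "bundlequant"), "out/")`, and a thin command-line wrapper lives at
`inst/cli/bundlequant.R`.

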