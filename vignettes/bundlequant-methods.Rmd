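---
title: "Methods and design of bundlequant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of bundlequant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models behind each analysis stage, the parameters
that matter, the numerical conventions, and what the synthetic phantoms do and
do not establish about real data.

## 1. The phantom generator

The generator emulates the specimens behind two-channel confocal
quantification of sensory hair cells. Each cell is an ellipsoid (default
semi-axes 4 x 2.5 x 2.5 um in z, y, x) with a membrane shell (0.4 um), a
bundle of apical cylinders standing in for stereocilia (default 12 cylinders,
radius 0.3 um, length 4 um), optionally one kinocilium (twice the
stereocilium length), and apically biased spherical lysosomes. Channels are
defined by probe models: a membrane density (intensity density per membrane
voxel), an *enrichment factor* E multiplying the stereocilia-membrane
density, a cytoplasmic background, and an optional lysosome density. The
default channel pair is a uniform membrane reference (E = 1) and a
cholesterol-probe-like channel with E = 8.

No published generative model exists for these scenes; all geometric and
photometric parameters are this package's own choices, picked to be realistic
in proportion for larval zebrafish hair cells, with two deliberate
departures:

* stereocilia are rendered thicker (0.3 um radius) than real stereocilia so
  that they are resolvable at the default 0.1 um lateral voxel size, and the
  whole stereocilium is treated as membrane (real stereocilia are effectively
  membrane-dense at confocal resolution, which is also why a uniform membrane
  probe over-represents in bundles);
* lysosome diameters are uniform on a configurable range rather than drawn
  from a measured size distribution. Cells that should carry an enlarged
  vesicle receive one with diameter drawn above the 2 um rule
  (default 2.2-3.2 um).

Rendering is by center-of-voxel inclusion: a voxel belongs to a shape iff its
center lies inside. This is deterministic and lets analytic volumes serve as
oracles (total noise-free intensity matches the analytic
`sum(volume x density x gain)` within 5% voxelization error at the default
resolution). Detection follows optics: the expected image (density x gain) is
blurred by an isotropic Gaussian PSF specified in um (default sigma 0.1 um,
converted per-axis for anisotropic voxels), then Poisson photon noise is
applied (gain = 50 counts per density unit), then Gaussian read noise
(sd = 2 counts), and negative values are clamped to zero so intensities stay
non-negative.

One RNG substream is derived per cell from `(seed, cell index)`, so cell i's
geometry is unchanged when `n_cells` grows. Within a cell, vesicle diameters
are drawn first and spheres placed largest-first with rejection sampling
(non-overlap plus a one-voxel buffer so 6-connected components stay
separate); the ground truth records what was actually rendered, so a
placement failure can never silently desynchronise truth from image. The
per-cell `enlarged` truth flag is therefore "an enlarged vesicle is present
in the rendered scene".

**What phantoms do not emulate:** optical aberrations beyond a Gaussian PSF,
bleaching, scanner artifacts, tissue autofluorescence, cell-to-cell
biological variability in probe expression, or touching/overlapping cells.
Tests passing on phantoms establish that the measurement code is correct
under its stated model, not that the model captures every property of real
specimens.

## 2. Adaptive segmentation and quantification

The segmentation rule is: a voxel is foreground iff its intensity exceeds the
local mean over a window of physical size `window_um`, times
`(1 + offset_frac)`. Windows are 2D within each optical section by default
(confocal data are quantified per slice; a 3D mode exists). Defaults —
window 5 um, offset 0.10 — are declared package conventions, recorded in the
mask's provenance; the historical scripts this emulates did not document
their exact algorithm. Local means use integral-image box sums with
border-truncated windows (no padding bias). Note one consequence of the rule:
re-thresholding an already binarised field reproduces the foreground only for
structures thinner than the window (local foreground fraction below
`1/(1 + offset_frac)`); the interior of a blob much larger than the window
equals its own local mean and would not re-select. Membranes, stereocilia and
vesicles are in the thin regime.

ROIs are axis-aligned boxes in micrometres, converted to voxels by rounding
outward (floor on the origin, ceiling on the far edge), 0-based half-open
indexing internally, micrometre reporting externally. Zero-voxel selections
report sum 0 with the mean explicitly flagged undefined rather than silently
zero.

Compartment enrichment reports per-compartment volumes and mean
fluorescences, within-channel stereocilium/basolateral ratios in percent, and
the cross-channel ratio of ratios. For pipeline use, a segmented cell is
split at the apical plane; because the apical surface is curved, a
transition slab (default choice in examples: 0.9 um) below the plane is
excluded from both compartments so stereocilia bases do not contaminate the
basolateral mean. The ratio of ratios is the robust readout: PSF attenuation
and mask dilation affect both channels identically and cancel; residual bias
under default noise comes from zero-clamped read noise in dim halo voxels and
from segmenting on the reference channel (selection bias), measured at about
20% at E = 8 — inside the 25% tolerance the recovery analyses use, while the
noise-free pipeline recovers E exactly.

## 3. Morphometry

Connected components use 6-connectivity (face adjacency) by default — the
conservative choice that splits touching vesicles; 26-connectivity is
available. The enlarged call uses a strict `>` at 2 um on the equivalent
diameter, applied per connected component (whether aggregates should be
judged jointly is unknowable from the available description; per-component is
the declared convention). Cell ownership is by centroid containment.

Bundle length/width use the inertia tensor of pixel centers for the principal
axis. Extents are moment-based — `sqrt(12)` times the standard deviation of
center projections with the within-pixel variance `p^2/12` added back —
which is exact for axis-aligned rectangles and stable under rotation
(range-based extents inflate by up to a pixel diagonal on staircase edges;
measured rotation error of the moment form is below 0.5% at 0.1 um pixels).
Width is measured in a one-pixel band at mid-length, a declared convention
recorded in the result. Cell counting uses centroid-in-region (inclusive
bounds) over a 50 x 50 um box by default, a deterministic stand-in for
manual multi-point counting.

## 4. AEP simulation and threshold estimation

Stimuli are Blackman-windowed tone pips; the response template defaults to
one cycle of the stimulus frequency under a Blackman window, matching the
stimulus bandwidth. Response amplitude follows
`A(L) = A_max * logistic((L - theta) / s)` with slope `s` in dB (default
2 dB; `s = 0` is the hard-threshold limit), latency 5 ms, epochs averaged per
(frequency, level).

Detection declares a response when the post-stimulus peak-to-peak amplitude
of the averaged trace reaches `k` times a baseline RMS (tie detects;
`k = 2` default). The choice of baseline matters more than `k`: the
peak-to-peak of pure *averaged* noise over a 30 ms window is itself about
6-7 times the averaged trace's own RMS, so referencing the averaged baseline
would detect noise at every level for any small `k`. The threshold pipeline
therefore references the *unaveraged* per-epoch pre-stimulus RMS (the raw
noise floor): averaging N epochs pulls noise peak-to-peak down by
`sqrt(N)` relative to that floor, which makes `k = 2` discriminative at the
default 20 epochs. This is the package's declared criterion; the physiology
literature does not standardise one.

Thresholds use the contiguous-from-top rule over strictly descending levels:
the threshold is the lowest level detected with all higher levels also
detected; an undetected top level means "not reached"; detection gaps warn
and terminate the run (the descending-level audiometric convention). With
zero noise and a hard threshold, the estimate equals theta rounded up to the
nearest tested level. Under default noise, 100-run simulations at 5 dB steps
recover theta within one step in at least 95 runs. Real printed thresholds
from animal recordings are not desk-reproducible (they depend on unreported
detection criteria and epoch counts) and are deliberately not targets.

## 5. Sequence patterns and motifs

The residue-class table (Omega = FWYH, Psi = ILVM, pi = AGPS,
zeta = DEHKNQRST, Phi = ACFILMVWY, plus charge classes) follows the standard
normalized nomenclature and is overridable, since published figures using
these symbols rarely reprint memberships. Column classification: more than
50% gaps makes a wildcard; otherwise a literal at >= 90% frequency, an
explicit set at <= 2 distinct residues, else the smallest class containing
all residues (ties broken by size then table order), else a wildcard.
Maximal non-wildcard runs of length >= 3 become patterns. Derivation is
order-invariant across sequences.

The alignment simulator gives every column a consensus and substitutes
within the column's residue set (pattern positions use their own set;
background columns use the smallest class of their consensus) at a
configurable rate, across classes at another, mimicking an alignment of
conserved orthologs. With the across-class rate at zero, derivation recovers
the planted pattern exactly at the planted columns (the surrounding
conserved background derives to its own class symbols, as real conserved
flanks would).

Scanning enumerates all gap lengths of `x(m,n)` positions, so there is no
greedy/lazy ambiguity; all overlapping matches are reported with 1-based
inclusive coordinates, and identical spans arising from different gap splits
are reported once. CRAC keeps the strict central Y; CARC allows Y/F/W; both
centers and the 1-5 spacing are configurable. The bundled 190-residue FASTA
is a synthetic stand-in with exactly three engineered CRAC/CARC motifs (the
real ortholog sequence is not redistributable here); motif counts on real
proteins depend on the spacing convention chosen.

## 6. Group statistics and the runner

The Fisher exact test is implemented from first principles because it
anchors the enlarged-lysosome analysis: with margins fixed, cell (1,1) is
hypergeometric; the two-sided p sums all tables no more probable than
observed (the standard convention — the doubling convention differs and is
not used), with `lchoose` arithmetic and a 1e-7 relative tie guard. It agrees
with full enumeration to 1e-12 over every table with n <= 40 and with
`stats::fisher.test` on random tables. All other comparisons (Welch t,
Mann-Whitney, ANOVA, Kruskal-Wallis) delegate to the standard R routines
behind a uniform result type. Percent-of-control is
`100 * value / mean(control)` with mean +/- sem (sd with n-1 denominator)
summaries.

`run_config` validates stage names against its registry before anything
executes, writes one artifact per stage plus a provenance record
(package version, seed, parameters), and is deterministic: identical config
and seed give bit-identical CSVs.

## 7. Numerical choices and problem sizes

* Stacks are written as multi-page 32-bit-float TIFF scaled to [0, 1] with a
  JSON sidecar (voxel size, channel names, intensity scale); round trips are
  exact to float32 precision (~1e-7 relative). Ground-truth masks serialise
  as run-length-encoded JSON.
* Default phantom: 96 x 80 x 80 voxels at 0.15 x 0.1 x 0.1 um — large enough
  that voxelization error is inside the stated bands, small enough that the
  full recovery sweep (four enrichment factors, noise-free and noisy) runs in
  well under a minute on one CPU. Test-suite phantoms use a reduced geometry
  (48 x 32 x 32) with proportionally shrunken cells.
* Threshold-recovery simulations use one frequency, nine levels (160-120 dB,
  5 dB steps), 20 epochs, 10 kHz sampling.
* Scanner equivalence uses 1,000 random length-50 sequences and 20 random
  patterns per run.

## 8. Known limitations

* The adaptive-threshold parameters are conventions, not reconstructions of
  any historical script; results depend on them and they are always recorded
  in provenance.
* Whether "recruited" quantification should threshold the marker channel or
  use a fixed mask is not standardised; both are supported
  (`marker_mask` overrides segmentation).
* The enrichment pipeline's noisy-case bias (~20% at E = 8) is structural
  (clamped read noise in halo voxels, reference-channel selection bias), not
  seed noise; improving it would need joint-channel segmentation, which is
  out of scope.
* No registration, deconvolution, bleaching correction or spectral unmixing;
  no per-stereocilium reconstruction; no hardware control or artifact
  rejection beyond optional amplitude clipping.
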