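---
title: "Quantifying nanoparticle trafficking to lysosomes in high-content RNAi screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying nanoparticle trafficking to lysosomes in high-content RNAi screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

After endocytosis, most synthetic nanoparticles (NPs) are routed through
the endosomal system to lysosomes. An RNAi screen for regulators of this
route images thousands of wells — each well a population of cells depleted
of one gene product by siRNA, incubated with fluorescent NPs and
immunostained for the lysosomal membrane protein LAMP1 — and asks, per
well: *what fraction of the cellular NP signal sits in LAMP1-positive
compartments?*

`hcsnano` implements that measurement chain end to end:

1. **Background correction** of the LAMP1 and NP channels (rolling ball,
   radius 10 px by default). The nuclei channel is segmented raw.
2. **Segmentation**: nuclei by smoothed-Otsu thresholding plus a
   distance-transform watershed; cell bodies by nucleus-seeded region
   growing over a cytoplasmic reference channel; LAMP1 puncta by a white
   top-hat at spot scale with a contrast threshold.
3. **Per-cell QC**: cells touching the field border, apoptotic cells
   (small condensed nuclei) and mitotic cells (bright condensed
   chromatin) are removed before aggregation.
4. **The per-well statistic**, the *LAMP1-associated NP ratio*:

   $$ R_\text{well} \;=\; \frac{\overline{\sum_\text{spots} I_{NP}}}
         {\overline{\sum_\text{cell} I_{NP}}} $$

   the average over QC-passing cells of total NP intensity inside LAMP1
   spots, divided by the average of total NP intensity over the whole
   cell mask — a ratio of averages, not an average of per-cell ratios.
   Per-field cell records are pooled across the fields of a well before
   averaging.
5. **Screen statistics**: every well ratio is divided by the mean ratio
   of the non-targeting negative-control (NEG) wells of its plate and
   replicate; treatments with any well under 50 analyzed cells or under
   150 cells total across replicates are discarded as non-viable;
   surviving treatments are classified from their replicate-averaged
   normalized ratio against the normalized NEG distribution — at least
   2 SD below the NEG mean is a *mild decrease*, at least 3 SD a *strong
   decrease*, with mirrored increase classes; a gene is *validated* when
   at least 2 of its independent siRNAs reproduce a decrease. One-tailed
   Student's t-tests (pooled variance; Welch optional) compare each
   treatment's normalized wells with the NEG wells.
6. **Colocalization** for confocal-style validation: the rank-weighted
   coefficient (RWC), reported per cell as the percentage of NP signal
   colocalizing with a marker.

Because the screen's raw images are not publicly available, the package
ships a synthetic-microscopy generator that emulates the screen's
statistical structure with known ground truth; all quantitative claims
made by the test suite are claims about this generator.

## The rank-weighted colocalization coefficient

For the \(n\) pixels of one cell, both channels are ranked by descending
intensity with tied values receiving average ranks. With
\(D_i = |\operatorname{rank}_{NP}(i) - \operatorname{rank}_{M}(i)|\) and
weight \(W_i = (n - D_i)/n\),

$$ \mathrm{RWC} \;=\; \frac{\sum_{i \in C} I_{NP}(i)\, W_i}
        {\sum_{i \in A} I_{NP}(i)}, $$

where \(A\) is the set of pixels above the NP threshold and
\(C \subseteq A\) those also above the marker threshold. The coefficient
is 1 exactly when the two channels agree in rank everywhere above
threshold, and 0 when nothing clears both thresholds. Being a fraction
of NP *intensity*, RWC is invariant under any strictly increasing
transform of the **marker** channel (ranks are unchanged) and under
positive **linear** rescaling of the NP channel, but not under nonlinear
NP transforms — the intensity weighting is deliberate, since the
quantity reported is "percentage of NPs colocalizing". Both invariances
are asserted by the test suite against a brute-force rank-enumeration
oracle.

Per-cell thresholds default to a fixed fraction (0.15) of the in-mask
maximum, the convention of standard colocalization pipelines. An Otsu
cut within the mask is available but ill-suited here: with strongly
bimodal NP signal it lands *between* the diffuse and punctate modes and
silently drops the diffuse pool from \(A\), making the percentage
insensitive to the diffuse/punctate split that the screen is about.

## The synthetic screen generator

`simulate_field()` renders one 3-channel field; `simulate_screen()`
renders every (well, replicate, field) of a plate layout to TIFF;
`simulate_well_table()` skips imaging and draws per-well ratios directly
for statistics-scale testing.

Geometry and intensities (defaults in `simulation_config()`):

* 192×192 px fields at a nominal 0.16 µm/px, 25 cells per field placed
  with a minimum separation; nuclei are filled ellipses (semi-axes
  3.5–5 px), cell bodies concentric ellipses (6–8.5 px). Cell radii are
  deliberately **smaller than the 10 px rolling-ball radius**: the ball
  cannot descend into a cell-sized plateau, so diffuse cytoplasmic NP
  signal survives background correction while slow illumination
  gradients (a low-order random polynomial surface, amplitude 25) are
  removed. Had cells been larger than the ball, the correction itself
  would flatten the diffuse pool the ratio's denominator needs.
* Each healthy cell gets \(1 + \mathrm{Poisson}(3)\) LAMP1 spots
  (radius 0.7–1.1 px, amplitude 110 over a faint diffuse haze of 3), so
  a planted in-spot fraction is always realizable.
* The NP channel plants the trafficking effect exactly: a cell's total
  NP intensity (60 000 camera units) is split so spot pixels carry
  fraction \(f = \mathrm{clamp}(f_0 \cdot e, 0, 1)\) and the remaining
  cytoplasm the rest, *before* background and noise. The control
  fraction is \(f_0 = 0.55\); a treatment's effect multiplier \(e\)
  scales it. Pre-noise, the realized in-spot fraction equals \(f\) to
  machine precision (asserted in tests).
* Apoptotic cells (small, bright nuclei: radius ×0.5, intensity ×2.2),
  mitotic cells (condensed bright chromatin without a cytoplasm ring:
  intensity ×2.8) and border cells (placed across a field edge) default
  to 6%, 6% and 12% of cells, giving the QC gates real work.
* Noise follows the standard fluorescence camera model: Poisson shot
  noise on the signal plus additive Gaussian read noise (SD 2), then
  quantization to 16-bit camera units.
* Screen-level variability: a shared multiplicative offset per replicate
  (CV 0.05; it cancels under per-replicate NEG normalization) and an
  independent multiplicative jitter per well (CV 0.05), which is what
  sets the width of the NEG distribution and hence the phenotype bands.

What the generator does **not** emulate: optical PSF blur, 3D structure,
cell-to-cell heterogeneity in NP uptake, spatially correlated
plate-position effects, or NP corona physics. Passing tests therefore
demonstrate that the *analysis chain* is correct and unbiased on images
matching its assumptions — not that it is robust to every real-world
imaging artifact.

## Numerical and design choices

* **Rolling ball.** Background is the grayscale opening with a
  hemispherical structuring element (support \(dx^2+dy^2 \le r^2\),
  height \(\sqrt{r^2-d^2}\) in intensity units); out-of-image neighbours
  are ignored, so a constant image maps to exactly zero. The estimated
  background never exceeds the image and output is clipped at 0. Because
  the ball's height is an absolute intensity, the operation — like the
  original implementations — is not equivariant under intensity
  rescaling; the well ratio is exactly invariant to NP rescaling given
  fixed masks (pure sums) and invariant to within 1% through the whole
  pipeline, which the tests assert and which makes the unknown
  microscope intensity scaling immaterial.
* **Proprietary building blocks.** The commercial screening software's
  nucleus/cytoplasm/spot operations are unpublished; the package uses
  their standard open equivalents (smoothed Otsu + distance-transform
  watershed; seeded propagation; top-hat + contrast threshold) behind
  the same interfaces.
* **Cytoplasm threshold.** The reference channel (background-corrected
  NP) is strongly trimodal — background, diffuse cytoplasm, bright
  puncta — so the mask threshold is computed on a log scale and then set
  to 0.6 of the estimated cytoplasm plateau: for a blurred step edge
  this crosses near the true boundary (calibrated against generator
  ground truth; default `cyto_threshold_factor = 0.6`). Speckle
  components under 25 px are discarded before region growing.
* **QC gates** (`qc_gates()`: nucleus area < 40 px², nucleus mean
  intensity > 150) are calibrated on the generator's *detected* nucleus
  measurements — smoothing inflates small nuclei and dilutes their mean
  intensity, so gates on truth-scale values would miss. Precedence:
  border, then apoptotic (area), then mitotic (intensity).
* **Boundary conventions.** "Fewer than 50 cells" is strict (50 passes);
  phenotype boundaries are closed toward the extreme class (exactly
  \(\mu - 2\sigma\) is a mild decrease). Wells with no usable cells
  yield an `NA` ratio flagged `ratio_defined = FALSE` and are left to
  the viability rule, not raised as errors.
* **Ratio of averages.** The well statistic averages numerator and
  denominator separately over cells (equivalently, a sum ratio). The
  alternative — averaging per-cell ratios — weights dim and bright cells
  equally and is *not* what this pipeline computes.
* **Normalization and σ scope.** Default scope is per plate × replicate;
  the SD used for classification is computed over normalized NEG wells
  pooled across the screen. Classification applies to the
  replicate-averaged normalized mean. Per-plate and per-screen scopes
  are selectable and recorded in the output metadata.
* **Open interpretation.** Whether the original analysis pooled cells
  across fields before the well average or averaged per field first is
  not documented; this package pools across fields.

## Statistical behaviour worth knowing

Classification is scale-invariant (a global rescaling of all raw ratios
cancels in normalization, asserted exactly in tests). Planted strong
effects (0.5×) are recovered with sensitivity 1.0 and zero strong-call
false positives among nulls in 20-seed imageless screens at 348-gene
scale with NEG CV 0.05.

A *mild* phenotype, by contrast, occupies a band only one NEG-SD wide
(between \(\mu-3\sigma\) and \(\mu-2\sigma\)), while a treatment's
replicate-averaged ratio carries noise of about \(\sigma/\sqrt{n}\) for
\(n\) wells. Exact recovery of a planted mild phenotype is therefore
intrinsically probabilistic at realistic replicate counts — with 18
wells per treatment and 72 NEG wells the all-mode recovery demonstration
has roughly an 83% a-priori chance of landing every planted mild call in
its band. The shipped end-to-end test runs that design at a fixed seed;
the general caveat — mild/strong boundaries on single-screen data are
soft — applies equally to real screens of this design.

## Problem sizes used by the tests

Test and demonstration runs use 128–192 px fields with 10–30 cells,
one to three fields per well, screens of 2–348 treatments and up to
three replicates (the recovery demonstration uses 6 wells per treatment
and 24 NEG wells per replicate); these sizes were chosen so the full
chain, including the image-level simulations, completes comfortably on a
single CPU while exercising every code path at the screen's statistical
structure.

## Known limitations

* Segmentation quality is only demonstrated on the generator's ellipse
  geometry; highly confluent or irregular cells would need parameter
  re-tuning (`analysis_params()` exposes every knob).
* The rolling-ball interaction with object size means the default
  radius is tied to the expected cell scale; cells larger than the ball
  radius would have their diffuse signal partially subtracted, biasing
  the ratio upward.
* RWC percentages saturate near 100% once the diffuse NP pool falls
  below the per-cell threshold (high in-spot fractions); comparisons
  are most informative in the low-to-mid range.
* No plate-effect correction (B-score/median polish) and no FDR
  machinery are provided; the screen's published analysis used neither.
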