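---
title: "Methods: 3D cardiomyocyte volume, nuclearity and ploidy from thick-section stacks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3D cardiomyocyte volume, nuclearity and ploidy from thick-section stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(cardiomorph)
```

cardiomorph measures individual cardiomyocytes directly in 3D from
two-channel confocal z-stacks of thick histological sections: a nuclear
stain (DAPI) and a membrane stain (WGA). Per cell it reports volume,
nuclearity (number of nuclei) and the ploidy class of each nucleus, then
aggregates per animal and group. This vignette explains the measurement
decisions; every step below runs on synthetic stacks whose ground truth is
known exactly, which is also how the package validates itself.

## Geometry conventions

Stacks are arrays indexed `[z, y, x]` with voxel extents in micrometres
(`voxel_size`, z first). Voxel `i` along an axis of spacing `w` has its
centre at `(i - 0.5) * w` µm; plane `i` lies at depth `(i - 1) * w_z`.
All reported volumes are voxel counts times the voxel volume.

## Synthetic validation stacks

`generate_phantom()` builds membrane-delimited capsule-shaped cells
(optionally branched) with 1–2 ellipsoidal nuclei each; cell length is
tip-to-tip, so an unbranched cell of length $L$ and radius $r$ has the
analytic volume $\pi r^2 (L - 2r) + \tfrac{4}{3}\pi r^3$, which the
rasterised ground truth matches to a fraction of a percent at 0.5 µm
voxels. The membrane shell is drawn *outside* the true cell region, so the
ground-truth label is exactly the volume enclosed by the membrane staining
— the quantity a segmentation growing "to the limits of the membrane
staining" should report.

```{r phantom}
ph <- generate_phantom(phantom_spec(shape = c(40L, 192L, 192L),
                                    n_cells = 4L, seed = 21L))
ph$truth$cells[, c("cell_id", "volume_um3", "nuclearity", "ploidy_label")]
```

Nuclei-only generators complement it: `generate_control_field()` emulates
the haploid calibration control, `generate_nuclei_field()` a pure
densitometry target, and `generate_tissue_field()` a depth-uniform slab for
acquisition QC fixtures.

## Acquisition QC

Quantitative densitometry is only valid when signal intensity is preserved
through the section. `assess_dapi_profile()` checks the per-plane mean
intensity profile of the nuclear channel:

* **Flatness** — the coefficient of variation of smoothed plane means over
  the tissue core must stay below `max_flatness_cv` (default 0.10). Depth
  attenuation inflates this monotonically.
* **Terminal drop-off** — the maximal suffix of planes below
  `drop_fraction` (default 0.5) of the core level (75th percentile of
  smoothed plane means) marks where the section ends; it is excluded from
  the core before the flatness test.
* **Saturation** — at most `max_saturated_fraction` (default 0.1%) of
  voxels may sit at the detector limit; clipped nuclei destroy the
  intensity–DNA proportionality.
* **Noise floor** — the dimmest core plane must exceed the background level
  (histogram mode) by `min_noise_margin` (default 3×).

```{r qc}
tf <- generate_tissue_field(phantom_spec(shape = c(48L, 128L, 128L),
                                         n_cells = 500L, seed = 31L))
assess_dapi_profile(compute_profile(tf$stack), tf$stack)
```

By default ploidy classification refuses stacks that fail QC
(`ploidy.require_qc_pass`).

## Nucleus segmentation and densitometry

Nuclei are segmented in the smoothed nuclear channel by a global Otsu
threshold, 26-connected components, and a watershed on the negated
anisotropic Euclidean distance transform seeded at h-maxima
(`split_depth`, default 1 µm) so touching nuclei separate.

Integrated intensity — the densitometric quantity ploidy rests on — is the
sum of background-corrected intensity over the nucleus. Two details matter:

* the background is the histogram mode of the channel, not a fixed offset;
* each label is grown 1 µm (`measure_dilation`, nearest-nucleus wins) *for
  the intensity sum only*, because the foreground mask clips the dim
  PSF-spread rim of each nucleus. Without this the loss is intensity
  dependent and dim nuclei are penalised disproportionately. Morphology
  (volume, centroid) always uses the undilated label.

## Cell segmentation: growth to the membrane limits

Each nucleus seeds a marker-controlled watershed that floods the smoothed
membrane channel, so fronts meet at membrane ridges. The growth mask stops
at the **half-maximum boundary level**: the midpoint between the image base
level (histogram mode) and the membrane ridge peak (95th percentile of
above-Otsu voxels). Half-maximum edge placement puts the measured boundary
at the membrane edge independently of the smoothing width; a plain
foreground threshold would shrink cells as smoothing increases.

Adjacent regions are then merged when their shared interface has
sub-threshold mean membrane intensity — true membranes lie at or above the
ridge threshold, whereas watershed partitions through open cytoplasm do
not. This merging is what yields multinucleated cells with the correct
nuclearity. Finally each cell is made cavity-free in 3D (`fill_holes`),
since nuclei and imperfect staining leave internal voids that belong to the
cell volume.

```{r cells}
nuc <- segment_nuclei(ph$stack)
seg <- apply_exclusions(segment_cells(ph$stack, nuc))
seg$cells[, c("id", "volume_um3", "nuclearity", "membrane_coverage",
              "excluded")]
```

### Exclusion rules

Measurement requires *complete* cells. `apply_exclusions()` flags, in order
of precedence: cells touching any stack face (`border`); cells none of
whose nuclei are surrounded by cytoplasm of the same cell
(`no_cytoplasm_nucleus`, e.g. endothelial nuclei); cells whose surface
faces above-threshold membrane signal over less than
`membrane_coverage_floor` of its area (`incomplete_membrane`); and manual
review ids (`manual`). Nothing is deleted — reasons are recorded, and
`split_cell()` / `merge_cells()` support manual correction with exact
voxel conservation.

## Ploidy classification

A control field of nuclei with known genome copy number (e.g. a haploid
sperm smear imaged with identical settings) calibrates the diploid
reference: `reference_2n_intensity = median(control) * 2 / copies`, with
the median guarding against debris and clumps. Each nucleus is then
classified by its log2 intensity ratio: candidate class
$k = \mathrm{round}(\log_2 I/I_{2n})$, accepted when
$|\log_2 I/I_{2n} - k| \le 0.35$; everything else — S-phase intermediates,
clumps — is `"unclassified"` rather than interpolated. The procedure is
scale-invariant, so a global gain shared by sample and control cancels.

```{r ploidy}
ctl <- generate_control_field(phantom_spec(shape = c(32L, 192L, 192L),
                                           n_cells = 40L, seed = 34L))
cal <- calibrate_ploidy(segment_nuclei(ctl$stack)$records,
                        control_genome_copies = 1)
cal
```

Cell-level labels combine the nucleus classes: `"2n"`, `"2*2n"` (binucleate
diploid), `"mixed"`, or `"unclassified"`.

## Summaries and repeatability

`summarize_cells()` treats the animal as the experimental unit: nuclearity
percentages and mean volumes are computed per animal first, then reported
as mean ± SD across animals (the convention is recorded in the output).
`percent_volume_difference()` reports the headline "binucleated cells were
X% larger" statistic to 3 significant figures;
`published_group_volumes()` ships a reference table of group mean volumes
for regression-testing that computation.

`match_cells()` pairs cells between two runs of the same stack by greedy
maximum overlap (minimum Jaccard 0.25) and `volume_difference_stats()`
summarises per-cell percent differences with the symmetric denominator
$100\,|V_1 - V_2| / \bar V$. A deterministic re-run yields exactly
0.00 ± 0.00%, so any nonzero repeatability figure isolates acquisition and
curation variation rather than algorithmic noise.

## Limitations

* Segmentation accuracy is validated on phantoms whose membranes are
  closed and well stained; heavily disrupted membranes will fail the
  coverage floor and be excluded rather than mis-measured.
* The phantom generator arranges near-aligned, non-overlapping cells; it
  validates the measurement chain, not crowding artefacts of real tissue.
* Densitometry assumes depth-uniform signal; stacks failing QC should be
  re-acquired rather than corrected post hoc.
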