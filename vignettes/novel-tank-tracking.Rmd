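---
title: "Tracking and phenotyping the novel tank test: methods and design notes"
author: "noveltank"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking and phenotyping the novel tank test: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(noveltank)
```

This vignette is the package's own account of its methods: the tracking model
and its assumptions, the parameters that matter and why their defaults are
what they are, what the synthetic scenes do and do not emulate, the numerical
choices, and the known limitations.

## The measurement problem

A single zebrafish swims in a rectangular tank (30 × 20 × 10 cm) filmed from
the front by a fixed camera. The scene is static except for the fish; lighting
is constant; the fish subtends a small, roughly isotropic bright (or dark)
patch of perhaps 5–15 px in a typical recording. From such a video we want a
per-frame position trace, and from the trace three behavioral readouts:
distance moved, latency to first enter the upper half of the tank, and
freezing (immobility) time.

## Tracking model

### Background removal

Every frame is converted to grayscale with fixed luma weights
(0.299, 0.587, 0.114) and held as floats on a 0–255 scale regardless of
source bit depth, so one threshold scale applies everywhere. A base frame is
subtracted as an *absolute* difference, `|frame − base|`, which makes the fish
bright whether it is darker or lighter than the background — the sign of the
contrast is a property of the lighting, not of the animal.

Two base-frame modes are offered. `"index"` takes a user-chosen frame — the
manual practice when one can find a moment with the fish absent or out of the
analyzed region. `"median"` (the default) takes the per-pixel median over an
evenly strided subsample of at most 101 frames; it equals the true static
background exactly wherever the fish spends less than half the sampled frames,
which is essentially everywhere for a moving animal in a multi-minute
recording. The median mode removes the human from the loop; its known failure
mode is a *short* clip in which the fish lingers in one spot for more than
half the frames, leaving a ghost in the base — for short clips, pass an
explicit frame or a known background raster.

### Detection

The fish is located in the difference image by a single-scale
Difference-of-Gaussians (DoG) band-pass:
\(R = G_{\sigma_s} * D - G_{\sigma_l} * D\), computed by separable convolution
with truncated (3.5 σ), renormalized kernels and half-sample-symmetric
(mirror) boundary handling. Reflection at the borders avoids the spurious edge
maxima that zero padding would create. Local maxima of \(R\) above a response
threshold are candidate features; maxima closer than a minimum separation are
merged to the strongest; and each detection is reported at the
response-weighted centroid of its connected above-threshold support region,
which gives sub-pixel localization (the weighted centroid of a symmetric
response is unbiased, and in practice lands within ~0.1 px of a rendered
blob's center).

Parameter defaults, all configurable via `detector_config()`:

| parameter | default | units | rationale |
|---|---|---|---|
| `sigma_small` | 3 | px | matches a fish body of ~5–15 px |
| `sigma_large` | 1.6 × `sigma_small` | px | the classic band-pass scale ratio |
| `response_threshold` | 5 | intensity (0–255) | well above the DoG response of moderate sensor noise, well below that of a real fish blob |
| `min_separation_px` | 8 | px | merges plateau/duplicate maxima of one body |

None of these values is derived from the original study — it reports using
the DoG approach but not its scales or threshold — so they are declared
package defaults, chosen for the stated geometry and validated on synthetic
scenes.

### Linking rules

The trajectory is assembled frame by frame from the detections under five
rules:

1. **Start-frame dropping.** Frames are discarded from the start of the video
   until exactly one feature is detected; that feature anchors the track. The
   predicate is *exactly one*, not *at least one*: an anchor chosen among
   several candidates could be the wrong one.
2. **Append.** A single detection within the jump gate extends the track
   (`source = "detected"`).
3. **Hold on empty.** With no detections the last known position is repeated
   (`source = "held"`), so held frames contribute zero distance.
4. **Nearest on multiple.** With several detections — typically the fish plus
   its reflection in the bottom glass — the one closest (Euclidean, in pixels)
   to the last known position wins (`source = "selected"`). Ties resolve by
   the detector's deterministic ordering (descending response, then row-major
   position), so the tracker has no randomness anywhere.
5. **Jump gate.** If the winning detection lies farther than `max_jump_px`
   (default 5000 px) from the last position, it is assumed to be a non-fish
   feature and the last position is held. The gate is applied uniformly to
   whichever detection wins, not only to the single-detection case — one
   consistent, conservative rule.

The gate default of 5000 px is meaningful at DSLR resolution, where a
non-fish feature (a hand, a cable) can appear thousands of pixels away. At
the 320 × 240 scale of the synthetic scenes it is effectively infinite: no
in-frame feature can ever be rejected by it. This exposes the linking rules'
one acknowledged blind spot: if, in some frame, a non-fish feature is the
*only* detection and it sits within the gate, the track jumps to it, and the
nearest-to-last rule will then keep it — there is no recovery heuristic, by
design. Users tracking at low resolution should set `max_jump_px` to a few
multiples of the largest credible per-frame displacement.

## Behavioral readouts

All metrics operate on a windowed trajectory. The assay protocol records
7 minutes and discards the first 2 (acclimation), so
`analysis_window(skip_s = 120, duration_s = 300)` is the default; the window
drops `round(skip_s · fps)` points and truncates to `round(duration_s · fps)`.

**Distance** is the sum of consecutive Euclidean pixel displacements times
`cm_per_px = width_cm / width_px`. It is translation invariant and linear in
the calibration; held points contribute zero by construction.

**Latency to the upper half** is the time from window start to the first
point with `y_px` above (numerically smaller than) the midline row, the
geometric midline of the tank ROI by default. A fish already in the upper
half scores 0. A fish that never crosses is *censored* at the window duration
rather than recorded as missing: censoring keeps group statistics computable
while the flag preserves the information. The latency clock starts at the
window start, not the recording start, so all reported metrics share one
analysis window.

**Freezing** needs a numeric operationalization of "total absence of
movement", because tracking jitter makes literal zero displacement
unattainable. A step is immobile if its displacement is below
`speed_threshold_px_per_frame` (default 0.5 px/frame — an order of magnitude
above centroid jitter on clean scenes, an order of magnitude below real
swimming displacement), and maximal immobile runs of at least `min_bout_s`
(default 1.0 s, the common practice in zebrafish behavior work) count as
freezing. Freezing time is the summed run lengths divided by fps; note the
bookkeeping is per *step*, so a fully stationary window scores one
inter-frame quantum less than its duration. Freezing is monotone in both
parameters: lowering the threshold or raising the minimum bout can only
decrease it.

## Synthetic scenes: what they emulate, and what they do not

The generator scripts a ground-truth path (straight line, seeded random walk
with reflecting walls, bottom-dweller confined below the midline, or a
scripted crossing), optionally pinned by a freeze schedule, and renders it as
background + isotropic Gaussian blob + artifacts + seeded Gaussian noise,
clipped to 0–255:

- **reflection** — a vertically mirrored blob about the tank-floor row with
  gain < 1, rendered when the fish is below an activation row; geometrically
  the failure mode a bottom-dwelling fish creates in the real assay;
- **dropout frames** — frames rendered without the fish, emulating detection
  loss (exercises the hold rule);
- **static distractors** — extra blobs appearing from a given frame onward
  (exercises the nearest-to-last rule; a distractor present from the very
  first frame would simply be absorbed into the base frame, which is the
  point of background subtraction);
- **additive Gaussian noise**, seeded, the simplest model that exercises the
  response threshold.

Everything is deterministic given the script and noise seeds.

The renderer does *not* emulate body-shape deformation (a real fish is an
elongated, bending target whose centroid wanders within the body), partial
occlusions, water-surface optics, illumination drift, or compression
artifacts. Passing the synthetic recovery tests therefore demonstrates the
correctness of the algorithmic chain — detection, linking, windowing, metric
arithmetic — not robustness to every artifact of real video. The validation
scenes use 60-s clips at 10 fps and 320 × 240 (with the analysis window set
to the full clip, since the 2-minute protocol skip cannot apply to a 60-s
clip); those sizes keep the full 20-scene recovery suite to a few minutes
while leaving per-frame localization error measurable at the 0.1-px level.
One scheduling constraint follows from the linking rules themselves: the
scenes never drop the fish in a frame where a distractor is visible, because
a distractor that is the sole in-gate detection captures the track
permanently (see the jump-gate discussion above).

## Statistics

The group-level procedures mirror how this assay's data are analyzed:

- **Two-way factorial ANOVA** (`two_way_anova()`): genotype × age fixed
  effects, fit by `lm()`. Balanced designs reduce to the classical sums of
  squares; unbalanced designs (group sizes of 8–10 are typical) use Type II
  sums of squares via `car::Anova()` — the standard choice when imbalance is
  not interaction-driven. Ratio-valued responses (redox couples) are
  log10-transformed before fitting (`log10_transform = TRUE`), reflecting
  their approximately lognormal sampling distribution. Degenerate designs
  (an empty cell, zero residual variance) raise typed errors rather than
  returning NaN tables.
- **Tukey HSD** (`tukey_hsd()`): all pairwise cell-mean comparisons of a
  chosen effect, with \(q = |\bar y_i - \bar y_j| / \sqrt{(MS_e/2)(1/n_i + 1/n_j)}\)
  and adjusted p from the studentized-range distribution. R's `ptukey()` is
  used for that distribution — it is the established numerical implementation
  of exactly the integral one would otherwise code by hand. In the two-group
  case the procedure collapses to the ordinary equal-variance t test via
  \(q = t\sqrt 2\), which the tests verify numerically.
- **Wilcoxon rank-sum** (`wilcoxon_rank_sum()`): midranks for ties; exact p
  (from the null Mann–Whitney distribution) when the pooled sample is ≤ 12
  with no ties, otherwise a normal approximation with tie and continuity
  correction. Rank-sum rather than signed-rank because the genotype groups
  being compared are independent, not paired.
- **Proteomics filtering** (`filter_protein_table()`), for a 3 + 3 replicate
  label-free design: drop contaminants and proteins with fewer than two
  unique peptides; drop proteins not detected in all three replicates of at
  least one genotype; two-sample t test and fold change
  \(2^{\overline{\log_2 KO} - \overline{\log_2 WT}}\) for proteins complete
  in both genotypes; one-sample t test for genotype-exclusive proteins. The
  one-sample null value is not specified anywhere in the source protocol, so
  the package declares one: the across-table mean of all retained log2
  abundances, the natural "no regulation" reference level when the other
  genotype provides no signal. This is a convention, and it is flagged as
  such in the output documentation.

## Metabolite quantification arithmetic

Monoisotopic masses are sums of most-abundant-isotope masses (C = 12 exactly,
H = 1.00782503, N = 14.00307401, O = 15.99491462, P = 30.97376151,
S = 31.97207069 Da). Ion m/z is `(mass − n_e · 0.00054858) / z`, with the
electron count set per entry rather than globally, because the packaged
four-row NAD inclusion list is internally inconsistent: the oxidized
dinucleotide's printed mass is a plain atomic sum, the reduced and
phosphorylated forms are one-electron-corrected, and the NADPH row matches no
single-electron convention at all (it is consistent only with removing two
electrons — almost certainly a typo at its source). The NADPH entry is
therefore stored verbatim with convention `"as-printed"` and excluded from
the package's mass-consistency checks; the other three rows reproduce their
printed values to 5 decimal places.

```{r masses}
il <- load_inclusion_list()
il[, c("name", "ion_formula", "convention", "printed_mass_da")]
round(theoretical_mz("C21H30N7O14P2", 1, "minus-1e"), 5)
```

Observed-to-theoretical matching uses a relative ppm window (default 5 ppm,
the targeted acquisition's tolerance) with the theoretical value as the
reference. Per-sample metabolite areas are normalized to protein
concentration (`area / protein_conc`); the NAD⁺/NADH and NADP⁺/NADPH ratios
are computed from *raw* areas, because both members of a ratio come from the
same sample and the protein normalization cancels algebraically — the ratios
are therefore invariant to any rescaling of the protein measurements, which
the tests assert. A zero or missing denominator flags the ratio as missing
rather than raising an error, since a failed peak is a data point, not a
programming fault. A `log10(ratio)` column is emitted for the downstream
ANOVA described above.

## Numerical choices and edge cases

- Gaussian kernels are truncated at 3.5 σ and renormalized; the discarded
  tail mass is below 5 × 10⁻⁴. The DoG implementation (separable, compiled)
  agrees with a brute-force direct 2-D convolution to better than 10⁻⁶
  relative on 64 × 64 fixtures.
- Boundary handling is half-sample mirror reflection in both the row and
  column passes; reflecting per axis is exactly equivalent to reflecting the
  full 2-D padding.
- Coordinates are 0-based pixels, origin top-left, y increasing downward;
  frame indices are 0-based. All CSV outputs state positions at six
  significant digits and masses at five decimals, and embed the tool version
  and an FNV-1a configuration hash, so reruns are byte-identical.
- Equidistant detections, plateau maxima, and tied ranks all resolve
  deterministically (detector sort order; component merging; midranks).
- Typed conditions separate user-facing failure modes: input, format, config,
  window, design, chemistry, degenerate-data, and tracking-initialization
  errors; the CLI maps them to exit codes (2 for input/format/usage, 3 for
  tracking initialization, 0 on success).

## Known limitations

- One animal, one camera, 2-D positions: no identity maintenance for multiple
  fish, no depth reconstruction, no Kalman smoothing — the linking rules are
  deliberately simple and deterministic.
- The latched-distractor case described above is inherent to the rule set;
  the gate parameter is the only defense and must be scaled to the image.
- Video containers (AVI/MP4) are not decoded; recordings enter as multi-page
  TIFF or numbered-image directories, and the frame rate must be supplied
  because those formats carry none.
- `filter_protein_table()` is restricted to the 3 + 3 replicate design it
  was written for; other designs raise a design error rather than guessing.
- The synthetic validation bounds real-world accuracy only to the extent that
  real recordings resemble the rendered model (static background, isotropic
  blob, Gaussian noise).
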