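---
title: "Methods: dual-isotope PC tracing in MALDI-MSI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-isotope PC tracing in MALDI-MSI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pctracer)
```

## The measurement problem

Stable-isotope tracing of phosphatidylcholine (PC) in lung tissue uses
two labels with very different metabolic meanings. *methyl*-D9 choline
(nine deuteriums on the three N-methyl groups) enters PC only through
de novo synthesis via the CDP:choline pathway, so a D9-shifted PC ion
is newly made lipid. Universally ¹³C-labelled DPPC, administered as
part of a therapeutic surfactant, marks the exogenous pool; its
hydrolysis products (¹³C₅-choline from the headgroup,
¹³C₂₄-lysoPC16:0 from the labelled palmitoyl backbone) can re-enter PC
pools, and re-acylation of the lyso species through the Lands cycle
produces diagnostic ¹³C₂₄ species such as ¹³C₂₄-PC16:0_20:4.

Labelled ions sit ~1 % (D9) and ~0.1 % (remodelling products) below
their unlabelled counterparts in intensity, a few mass units away, in
spectra crowded with isobaric lipid signal. Everything therefore rests
on exact-mass arithmetic: a nine-deuterium substitution shifts a
sodiated PC ion by 9 × (m(D) − m(H)) = 9.0565 Da, a ¹³C substitution by
1.0034 Da per carbon, and assignments are accepted or rejected on ppm
errors against theoretical values.

## The mass engine

Formulas are count vectors over element *and isotope* symbols: ¹³C and
D are first-class, so a label is a structural substitution
(`apply_label()` moves counts from C to ¹³C and H to D), never a mass
offset bolted on afterwards. Monoisotopic masses come from a single
constant table (AME2020 values) defined in one place; all adduct m/z
values subtract one electron mass for the +1 cations. The diacyl PC
sum-composition rule is C(n+8) H(2n+16−2d) N O₈ P for n acyl carbons
and d double bonds; chain-resolved species (`PC16:0_20:4`) carry the
same sum formula. With this table the sodiated PC32:0 lock ion
computes to 756.551376, within 0.01 ppm of the conventional printed
value 756.551374 — the residual is the difference between atomic-mass
tables, which is why the package treats agreement to 0.01 ppm as
exact.

Natural-abundance isotopologue envelopes are computed by element-wise
polynomial convolution (binomial/multinomial per element, truncated at
the requested depth, peaks reported at the ¹³C spacing). Sites already
substituted by a label are isotopically pure: a U¹³C species has
essentially no carbon contribution to its M+1. Fine structure within a
nominal mass is aggregated; that is sufficient for emulating envelope
interference at lipid masses and deliberately short of a fine-structure
isotope calculator.

## MS/MS fragment model

Sodiated and potassiated PC precursors lose trimethylamine (C₃H₉N,
nominal 59) and phosphocholine (C₅H₁₄NO₄P, nominal 183); protonated PC
yields the phosphocholine cation (nominal 184) used by precursor-ion
scans. Label atoms are routed into each loss by an explicit per-label
table: a D9 label leaves entirely with either headgroup loss (giving
nominal 68 and 192, and making the D9 fragment coincide with the
unlabelled one); a ¹³C₅ choline label contributes 3 carbons to
trimethylamine (62) and all 5 to phosphocholine (188); ¹³C₂₄ and U¹³C
labels route identically for the headgroup while the remaining
labelled carbons stay on the charged fragment. One chemical point is
worth stating because it is easy to get wrong: for ¹³C headgroup
labels the trimethylamine-loss fragment does *not* cancel to the
unlabelled value — the two choline CH₂ carbons (+2.0067 Da) remain on
the fragment; only the phosphocholine loss removes the whole
headgroup. Unknown label names require a user-supplied routing rather
than a guess. Fragment ppm errors are computed against fragments of
the *theoretical* precursor; on the values of interest the choice of
theoretical vs measured precursor does not move the rounded first
decimal.

## Imaging workflow

- **Recalibration.** Per pixel, the most intense peak within ±20 ppm
  (default; the drift amplitudes worth correcting are well inside it)
  of the lock m/z defines a multiplicative correction
  `lock/observed`. The multiplicative form matches a proportional
  (ppm-scale) drift model, so a uniformly shifted spectrum is restored
  exactly; pixels without a lock peak are flagged and left untouched.
- **Peak picking/alignment.** Defaults follow standard MSI import
  settings: peaks below 0.05 % of the dataset base peak are dropped,
  features seen in fewer than 0.5 % of pixels are dropped, and the
  alignment tolerance is 3 ppm. Clusters are seeded greedily from the
  most intense unassigned peak (the documented, deterministic
  tie-break) and collect unassigned peaks within the tolerance of the
  seed; the consensus m/z is the intensity-weighted mean. The
  frequency filter counts pixels with nonzero intensity *after* the
  relative-intensity filter. The greedy procedure is tested for exact
  agreement with a brute-force O(n²) oracle.
- **Ion images.** Symmetric closed ppm windows; per-pixel window sums.
  TIC normalisation divides by the pixel's total ion current;
  zero-TIC pixels become missing (NA), while acquired pixels without
  in-window signal are 0. Unacquired grid positions are always NA —
  missingness is never conflated with zero.
- **Hotspot clipping.** Values above the 99 % (default) quantile of
  non-missing pixels are set to that quantile. The quantile rule is
  the linear-interpolation "type 7" definition. Because the
  interpolated quantile of an already-clipped image falls slightly
  below the original cut, naive re-clipping would keep eroding the top
  pixels; the image records its `clipped_quantile` and a repeat clip
  at the same quantile is a no-op, which restores idempotence without
  abandoning the interpolated quantile.
- **Ratio images** divide pixelwise and mark zero-denominator pixels
  missing; both inputs must share a normalisation state. Ratios are
  invariant to any common rescaling, including TIC.
- **Overlays** clip (99 %), min–max scale each channel to [0, 1], and
  compose up to three images into RGB.

## Tracer statistics

`incorporation_ratio()` reports mean, sample SD and SE of the
pixelwise labelled/unlabelled ratio over a mask, excluding
zero-denominator pixels (the ratio is undefined there, not zero).
`region_fold_change()` is the ratio of regional means with a
delta-method SE. `remodeling_abundances()` expresses intensities as a
percentage of an explicitly supplied dose-reference value at time zero
— the normalisation constant is an input, not something inferred from
the table. `group_compare()` is the classical pooled-variance
two-sided Student's t-test (`var_equal = FALSE` switches to Welch),
with SDs reported as sample SDs (n − 1) throughout.

## What the phantom emulates — and what it does not

`generate_phantom()` renders a 64 × 64 grid (40 µm pixels) with three
region types: parenchyma everywhere, two circular bronchiole
cross-sections, and one elliptical surfactant-deposition blob. The
default species panel places PC32:0, PC32:1 and PC34:1 across the
tissue and restricts the polyunsaturated PC36:4 and PC38:6 to
bronchioles, reproducing the spatial segregation that makes PC36:4 a
bronchiolar marker. Defaults encode the study conditions: D9-PC32:0 at
1 % of endogenous PC32:0; the ¹³C₂₄ remodelling product at 0.1 % of
total PC32:0 (parenchyma only); deposited exogenous DPPC at 2.5× local
enhancement (the centre of the observed 2–3× range) with 7.55 % U¹³C
enrichment (the porcine-surfactant formulation; 2.87 % is the
synthetic-surfactant alternative); H:Na:K adduct ratios 0.3 : 1 : 0.25
reflecting sodiated-dominated tissue spectra; three envelope peaks per
ion; and linear acquisition-order ppm drift (default ±3, ±5 in the
stress tests) emulating slow calibration drift.

Noise is multiplicative and two-level: one shared log-normal draw per
species and pixel (CV 0.2) that every adduct, isotopologue and derived
label signal of that species inherits — shot-to-shot MALDI variability
acts on the ablated material as a whole — plus an independent
per-peak log-normal detection noise (CV 0.02, the order of Orbitrap
centroid repeatability). The split matters statistically: the mean of
pixelwise ratios under *independent* numerator/denominator noise is
biased upward by exp(σ²); keeping the independent component small
keeps that bias an order of magnitude below the standard error of the
regional means, so the estimator the package reports is unbiased for
the configured fractions at the phantom's size. Labelled fractions are
applied to the noised parent signal, which is what makes them exact
per-pixel quantities with known sampling behaviour.

The phantom does not simulate matrix cluster peaks, profile peak
shapes, detector saturation, co-isolation in MS/MS, spatial noise
correlation, or fine isotope structure. Passing the recovery tests
therefore demonstrates that the *pipeline arithmetic* (recalibration,
alignment, windowing, normalisation, ratio statistics) is faithful
under realistic intensity variability and drift — not that the
package would segment real histology or resolve real isobaric
interferences beyond what exact mass separates.

`generate_shotgun_profiles()` is the tabular counterpart for the
macrophage remodelling analysis: eight samples per group, species
means expressed as percent of the administered tracer at t = 0
(defaults 38.7 / 36.8 / 24.5 % for the tracer and its two
re-acylation products), mean-preserving log-normal variability
(CV 0.2). Recovery within 3 SE holds in ≥95 % of seeded replicates by
construction.

## Numerical and interface choices

- Pixel coordinates are 0-based image convention (x right, y down);
  imzML's 1-based positions are shifted on read and restored on write.
- Binary storage is 64-bit m/z / 32-bit intensity little-endian floats
  (common practice); round trips are bit-exact at those widths. The
  ibd UUID is content-derived (MD5 of the payload), recorded in both
  files, and verified on read; profile-mode files are rejected rather
  than mis-centroided.
- Determinism: both generators take an explicit seed, record it in
  their output, and restore the caller's RNG state.
- Display convention: 4 decimals for m/z, 1 decimal for ppm.
- Problem sizes in the test suite (toy datasets of ≤100 peaks for
  oracle comparisons, 6×6–16×16 phantoms for property tests, one
  64 × 64 phantom for the end-to-end recovery) were chosen so the
  statistical checks have the power they claim while the whole suite
  stays interactive.

## Known limitations

Only diacyl PC in positive-ion mode is modelled; ether/lyso classes,
other phospholipid classes, negative mode and multiple charging are
out of scope (lysoPC appears only implicitly, inside neutral-loss
building blocks). sn-position and double-bond localisation are not
attempted. The imzML writer always emits processed mode. Alignment is
greedy rather than globally optimal — adequate at 3 ppm tolerances
with well-separated lipid features, and deliberately deterministic.
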