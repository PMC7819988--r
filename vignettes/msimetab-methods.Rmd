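---
title: "Methods: models, parameters and design choices in msimetab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in msimetab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msimetab)
```

msimetab implements a complete MALDI-FTICR mass spectrometry imaging (MSI)
metabolomics workflow for two-group tissue comparisons — the setting of a
dystrophin-deficient (DMD) muscle study with nine child patients and nine
adult controls — together with a ground-truthed synthetic data generator, so
that every stage can be exercised and validated without access to raw
imaging data. This vignette explains the underlying models, the parameters
that matter, and the design decisions taken where more than one reasonable
choice existed.

## Exact-mass arithmetic

All mass computation is monoisotopic. The packaged element table carries
CODATA/AME monoisotopic masses to at least seven decimals, plus the electron
mass as a distinct entry. An adduct ion's m/z is

$$ m/z = \frac{M + m_\mathrm{added} - m_\mathrm{removed} - z\, m_e}{|z|} $$

with the electron term mandatory: FTICR reference masses are
proton-accurate, and dropping the ~0.549 mDa electron correction produces
errors of roughly 1 ppm at m/z 500 — larger than the instrument's accuracy
and easily visible against published calibration lists. Formula strings are
flat Hill notation (no brackets, isotopes or charges), which covers every
species the workflow handles. Relative mass errors use the convention
(observed − theoretical)/theoretical, with ppb defined as exactly
1000 × ppm.

## Annotation

MS1 annotation scans the compound database over the adducts allowed per
ionization mode ({[M+H]+, [M+Na]+, [M+K]+} in positive mode, {[M−H]−} in
negative mode) and keeps every candidate within a ±2 ppm window, ranked by
absolute error with ties broken by compound id. MS/MS evidence uses
fragmentation rules whose neutral-loss masses (trimethylamine 59.073499 Da,
phosphocholine 183.066045 Da — the diagnostic head-group losses of
phosphatidylcholine and sphingomyelin lipids) and diagnostic-fragment m/z
are recomputed from molecular formulas at load time, never hard-coded. The
default MS/MS tolerance is 500 ppb: published worked examples show loss
errors in the 180–370 ppb range, so 500 ppb covers them with margin while
remaining four times tighter than the MS1 window.

Consolidation mirrors the "unambiguously identified" policy: a single MS1
candidate stands; multiple candidates are resolved only when fragmentation
rules discriminate by compound class; anything else is flagged ambiguous
with all competitors retained, rather than auto-picked.

The packaged database (63 species) contains the named study metabolites
(ATP, ADP, CMP, glycerophosphocholine, adenosine tetraphosphate, inositol
tetrakis- and pentakisphosphate, phosphoribosyl pyrophosphate,
LysoPC(20:4), representative PC/SM/PA/PS/TG species, carnitine,
acetylcarnitine, phosphocholine), additional non-differential species, and
the MALDI matrix ions (DHB and its clusters in positive mode,
9-aminoacridine in negative mode). It is a plain TSV and user-extensible.
Three published calibration entries are internally inconsistent (one with
an apparently dropped digit, two off by one water mass between formula and
printed m/z); they are excluded from the packaged calibrant list rather
than silently repaired, since it cannot be decided which field is wrong.

## The synthetic cohort generator

The generator emulates the study design: 9 patients (ages 5.5 ± 1.9 years)
vs 9 adult controls (ages uniform on 28–58), a panel of 59 metabolites of
which 34 are truly differential — 27 up and 7 down in patients — plus
ubiquitous matrix ions. Per pixel, each species contributes one centroided
peak:

- m/z: theoretical adduct m/z × (1 + per-sample calibration offset +
  per-peak jitter), with jitter SD 0.3 ppm (FTICR-grade) and per-sample
  offsets of SD 1 ppm that the recalibration stage must remove;
- intensity: exp(base + group effect + age drift + sample-level noise +
  pixel-level noise) × pixel TIC scale.

Intensities are log-normal because the downstream analysis log-transforms —
multiplicative noise is the simplest generative match. Three variance
components are deliberately distinguished:

- `sigma_sample` (default 0.4): biological between-sample SD per compound;
- `sample_scale_sdlog` (default 0.5): a *technical* per-sample factor
  (matrix deposition, ion yield) shared by every species of a sample —
  precisely the variation TIC normalization exists to remove;
- `sigma_pixel` (0.3) and a per-pixel TIC scale (log-SD 0.3) for
  within-section structure.

Matrix ions are given a high base intensity so that they dominate the
pixel TIC, as they do in real low-mass MALDI spectra, and only a small
sample-level SD of their own (0.1): they carry no biology. Both choices
matter for the realism of TIC normalization — if analytes dominated the
TIC, normalization would induce a strong compositional (closure) bias that
the real workflow does not exhibit.

Default effect sizes are ±2 × `sigma_sample` (a two-standard-deviation
shift, |Δlog| = 0.8 ≈ 2.2-fold). Seeds are hierarchical: one master seed;
per-(sample, mode) child seeds derived by counter, so partial regeneration
is stable and the full dataset is bit-reproducible.

What the generator does **not** emulate: isotope envelopes, profile-mode
peak shape, detector saturation, spatially structured biology (a two-region
mask is available but off by default), and any correlation structure among
metabolites beyond the shared TIC/technical factors. Passing tests
therefore demonstrate the pipeline's statistical and numerical behaviour
under a faithful but simplified data-generating process, not performance
on real tissue sections.

### Ages and confounding

The emulated cohort confounds age with group almost perfectly (children vs
adults; point-biserial R² ≈ 0.90). With age as a covariate this inflates
the SE of the group contrast ~3.6-fold, so *no* effect size expressed in
residual-SD units can reach conventional power: at 2-SD effects the
age-adjusted test has ≈ 0.23 power even unadjusted for multiplicity. This
is a property of the study design, not of the implementation. The
generator therefore exposes `age_scheme`: `"cohort"` (default; the
emulated study) and `"balanced"` (both groups drawn from the same age
distribution, giving an estimable contrast). Operating-characteristic
validation (power, direction recovery, clustering) is run under the
balanced scheme; the cohort scheme is used to verify FDR control and to
demonstrate the cost of confounding via the `age_drift` knob, under which
the covariate-adjusted model correctly rejects far less often than a naive
two-sample test.

## Preprocessing

**Recalibration.** Single-point recalibration (the default, matching
common vendor practice) matches calibrants within a 5 ppm search window
and applies the uniform multiplicative correction that zeroes the error of
the most intense matched calibrant peak (ties broken toward lower m/z). A
linear model (least-squares ppm drift vs m/z over all matched calibrants)
is available. Spectra with no matched calibrant are passed through
unchanged and flagged, never silently corrected. The packaged calibrant
list is validated at load: stored m/z must agree with the formula-derived
value to 1e-5 Da.

**TIC normalization.** Each pixel is scaled so its total ion current
equals the dataset mean TIC (or 1), preserving within-pixel ratios;
zero-TIC pixels are excluded and counted.

**Binning.** All peaks across pixels and samples are clustered on the m/z
axis: sort, split at relative gaps exceeding the tolerance (single-linkage
in one dimension), recenter each cluster on its intensity-weighted
consensus, then extract the feature from the ±1 ppm *interval* around the
consensus, excluding stray tail peaks — the interval semantics of vendor
MSI software ("m/z intervals set at ±1 ppm"). Splitting (rather than
trimming) at the tolerance would shatter dense peak clouds: with 0.3 ppm
jitter and tens of thousands of peaks per species, extreme peaks sit
beyond ±1 ppm of the consensus with near-certainty, while the species'
neighbours are tens of ppm away. Trimming loses ≈ 1–2% of tail intensity
and reassembles exactly one feature per planted species at default noise.
The procedure is deterministic and independent of sample order, and is
audited against a brute-force single-linkage oracle in the test suite.

Per sample, a feature's value is the mean intensity over **all** of the
sample's pixels (absent peaks contribute zero), matching whole-section
average reporting; cells still zero after aggregation are imputed at half
the smallest positive cell of the matrix (a standard metabolomics floor)
so the subsequent natural-log transform is defined everywhere.

## Statistics

Differential testing fits, per feature, ordinary least squares of log
intensity on a patient indicator plus age, and tests the group coefficient
two-sided on n − 3 residual degrees of freedom — the standard
operationalization of "t-test with age as covariate". Omitting the
covariate reduces exactly to the pooled-variance two-sample t-test (this
equivalence is tested). Degenerate fits (zero residual variance) are
flagged per feature with missing p-values that propagate through the FDR
step without entering the family size.

FDR control defaults to Benjamini–Yekutieli — the arbitrary-dependence
variant, inflating Benjamini–Hochberg by the harmonic factor c(m) — because
metabolite intensities are strongly correlated and the hyphenated method
name in the source protocol points to the Yekutieli correction;
Benjamini–Hochberg is selectable and the choice is echoed in the run
manifest. Note that BY is conservative: at n = 9/9 and 2-SD effects over a
~60-feature panel its expected per-feature detection power is ≈ 0.75–0.8,
whereas BH reaches ≈ 0.9; both are reported by the acceptance script.

Known MALDI matrix/background ions are excluded from the tested family
before FDR adjustment: they are identified a priori and are not candidate
metabolites, and through the TIC closure effect they would otherwise
appear as spuriously "significant" near-constant features.

Co-expression uses Spearman rank correlation (average ranks on ties);
zero-variance features yield missing correlations rather than arbitrary
values. Sample clustering is agglomerative on Euclidean distances over the
significant-feature vectors (complete linkage by default, configurable to
ward.D2/average/single — the source protocol does not state a linkage);
samples are ordered lexicographically by id beforehand so the tree is
deterministic. Trees export as Newick via ape.

## Pipeline and reproducibility

`run_pipeline()` chains simulate/ingest → recalibrate → normalize → bin →
annotate → test → correlate/cluster → render, writes stage CSVs, ion-image
PNGs and a JSON manifest (config echo, seed, package version, per-stage
log, md5 checksums), and is a pure function of (config, seed): identical
inputs give bit-identical CSV outputs. Stage outputs can seed a fresh run
from files, so no stage depends on hidden state. Ion images sum peak
intensity per pixel within a ±1 ppm window around a feature's m/z.

A minimal imzML 1.1 writer/reader (processed mode, centroided spectra,
64-bit arrays addressed by external offsets into an .ibd file) is
implemented in-package for interchange, alongside a plain-CSV dialect
(`sample,x,y,mz,intensity` with 17-significant-digit numerics so doubles
round-trip exactly).

## Numerical choices and problem sizes

Display rounding of m/z is 6 decimals; all comparisons use full precision.
Binning and annotation tolerances are half-windows in relative units.
The test-suite and acceptance computations use scaled-down problem sizes
chosen as the package's own validation design: per-sample grids of 3×3 to
12×12 pixels (the generator's default is 40×40), 50 zero-effect replicates
for null calibration, and Monte-Carlo checks over 12–40 seeds. At these
sizes pixel-level noise is already negligible after within-sample
averaging, so operating characteristics match the asymptotic-in-pixels
regime while the whole suite runs in minutes.

## Known limitations

- Annotation is accurate-mass plus class-level MS/MS rules; it does not do
  spectral-library matching, isotope fine structure, or multiply charged
  species.
- The OLS covariate model assumes homoscedastic Gaussian log intensities;
  no empirical-Bayes variance moderation is applied (n = 9/9 per group is
  large enough for per-feature variance estimation at the simulated noise
  levels).
- Under the cohort age structure the age-adjusted group contrast is close
  to unidentifiable (see above); no statistical method can recover
  moderate effects from that design, and the package makes the cost
  visible rather than hiding it.
- The imzML implementation covers the subset of the standard the package
  emits (processed mode, centroided spectra, 64-bit external arrays); it
  is an interchange convenience, not a general-purpose reader for vendor
  files.
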