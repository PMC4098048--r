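---
title: "silpair: methods, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{silpair: methods, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(silpair)
```

## The measurement model

`silpair` processes centroid MS¹ LC–HRMS runs of 1:1 (v/v) mixtures of a
native and a uniformly ¹³C-labelled metabolome. Because labelled and
non-labelled isotopologues of one metabolite are chemically identical,
they co-elute perfectly and appear in every spectrum as two mirror-imaged
isotopic patterns per ion species:

* the native pattern anchored at the monoisotopic ion M, with intensity
  ratios following a binomial distribution in the number of carbon atoms
  `n_C` at the natural ¹³C probability `p_nat` (default 0.0111, i.e.
  98.9 % ¹²C / 1.1 % ¹³C); to first order, `M+1/M = n_C · p/(1−p)`;
* the labelled pattern anchored at the fully labelled ion M′ at
  `m/z(M) + n_C · 1.00335/z`, descending towards lower mass with
  `M′−1/M′ = n_C · (1−p_enr)/p_enr` at the enrichment `p_enr`
  (default 0.995).

Everything in the package follows from this twin structure: the spacing
between M and M′ gives the carbon count, the spacing `1.00335/z` of the
inner isotopologues gives the charge, the presence and correct intensity
of *both* tails separates metabolites from background, and the M/M′ area
ratio is a built-in internal standard per metabolite ion.

The direct assignment of `n_C` requires M and M′ to be unambiguous
anchors of their patterns. `max_direct_carbon(p)` returns the largest
carbon count for which the residual M′−1 signal does not exceed M′,
`floor(p/(1−p))` — 49 carbons at 98 % enrichment, 5 at 85 %. We
implement the parity-inclusive floor because the expected ratio equals
1.0 exactly at the bound for p = 0.98; counts beyond the bound are still
detectable but their anchors are ambiguous.

## Pipeline stages and parameters

All defaults are collected in `pipeline_config()`; each stage takes its
own parameter object.

### Scan-level signal pairs — `pair_params()`

| parameter | default | meaning |
|---|---|---|
| `min_intensity` | 5,000 counts | threshold on M *and* M′ |
| `min_scans` | 3 | scans a pair must be seen in (enforced at clustering) |
| `ppm` | 2.5 | m/z matching tolerance |
| `abundance_tol` | 0.20 | relative isotopologue-ratio tolerance |
| `z_range` | 1–3 | candidate charges |
| `nc_range` | 1–60 | candidate carbon counts |

A pair is emitted for peak M, charge z and count n only when (a) M′
exists at `+n·1.00335/z` above threshold, (b) M+1 exists with a ratio to
M within tolerance of the natural expectation, and (c) M′−1 exists with
a ratio to M′ within tolerance of the enriched expectation. The
"±20 %" tolerance on a ratio needs a sidedness convention; we accept
`observed/expected` in `[1−tol, 1/(1−tol)]` (= [0.80, 1.25] at the
default), a band symmetric on the ratio scale and invariant under
inverting the ratio. M+1 and M′−1 must be *present* with valid ratios
but are not themselves thresholded; low-abundance principal ions lacking
visible tails are deliberately not detected (the count of true pairs is
thus an underestimate — the price of selectivity). One peak may seed
pairs at several (n, z) in pathological spectra; ties on the same
spacing go to the smaller charge, and de-isotoping resolves the rest.

### m/z clustering — `cluster_pairs()`

Scan-level pairs are partitioned by exact (n_C, z), then clustered on
their monoisotopic m/z with average-linkage hierarchical clustering. The
tree is cut top-down: any node whose members deviate more than ±10 ppm
from the node mean is split into its children. Clusters with fewer than
`min_scans` members are discarded. Average linkage was chosen as the
conventional compromise for one-dimensional m/z agglomeration; the split
criterion is exactly the ±10 ppm rule.

### Chromatographic confirmation — `feature_params()`

XICs are extracted for the cluster mean m/z and its labelled partner
with a ±5 ppm window (`xic_ppm`, twice the matching tolerance, so that
jittered centroids are not clipped at peak flanks; per-scan intensities
within a window are *summed*, which is deterministic and robust to
centroid splitting). Peaks are picked with a Mexican-hat continuous
wavelet transform: responses at scales `c(2, 3, 4, 6, 8, 12)` scans,
ridge lines linked from coarse to fine, ridges shorter than 3 scales or
below SNR 3 (ridge maximum over the MAD of the finest-scale
coefficients) are rejected; boundaries are raw-trace minima within three
scale-widths of the apex, and areas are trapezoidal sums of the raw XIC
between the boundaries (no Gaussian re-fit). Wavelet peak pickers have
no canonical parameterisation; these settings are exposed in
`feature_params()` and fixed in the tests.

An M peak is paired with the nearest M′ peak within ±15 scans (ties
toward the larger M′ area) and confirmed when the Pearson correlation of
the two shapes exceeds 0.5. The correlation window is the union of the
two boundary windows with absent scans as zero — a deliberate choice
penalising shape mismatch at the peak edges, where the window itself is
otherwise undefined.

### De-isotoping and grouping

An M+1 feature mistakenly picked as monoisotopic (or M′−1 as fully
labelled) shows `n_C` one lower and an m/z higher by `1.00335/z` (or
unchanged). `deisotope()` removes a pair iff a co-eluting pair with one
more carbon and the matching m/z relation exists *in the original list*:
a single pass with no cascade, hence idempotent and order-independent.

`group_features()` connects two pairs when their apexes lie within ±10
scans and their M peak shapes correlate at r ≥ 0.85; feature groups are
the connected components (single linkage), chosen for order
independence. The partition property — every pair in exactly one group —
is tested. Pairs at neutral mass > 700 u with fewer than 10 carbons are
chemically implausible and flagged (`plausibility_flag()`), not removed:
in blank measurements such pairings are the signature of correlated
artefacts that survive the shape filters.

### Bracketing — `bracket_params()`

Features are matched across samples by n_C (exact), m/z (±10 ppm) and
retention time (±9 s = 0.15 min), in that order. The key order is part
of the workflow definition; the tolerances are the ones conventionally
used for cross-method feature matching and are exposed. Matching is greedy
from the strongest total area (a deterministic anchor choice favouring
reliable features), at most one member per sample, consensus m/z and
retention time as intensity-weighted means. Brackets never mix n_C or z.
Missing cells are re-integrated in a targeted way: peaks picked in the M
and M′ XICs within the bracket's rt window, without abundance-ratio or
shape checks; we still enforce the ±15-scan co-elution of M and M′
(consistent with the primary path — the procedure is silent here).
Nothing found leaves the cell `NA`: no imputation, ever.

### Internal standardisation and evaluation

`internal_standardise()` divides, per file and feature pair, the ¹²C
area by the ¹³C area; zero or missing denominators leave the cell
undefined. `cv_summary()` computes per-feature CVs over replicates
(sample n−1 standard deviation — the appropriate estimator for the small
replicate counts typical here) on features complete in all replicates,
bins them at 5 % with everything above 120 % capped into the overflow
bin, and reports the median and 90th percentile. `range_scale()` applies
`(x − mean)/(max − min)` per feature (constant rows dropped with a
warning); `pca_scores()` performs covariance PCA with samples as
observations and draws per-group 95 % covariance ellipses in the PC1/PC2
plane (confidence level fixed at 95 %, the usual plotting convention
for group ellipses).

The key property, tested exactly: multiplying every intensity of one
run by any constant — which is what a multiplicative matrix effect or
injection-volume drift does — changes both areas of every pair equally
and leaves the ratio matrix bit-for-bit unchanged, while raw-area CVs
inflate.

## What the simulator emulates — and what it does not

`generate_run()` produces centroid runs from `metabolite_spec()` panels:
Gaussian elution profiles (σ 3–6 scans in the random panels), up to
three ESI species per metabolite from the default adduct table
([M+H]⁺, [M+Na]⁺, [M+H−H₂O]⁺, [M+2H]²⁺), full binomial isotopologue
ladders on both anchors truncated below 10⁻⁴ relative abundance,
per-peak uniform m/z jitter of ±1 ppm (below the 2.5 ppm tolerance),
isolated chemical-noise peaks, centroid merging below 0.0015 u, and a
per-sample matrix multiplier `exp(N(0, σ²))` on all intensities. The
native ladder is additionally scaled by a per-sample biological factor
while the labelled ladder is constant — the labelled material is a
pooled reference mixed 1:1 into every sample, which is exactly the
design that makes internal standardisation cancel matrix effects but
retain biology. Runs are byte-identical under a fixed seed, and every
generated ion is recorded in a ground-truth table for end-to-end
scoring.

`random_metabolites()` draws carbon counts uniformly (5–60 by default)
and neutral masses at 13.2–14.5 u per carbon — a deliberately compressed
stoichiometry (real metabolites range from ~14 u/C for apolar lipids to
30 u/C for sugars) chosen so that even 60-carbon singly charged ions stay
inside the simulated 100–1,000 m/z scan range. Apex abundances are
log-uniform between 10⁵ and 5·10⁶ counts
(so all four isotopologue anchors clear the 5,000-count threshold), and
retention times from a shuffled grid with ≥ 15 scans separation. The
grid is a stated-world choice: shape-correlation grouping convolutes
*any* co-eluting, correlated features into one group, so distinct
metabolites must be chromatographically resolved for "one group = one
metabolite" to be a meaningful check. Real chromatograms violate this —
co-eluting isomers and coincidental overlaps merge groups — which is a
known limitation of the grouping concept itself, not of the test.

The simulator does not model profile-mode peak shapes, Orbitrap
resolution/transient effects, Fourier-transform artefacts, retention
time drift between samples (the underlying workflow assumes negligible
shifts and performs no warping), detector saturation, or electrospray
adduct chemistry beyond fixed relative species intensities. A green
end-to-end test therefore establishes the correctness of the *data
processing* under the stated measurement model, not instrument-level
robustness.

## Numerical choices and degenerate inputs

* Mass constants at 5-decimal precision: Δ(¹³C−¹²C) = 1.00335 u, proton
  1.00728 u; only carbon is modelled (no S/Cl isotope corrections),
  because the pattern verification is carbon-only.
* `carbon_count()` accepts a rounded count only when the residual
  spacing error, on the m/z scale at M′, is within the ppm tolerance;
  counts < 1 are rejected as `NA`.
* Peak-shape correlations on zero-variance segments are defined as 0
  (no pair / no edge) rather than `NA`.
* Empty XICs, empty scans, empty cluster or pair tables flow through
  every stage as valid empty results; errors are reserved for malformed
  inputs (profile-mode data, unknown adducts, < 2 replicates, unmatched
  design entries).
* The mzML/mzXML layer is a minimal hand-written reader (no
  mass-spectrometry I/O package is available in the target environment):
  both dialects, 32/64-bit floats, zlib-compressed arrays and gzipped
  files, retention times normalised to seconds, MS² skipped, 0-based
  scan indices, profile-mode data rejected with an explicit error. The
  writer emits uncompressed 64-bit mzML that round-trips losslessly.

## Known limitations

* Charges above 3 and carbon counts above 60 are outside the default
  search space (both configurable).
* Metabolites whose every ion species falls below the intensity
  threshold in more than all-but-three scans are invisible to the
  primary path (recoverable only via bracketing re-integration when
  detected in some sample).
* Grouping cannot separate perfectly co-eluting distinct metabolites.
* Adduct identities within a group are not assigned (the grouping is
  species-agnostic), and no sum formulas are generated.
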