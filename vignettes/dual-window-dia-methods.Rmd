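---
title: "Dual-window DIA design and isotope-dilution quantification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-window DIA design and isotope-dilution quantification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualdia)
```

This vignette is the package's account of its models, parameters and
numerical choices: what is computed, why the defaults are what they
are, and what the synthetic tests do and do not demonstrate about real
instrument data.

## The acquisition model

A DIA *window scheme* is an ordered set of half-open isolation
intervals `[start, end)` covering a scan range (default 400–1000 Th).
Two window kinds coexist:

* **narrow target windows** (default 4 Th) that isolate one precursor
  of a light/heavy isotope pair each, and
* **wide profile windows** that tile everything else for untargeted
  profiling.

A spiked heavy internal standard is chemically identical to its light
endogenous twin but mass-shifted by the label: +8.014199 Da for
C-terminal ¹³C₆¹⁵N₂-lysine, +6.013809 Da for ¹³C₅¹⁵N₁-glutamate
(both computed from the ¹³C–¹²C and ¹⁵N–¹⁴N nuclide mass
differences). At charge *z* the precursor spacing is `shift / z` —
4.0071 Th for heavy-Lys at 2+. When both precursors fall into one
window ("coisolation") their fragment spectra overlap: a C-terminal
label shifts every y-ion but no b-ion, so all b-ions coincide exactly
and only y-ions remain usable. Separating the pair into adjacent
narrow windows restores the full fragment series to both channels;
`classify_pair_fragments()` encodes this and is verified against a
brute-force per-fragment m/z comparison in the tests.

### The narrow-window grid

Narrow windows come from a single global grid: boundaries at
`anchor_offset + k * narrow_width`. The default anchor offset of
1.0 Th with width 4 puts boundaries at ..., 453, 457, 461, ... — the
one simple rule that simultaneously yields the two reference
placements 453–457/457–461 (ITDFGRAK 2+, 454.25/458.26) and
513–517/517–521 (ELREATSPK 2+, 515.78/519.79). Both parameters are
configurable.

The half-open convention makes shared boundaries unambiguous: an m/z
exactly on a boundary belongs to the right-hand window.

Heavy-Lys 2+ pairs (spacing 4.0071 > 4) always occupy distinct grid
cells; in the rare case where the light m/z sits within 0.0071 Th
below a boundary the cells are distinct but not adjacent, which still
separates the pair. Labels whose spacing is *below* the narrow width
(heavy-Glu at 2+/3+: 3.007/2.005 Th) can land in the same cell; the
designer then re-anchors the pair's two windows locally so their
shared boundary is the midpoint of the two m/z values, and flags them
`off_grid`. This preserves pair separation — the design's defining
guarantee — at the cost of a local departure from the global grid.

### Wide-window allocation

After the narrow blocks are placed, the remaining gaps are tiled by a
fixed budget of wide windows (`n_wide`):

1. windows are apportioned across gaps by **largest remainder** on the
   gap's precursor-density mass (gap width when no density is given),
   clamped to the per-gap feasible count range — this conserves the
   total count exactly, by construction;
2. inside each gap, boundaries sit at equal
   **cumulative-density quantiles**, so each window carries roughly
   equal precursor load (the rationale behind variable-window DIA);
3. widths are clamped to `wide_bounds` with iterative redistribution,
   falling back to an equal split of the gap if redistribution cannot
   converge (always feasible given step 1's count bounds).

The density is interpreted as a piecewise-linear weight function of
m/z, integrated by trapezoid on a 4096-point grid; with a uniform
density the construction reduces exactly to the equal-width scheme,
which the tests assert.

`wide_bounds` defaults to `c(0, Inf)`: with a small window budget a
single wide window may legitimately span hundreds of Th, and any
instrument-style clamp (say 4–60 Th) would make such designs
infeasible by default. Users targeting a real method editor should
pass their instrument's limits explicitly; the designer then errors —
naming the gap — when the budget cannot tile a gap within bounds.

The total window budget is deliberately a free parameter rather than
a constant: published dual-window methods use both 36 (16 narrow +
20 wide) and 40 windows for the same 400–1000 range, so no canonical
count is assumed. Acquisition order is ascending m/z; duty-cycle
optimization and RT scheduling are out of scope.

## The quantification model

Absolute amounts come from stable-isotope dilution with external
calibration:

* **L/H ratio** — summed light transition areas over summed heavy
  areas across a chosen fragment set. Under a coisolating scheme the
  set *must* be restricted to channel-unique ions (the y-series for
  C-terminal labels); `lh_ratio()` errors when the restriction empties
  the set. Summation (not a per-fragment median) is used; the ratio is
  invariant to the subset chosen when channels are proportional, which
  a brute-force subset test verifies.
* **Calibration** — unweighted ordinary least squares of the
  replicate-mean ratio per nonzero level against nominal amount
  (`y = m·x + b`), with `r_squared`, `sy_x = sqrt(RSS/(n-2))`, and
  optional 1/x weighting or replicate-level fitting. Blanks
  (0 fmol levels) are excluded from the fit and reserved for `s_a`,
  the standard deviation of blank ratios; detection limits follow
  `LOD = 3·s_a/m` and `LOQ = 10·s_a/m`, so `LOQ/LOD = 10/3`
  identically. With fewer than two blank replicates LOD/LOQ are
  reported as unavailable rather than imputed.
* **Interpolation** — `amount = (ratio − b)/m`, concentration =
  amount / sample peptide mass (fmol/µg). Amounts below LOD/LOQ or
  outside the calibrated range are *flagged*, never clipped: a ratio
  below the blank mean yields a negative amount carrying `below_lod`,
  keeping the audit trail honest.
* **Reporting conventions** — m/z rounds half-up to 2 decimals,
  mutant/WT ratios to 1 decimal, mutant fractions to integer percent.
  All internal arithmetic keeps full double precision.

An unweighted fit over a wide dynamic range (0.5–500 fmol) lets the
top calibrators dominate the intercept, which degrades low-fmol
accuracy; this is a property of the estimator, not a bug. The tests'
QC closure therefore evaluates a 2.5 fmol sample against 0.5–25 fmol
calibrators, the design matched to that working range.

## Spectrum and profiling metrics

* **Cosine similarity** — dot product of intensities after greedy
  nearest-m/z matching (default tolerance 0.02 Th; candidate matches
  accepted in order of increasing m/z difference, each peak used
  once). Unmatched peaks keep their weight in the norms, so the score
  lives in [0, 1], is symmetric, and is scale-invariant. Plain
  intensities are used; whether square-root weighting (the dotp
  variant some vendor tools use) would better match vendor scores is
  unknowable from their documentation, so the simpler definition was
  chosen.
* **XIC area** — trapezoid over the peak bounds, optionally minus the
  linear baseline between the boundary intensities; additive over
  interval splits when the baseline is off.
* **S/N** — `(apex − median(background)) / max(1.4826·MAD, ε)` with
  ε = 0.01 and ≥5 flanking background points per side. This is the
  package's own estimator (vendor software computes S/N internally
  and undocumented), so its absolute values are not comparable to
  instrument-software S/N figures.
* **Pathway z-scores** — per protein across samples using the sample
  SD (zero-variance proteins contribute 0 with a warning); a
  pathway's per-sample score is the mean member z.
  `normalize_abundance()` provides the standard log2 + per-sample
  median-centering upstream; it is kept separate so z-scoring degenerate
  single-protein matrices behaves predictably.
* **DEP filter** — two-sided Wilcoxon rank-sum per protein,
  Benjamini–Hochberg adjustment, significance requiring *both*
  |log2 FC| ≥ 1 and adjusted p ≤ 0.05. No imputation is performed by
  default (missing values are excluded pairwise); imputation is a
  deliberate plug-in point rather than a hidden default, since
  imputer choice materially changes downstream statistics.

## The simulator: what it emulates, and what it does not

The simulator exists so the entire workflow can be exercised without
raw files. It emulates:

* target panels — random tryptic-like sequences (C-terminal K or E,
  no internal cleavage sites), 7–14 residues, precursors inside the
  scan range, pairwise separation ≥ 12 Th (three grid cells) so each
  precursor occupies its own narrow cell;
* acquisition — precursors assigned by the half-open rule; composite
  per-window MS2 spectra as amount-weighted sums of per-species
  fragment profiles (relative intensities drawn once per species from
  a seeded distribution: b-ions 0.05–0.6, y-ions 0.2–1, reflecting
  the typical y-dominance of HCD spectra); an interference report
  counting per-pair fragment collisions within 0.02 Th in the same
  window;
* calibration series — `ratio = (m·x + b) · LN(1, cv)` with mean-one
  lognormal noise, defaults mirroring a 0.5–500 fmol serial dilution
  with a fixed 25 fmol heavy spike, three replicates per level, plus
  blanks `N(b, sd)` truncated at 0;
* chromatograms — Gaussian peaks of exact area over a constant
  background of `5·noise_sd` (the offset keeps the noise distribution
  intact after the nonnegativity clamp).

It does **not** model real fragmentation chemistry, isotope
envelopes, retention-time drift, ion suppression, interference from a
background proteome (background species can be added explicitly but
no chemical noise is injected), or detector saturation. Passing tests
therefore demonstrate the *correctness of the computational
machinery* — window geometry, fragment bookkeeping, estimator
algebra, closure of the simulate→design→acquire→ratio→calibrate→
quantify loop — not instrument-level figures of merit. Published
LOD/LOQ, S/N or proteome-coverage numbers from real acquisitions are
intentionally not asserted anywhere in the test suite.

## Numerical choices and problem sizes

* Monoisotopic residue masses to 8 decimals; water 18.0105646863,
  proton 1.00727646688 Da. Fixed modifications (e.g. methylthio-C,
  +45.98772) are configurable and off by default — none of the
  reference peptides contain cysteine.
* Trypsin follows the Trypsin/P convention (cleaves before proline)
  by default, matching common DIA search settings; the classical
  no-P rule is a flag. GluC cleaves after E only by default
  (bicarbonate-buffer specificity); E+D is a flag.
* Variant panels digest with ≤2 missed cleavages, keep peptides of
  7–52 residues whose 2+ or 3+ precursor falls in the scan range, and
  record a reason for every exclusion. Heavy labels follow the
  C-terminal residue; peptides ending in R (tryptic) have no heavy
  twin here and are excluded with that reason.
* All generators draw through an isolated RNG scope keyed by an
  integer seed, so identical seeds give byte-identical outputs and
  the caller's RNG stream is untouched.
* Stochastic tests run 1000-replicate simulations at 5 % CV — large
  enough for stable means, small enough for a desk-scale suite; their
  tolerance bounds (slope mean bias < 1 %, per-seed slope error < 8 %,
  QC mean |RE| < 5 %, max < 20 %) were frozen from an independent
  plain-R oracle simulation of the same estimator before being
  asserted.

## Known limitations

* The narrow-window budget limits panel size: with 4-Th windows and a
  ~40-window duty cycle, roughly 25–35 target pairs per run is the
  practical ceiling; the designer errors rather than silently
  degrading when the budget is infeasible.
* Same-cell (off-grid) placements protect the affected pair but can
  collide with an immediately adjacent target pair; the designer
  detects and rejects such collisions instead of resolving them.
* Overlapping/staggered windows, RT-scheduled window switching and
  vendor binary method files are out of scope; the instrument-paste
  export covers the common method-editor path.
* The DEP filter requires ≥3 samples per group, but exact rank-sum
  p-values cannot clear α = 0.05 below 4 vs 4; interpret 3-replicate
  designs accordingly.
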