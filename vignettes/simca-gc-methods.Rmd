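---
title: "Identifying and annotating GC/MS metabolite peaks with weighted spectral correlation and SIMCA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying and annotating GC/MS metabolite peaks with weighted spectral correlation and SIMCA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(simcaGC)
```

## The problem

A GC/MS metabolomics run of a biological sample yields a few hundred aligned
peaks, of which typically only a fraction can be named by matching retention
time and electron-ionization (EI) spectrum against an in-house reference
library. The rest are usually discarded as "unknowns", losing potential
biomarkers. `simcaGC` keeps every peak: it names what it can (library
identification), assigns a chemical class to what it cannot name (SIMCA
annotation), and reports the remainder as unknown — producing an organized
peak × sample matrix with no missing values.

The pipeline assumes that baseline correction, peak picking, deconvolution
and cross-sample alignment have already been done upstream (e.g. by
alignment freeware exporting a per-mass-signal CSV). `simcaGC` starts from
that export.

## Retention-time correction by pseudo-internal standards

Chromatographic shift (column aging, cuts, lot changes) breaks RT-based
matching. Rather than an exogenous n-alkane ladder and retention indices,
the library's retention times are updated from up to eight *pseudo-internal
standards*: stable endogenous peaks the user names in the configuration.
Each anchor pairs a library RT with the RT observed in the current batch;
the map from old to new RT is piecewise-linear between adjacent anchors,
extends each boundary segment's affine law outside the anchor range, and
degenerates to a pure offset for a single anchor. This is the simplest
strictly monotone rule consistent with anchoring both early and late peaks,
and two anchors suffice to undo any global linear drift exactly.

Anchors are located among the observed peaks by the same weighted spectral
correlation used for identification, searched within `anchor_window_sec`
(default 60 s) of the library RT. This window must contain the *uncorrected*
drift — a few percent of the run length — and is therefore much wider than
the identification window; a window proportional to the identification
width `c` (a few seconds) would let late anchors lock onto the wrong peak,
which silently corrupts the whole correction. The library is corrected once
per batch: alignment has already put all samples of a batch on a common RT
axis, so per-sample correction would only re-fit noise.

## Identification: windowed, mass-weighted Pearson correlation

Spectra are vectors of relative intensities (base peak = 100) over integer
m/z 85–500, i.e. 416 variables. For a peak at retention time `rt`, all
library entries within the closed window `[rt - c, rt + c]` are candidates
(`c` is user-set; at `c` = 2 s a peak at 600 s selects the 598–602 s
entries). Each candidate is scored by the *degree of coincidence* (DOC): the
Pearson correlation between the two spectra after the weighting

\[ w(I, m) = I^{a} \, m^{b}, \qquad a = 0.5,\; b = 2 \text{ by default.} \]

EI is a hard ionization, so raw intensities pile up at low m/z while the
structurally informative fragments sit at high m/z; damping intensity and
up-weighting mass emphasizes exactly the informative region. The exponents
follow the dominant convention in EI library search and are both exposed in
the configuration (`weighting:`) — `(1, 0)` recovers the unweighted
correlation. The highest-DOC candidate wins; ties break on smaller |ΔRT|,
then library order, so results are deterministic. By default any positive
winner is accepted (`min_doc = 0`); a threshold can be configured to
suppress weak matches. One library compound may legitimately match several
peaks (sugar anomers, partial silylation), so duplicates are flagged in the
report rather than forbidden.

## Annotation: SIMCA class models

Unidentified peaks are classified into chemical classes (e.g. sugar, sugar
phosphate, organic acid, fatty acid, amine) by Soft Independent Modeling of
Class Analogy. Each class is modeled separately: its training spectra
\(X_K\) (m compounds × p = 416 bins) are mean-centered — no autoscaling,
since all variables share intensity units — and decomposed by SVD,

\[ X_K = T_K V_K^{\top} + E_K, \]

keeping `r` components. The training residual standard deviation

\[ s_0 = \sqrt{ \frac{\sum_{k,i} e_{ki}^2}{(m - r - 1)(p - r)} } \]

measures the class's spread around its subspace. A new spectrum `x` is
projected onto each class model; its residual distance is

\[ s_j = \sqrt{ \frac{\lVert (I - V_K V_K^{\top})(x - \bar{x}_K) \rVert^2}{p - r} }, \]

and membership is decided by an F-test on \(F = s_j^2 / s_0^2\): the object
belongs to the class when the residual variances are *not* significantly
different (upper-tail p-value > α, default α = 0.05). Two degrees-of-freedom
conventions are implemented, selected by `df_convention`:

* `"paper"` (default): \(df_1 = m - r - 1\), \(df_2 = (m - r - 1)^2\);
* `"classical"`: \(df_1 = p - r\), \(df_2 = (p - r)(m - r - 1)\).

The default follows the printed convention of the original description of
this method; the classical form is the one under which the test is
(asymptotically) calibrated, and the type-I error check below uses it. With
small training sets the classical test is conservative-to-liberal by
O(1/m) terms — the training RSD over-estimates the residual scale by roughly
\((m-1)/(m-r-1)\) when the subspace is signal-pinned, while mean estimation
and subspace leakage inflate \(s_j\) by ~\(2/m\) — so the calibration
experiment in the acceptance tests uses m = 400 training objects, where
these terms are negligible. At the m ≈ 10 of real class models the paper
convention's generous critical value (≈1.9 at m = 12, r = 1) makes the test
robust in practice.

A peak accepted by several classes gets the class with the **largest
p-value**; a peak accepted by none is reported as **unknown** but kept in
the output matrix.

### Choosing the number of components

`r` is chosen per class by leave-one-out cross-validation: for each
candidate rank the held-out spectrum's squared residual to the refitted
subspace is accumulated (PRESS). Because a naive row-wise PRESS decreases by
~1/p per extra component simply by absorbing noise, PRESS values are
compared *per residual degree of freedom*, PRESS/(p − r), and the smallest
rank within 1% of the minimum wins. The zero-component (mean-only) model
competes as a baseline so that structureless data do not inflate the rank,
but at least one component is always retained. `r_max` is capped at
min(5, m − 2) so the residual degrees of freedom stay positive.

### Interclass distance

Model separation is summarized by

\[ D_{12} = \max\!\left(0,\; \sqrt{ \frac{s_{12}^2 + s_{21}^2}{s_{11}^2 + s_{22}^2} } - 1 \right), \]

where \(s_{qr}\) is the residual SD of class q's training objects projected
into class r's model with \(m_q (p - r_r)\) degrees of freedom, and
\(s_{qq}\) is class q's own residual recomputed with \(m_q (p - r_q)\).
The distance is symmetric, exactly zero for a model against itself, and
values above one indicate genuinely separated classes. The m/z bins with the
largest variance-weighted loading magnitudes (`important_mz()`) name the
fragments that characterize each class.

## What the synthetic data emulate — and what they do not

All tests run on seeded generators (`make_default_templates()`,
`make_training_sets()`, `make_synthetic_batch()`); no instrument data are
required. The generators emulate the structure the method exploits:

* **class templates** with the diagnostic fragments of trimethylsilylated
  metabolite classes (sugar 89/103/147/217, sugar phosphate 89/147/217/299,
  organic acid 101/133/147, fatty acid 117/129/132/145, amine 86/100/174),
  the most class-specific fragment carrying the base peak and fragments
  shared between classes given matching intensities so they do not
  discriminate;
* **fragment-rich spectra**: 40 low-intensity background fragments per
  class, plus 3 compound-specific signature fragments per compound, so that
  within-class diversity (what \(s_0\) measures) is realistic rather than
  degenerate;
* **a rank-one within-class structure**: a bounded latent factor modulating
  the non-base diagnostic fragments (emulating varying silylation degree),
  which is why cross-validation selects one component per class;
* **noise**: multiplicative lognormal intensity noise (detector-like,
  default 5% relative SD) plus a low additive baseline floor
  (SD = 10 × `intensity_sd_rel` relative-intensity units), both zero when
  the noise parameter is zero;
* **batches**: library compounds on an RT grid, observed at
  `α·rt + β + jitter` with lognormal per-sample heights; training-set class
  sizes default to 12/10/12/9/13.

They do **not** simulate chromatographic peak shapes, co-elution,
derivatization by-products, or real EI fragmentation chemistry. Passing
tests therefore demonstrate that the algorithms are implemented correctly
and behave as designed under realistic structure and noise — not that any
particular real-world identification rate will be achieved.

## Numerical choices and degenerate inputs

* All-zero spectra cannot be normalized and raise an error; a candidate
  whose weighted spectrum has zero variance is treated as a non-match.
* Anchor sets must be strictly monotone in both old and new RT; violations
  name the offending pair. At most 8 anchors are accepted.
* `s0 = 0` (noiseless, duplicated training spectra) makes the F-test
  degenerate; the error message says to add training objects or noise.
* Interclass distance is clamped at zero; identical training sets on both
  sides give exactly 0.
* Signals outside the m/z bin range are dropped with a warning; duplicate
  m/z within one RT cluster keeps the more intense signal and warns, since
  it indicates unresolved co-elution upstream.
* RT clustering tolerance defaults to 1.5 s (three scan intervals at 20
  scans/s); peak heights are taken at the base-peak m/z (quantifier-ion
  practice).
* Leave-one-out cross-validation and all generators are deterministic given
  the seed; the pipeline is a pure function of (inputs, config, seed).

## Problem sizes used in the checks

The shipped tests run the five-class benchmark at the 12/10/12/9/13 class
sizes (56 × 416 training matrix), identification recall on batches of 100
library compounds, the type-I calibration on 2,000 simulated objects against
m = 400 training spectra, and end-to-end drift recovery (α = 1.02, β = 3 s)
on 100 peaks — sizes at which every statistical property under test is
stable while the whole suite stays fast.

## Known limitations

* The weighting exponents are a documented convention, not a fitted
  optimum; other EI search weights (e.g. NIST-style (0.5, 3) or dot-product
  scoring) may suit particular instruments better.
* The RT map is piecewise-linear; smooth nonlinear warps (LOESS/spline)
  are out of scope, as are retention indices.
* One library entry can absorb several peaks; no global one-to-one
  assignment is attempted (duplicates are flagged instead).
* SIMCA models are only as good as their training spectra: classes with
  m < 5 compounds give very weak F-tests, and compounds whose fragmentation
  does not follow their functional class will be misannotated.
* The paper-convention F-test degrees of freedom are statistically unusual;
  they are the default for fidelity, but calibration-sensitive work should
  select the classical convention.
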