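---
title: "MS2-level isotopic distributions and chromatogram deisotoping: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MS2-level isotopic distributions and chromatogram deisotoping: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmdeiso)
```

This vignette documents the models, parameter choices and numerical
decisions behind the package, in the spirit of a methods section: what is
computed, under which assumptions, and where the design was genuinely open.

## 1. Aggregated isotopologue distributions

A triple quadrupole operated at unit mass resolution cannot separate the
isotopic fine structure within one nominal mass. We therefore aggregate
isotopologues by *nucleon offset*: Mn is the sum of all species n nucleons
heavier than the monoisotopic ion, regardless of which elements carry the
extra neutrons. For a formula with per-element counts $k_e$, the
distribution is the convolution product over elements of the single-atom
offset distribution raised to the $k_e$-th convolution power:

$$p = \mathop{\ast}_{e} \; a_e^{\ast k_e},$$

where $a_e$ is the vector of isotopic abundances of element $e$ indexed by
nucleon offset. `isotope_pattern()` evaluates this by exponentiation-by-
squaring under truncated convolution. Because offsets only add, truncating
every intermediate at `max_order` leaves the retained prefix exact — no
renormalisation is applied and discarded tail mass is simply absent (this
is the "monotone truncation" property verified in the tests). Ratios
$r[n] = p[n]/p[0]$ are the quantities used everywhere downstream, so the
overall scale never matters.

**Abundance table.** The embedded table (`isotope_table()`) carries CIAAW/
IUPAC representative terrestrial abundances for C, H, N, O, P, S — the
elements occurring in phospholipid and sphingolipid adduct ions. The table
is fixed and versioned rather than configurable: every reference value in
the test suite is a deterministic function of it. Two consequences are
worth stating. First, M10-order ratios scale roughly with the 10th power
of the ¹³C abundance, so published theoretical values computed from a
slightly different table can differ by a unit in the second significant
figure at high orders; comparisons at that order tolerate ±1 second-digit
unit. Second, a handful of published reference factors sit exactly on a
2-significant-figure rounding boundary and are mutually inconsistent at
the last printed digit (no single natural-abundance table reproduces all
of them simultaneously); the affected comparisons are documented inline in
the acceptance tests and held to the same ±1-unit criterion.

**Formula conventions.** Formulas denote the ion *as measured*: the adduct
proton (or ammonium) is included in the composition and charge ±1 is
assumed; electron mass is ignored, which at unit resolution is far below
any tolerance used. The parser accepts plain element symbols only —
isotope-labelled notation such as "D" is rejected, because a labelled
internal standard violates the natural-abundance model and silently
accepting it would produce confidently wrong factors.

## 2. Transition-level (MS2) distributions

For a transition A → B the precursor separates into two independent
moieties: the product ion B and the neutral fragment [A − B]. Extra
neutrons distribute over the two moieties independently, so the intensity
of the isotopologue pair $(A_i \to B_j)$ relative to $(A_0 \to B_0)$ is

$$f(i, j) = r_{[A-B]}[i - j] \cdot r_B[j], \qquad 0 \le j \le i.$$

Compound libraries specify the MS2 moiety either as the shared product ion
(`ConstantProduct`, e.g. phosphocholine, m/z 184) or as the shared neutral
loss (`ConstantNeutralLoss`, e.g. the 87 Da serine fragment); the other
moiety is derived by formula subtraction, which fails loudly when the MS2
formula is not a sub-formula of the precursor — that always indicates a
corrupted library row. Two identities pin the implementation down and are
enforced as property tests: $f(0,0) = 1$, and marginalisation
$\sum_{j \le i} f(i,j) = r_A[i]$, which holds exactly because the precursor
pattern is the convolution of the two moiety patterns.

## 3. Interference discovery and cascaded subtraction

For every deisotoping-eligible annotation (compound with full formula trio
linked to a "source" channel), predicted interfered transitions are placed
at $(Q1 + i\,\Delta,\; Q3 + j\,\Delta)$ with $\Delta$ = 1.00335 Da, the
¹³C–¹²C spacing. The published method does not state which spacing it uses
for matching; at the ±0.2 Da default tolerance every plausible one-nucleon
spacing (e.g. 1.00628 for ¹⁵N) selects identical channels through M10, so
the choice is immaterial and we use the carbon spacing that dominates
organic molecules. Acquired channels of equal polarity matching within
`mass_tol`, with |ΔCE| ≤ `ce_tol` (default 1.0 V — different collision
energies yield non-comparable intensities), receive an edge weighted by
$f(i,j)$; factors below 1e-12 are dropped as numerically meaningless.
Every edge strictly increases Q1, so the interference graph is a DAG.

Subtraction processes affected channels in ascending Q1, using the
*already corrected* source chromatograms — this resolves nested
interference in a single pass and provably equals the fixed point of the
full linear subtraction system (tested against an iterative oracle). Three
deliberate interpretations, where the prose description of the original
method is ambiguous:

* **Tie-break.** Channels with equal Q1 are ordered by Q3, then CE. The
  published description is silent; any fixed order gives deterministic
  output, and channels with identical Q1 cannot feed each other (edges
  require i ≥ 1), so the choice cannot change results.
* **Redundant channels.** "Subtract only once" is implemented per
  (affected channel, source compound): across redundant source channels
  carrying the same compound, the subtracted trace is the point-by-point
  *maximum of factor × resampled source intensity* — the physically
  meaningful quantity — rather than comparing bare factors. If a single
  source channel carries several eligible annotations, only the one with
  the largest factor is used.
* **Negative residuals** are kept by default. They are diagnostic (they
  flag over-subtraction from a wrong annotation) and keeping them makes
  the correction exactly linear in the input intensities, a property the
  tests rely on. `clamp_negative` floors at zero for display parity with
  typical viewers.

Source chromatograms are linearly interpolated onto the affected channel's
time grid and taken as zero outside their acquired span — scheduled MRM
gives every channel its own grid, so resampling is unavoidable; linear
interpolation keeps the subtraction linear and is exact for the shared-grid
case.

## 4. Annotation, alignment, integration

**Annotation** links library entries to channels within ±0.2 Da on Q1 and
Q3 (closed interval — "±0.2" reads as inclusive) and marks *possible
detection targets*, never identifications; no score is attached. CE is
ignored for annotation by default: the ±1.0 V rule is stated only for the
correction step, and an annotation screen should over-collect rather than
silently drop candidates. A strict mode (`ce_tol` in `match_config()`)
applies the CE rule to annotation too.

**Alignment** is anchor-based and deliberately manual: automated peak
picking across arbitrary user panels is unreliable, so the package warps
each run through the piecewise-linear monotone map defined by
user-supplied anchors (identity with none, constant shift with one,
constant-offset extrapolation beyond the outermost anchors to avoid wild
extrapolation at gradient ends). Times are warped in place — lossless, no
resampling onto a common grid. Where a shared reference timeline is
needed, `median_reference_anchors()` takes the per-landmark median across
runs, which minimises total displacement.

**Integration** is a plain trapezoid over the requested range with
endpoint interpolation. "Background-subtracted" is implemented as the
standard drop-line baseline (the chord between the interpolated endpoint
intensities); the original description names no background model. The
before/after report defaults to `background = "none"` over the full trace
so that the percent-remaining statistic reflects the subtraction alone,
not a second modelling choice; both models are exposed. Channels with
nonpositive mean before-AUC are excluded from the report and counted — the
published "channels with some signal" filter is undefined, so the raw
exclusion rule is exposed and any further thresholding is left to the user.

## 5. The simulator: what it emulates, what it does not

`simulate_dataset()` is the package's testbed: Gaussian elution peaks per
compound, the *forward* interference model (add $f(i,j)$ × clean source
trace into every matching channel, using the same matching rule as
discovery), per-run retention-time drift, additive Gaussian noise, and
optional detector clipping. The default scenario
(`default_simulation_spec()`) encodes the canonical nested PC/SM case —
PC 38:4 → SM 42:3;O2 → PC 38:3 plus three blank monitor channels (six
channels, nine edges), five runs at a 0.01 min sampling interval over
11.5–13.5 min, peak heights 10⁶/3·10⁵/5·10⁵ (upper TQMS working range),
σ = 0.05 min (≈ 7 s FWHM, typical UHPLC), drift ±0.02 min across runs.
Noise defaults to off because the generator's primary role is validating
exact recovery: with noise off, no saturation and a shared grid, cascaded
subtraction must reproduce the interference-free ground truth to < 1e-6
relative, and the emitted true-edge list must coincide with
`find_interference_edges()` output — both are acceptance properties.

What a green round trip does **not** establish: the simulator uses
symmetric Gaussian peaks (no tailing), a global time grid (real scheduled
MRM windows differ per channel, exercised only through the resampling
path), additive white noise (no shot noise or baseline drift), and
annotations that are correct by construction. It therefore validates the
algebra and the cascade, not robustness to mis-annotation or detector
physics.

**Saturation** is modelled as a hard ceiling (`clip_saturation()`), and
deliberately *not* compensated: when the source peak clips, the
subtraction uses the flattened trace and under-corrects, leaving strictly
positive residual interference around the saturated region. The package
reproduces this known failure mode rather than papering over it; any
compensation scheme would be instrument-specific.

## 6. Degenerate inputs and numerical edges

The empty formula is valid (pattern $[1, 0, \ldots]$); `max_order = 0`
yields the trivial pattern; phosphorus-only formulas have an exactly
degenerate pattern (offset 0 only). Chromatograms must have strictly
increasing finite times; a one-point chromatogram integrates to zero and
cannot be resampled (error, by contract). Channel identity rounds Q1/Q3 to
4 decimals and CE to 1 decimal — instrument exports jitter in trailing
digits, and the grain is two orders below any matching tolerance. The
interchange TSV stores 9 significant digits, so file round trips are exact
to ~5·10⁻¹⁰ relative per value; comparisons against files account for that
quantisation. mzML ingest converts seconds to minutes on read, records a
missing collision energy as 0 V with a warning (the msconvert
lossy-conversion case — downstream CE matching then degrades, which the
warning states), and refuses to guess polarity when it is absent at both
chromatogram and file level.

## 7. Known limitations

Charge states above 1 are out of scope (their isotopologue spacing falls
below unit resolution, where this whole approach is inapplicable).
Isotope-labelled standards are rejected at the parser. Peak-area isotope
correction by matrix inversion for fully co-eluting designs is a different
method with different assumptions and is intentionally not provided. The
mouse-tissue scale validation (hundreds of channels, ~100 runs) requires
the public deposit and is packaged as an optional script
(`inst/scripts/external_validation.R`) rather than a test.
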