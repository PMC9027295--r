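# mrmdeiso

Chromatogram-level isotopic interference correction ("deisotoping") for
LC-MRM-MS data, with the supporting machinery to go from raw chromatograms
to corrected, quantified output: mzML / tabular chromatogram input,
compound-library channel annotation, anchor-based retention-time alignment,
background-subtracted AUC integration, and a scheduled-MRM simulator for
end-to-end validation.

## The problem

In widely targeted LC-MRM-MS (hundreds of transitions per run on a triple
quadrupole), the isotopologues of one compound leak into the MRM channels of
others. A compound measured at transition Q1 → Q3 has Mᵢ isotopologues at
Q1 + i·Δ (Δ ≈ 1.00335 Da); upon fragmentation each splits over product
isotopologues at Q3 + j·Δ, j ≤ i. In lipid classes sharing a head-group
fragment (PC/SM at m/z 184, PS at neutral loss 87 Da, ...), these isotopic
signals land squarely on neighbouring channels — e.g. the M+1 of a PC
contaminates an SM channel one Dalton up — producing spurious peaks and
inflated areas. Relationships are many-to-many and *nested*: a channel that
receives interference can itself contaminate channels further up in m/z.

Correcting this at the **chromatogram level** (not just peak areas) requires
the MS2-level isotopic distribution. For a transition A → B, write
[A − B] for the neutral fragment. The signal of the isotopologue pair
(Aᵢ → Bⱼ) relative to the monoisotopic transition factorises as

    f(i, j) = r₍A−B₎[i − j] · r_B[j],        j ≤ i,

where r_X[n] is the Mn:M0 abundance ratio of moiety X computed from its
elemental composition (aggregated by nucleon offset — the unit-resolution
quadrupole view). MS1-level ratios are *wrong* for MRM data; the
factorisation above is what this package implements, up to M10.

Deisotoping then proceeds by discovering every source → affected channel
relation in a dataset (Q1/Q3 match within ±0.2 Da on the predicted shifted
transition, collision energies within ±1.0 V), and subtracting
f(i, j) × source chromatogram from each affected chromatogram, processing
channels in ascending Q1 so that already-corrected sources feed the next
subtraction (cascade). Redundant acquisitions are collapsed by a pointwise
maximum so each contribution is subtracted only once.

## Worked example

The built-in simulator generates the canonical nested-interference scenario:
PC 38:4 (810.6 > 184), SM 42:3;O2 (811.7 > 184) and PC 38:3 (812.6 > 184)
plus three blank monitor channels, five runs, with the forward interference
model applied:

```r
library(mrmdeiso)

sim <- simulate_dataset(default_simulation_spec(seed = 11))
res <- deisotope_dataset(sim$contaminated, sim$library)
res$edges[res$edges$run_id == "run01", -1]
#>                   source_id                affected_id   compound i j factor
#>  (+)810.6013>184.0739@33.0V (+)811.6693>184.0739@33.0V    PC_38:4 1 0 0.4530
#>  (+)810.6013>184.0739@33.0V (+)811.6000>185.0700@33.0V    PC_38:4 1 1 0.0610
#>  (+)810.6013>184.0739@33.0V (+)812.6169>184.0739@33.0V    PC_38:4 2 0 0.1084
#>  (+)810.6013>184.0739@33.0V (+)812.6000>185.0700@33.0V    PC_38:4 2 1 0.0276
#>  (+)810.6013>184.0739@33.0V (+)813.6200>184.0700@33.0V    PC_38:4 3 0 0.0181
#>  (+)811.6693>184.0739@33.0V (+)812.6169>184.0739@33.0V SM_42:3;O2 1 0 0.4675
#>  (+)811.6693>184.0739@33.0V (+)812.6000>185.0700@33.0V SM_42:3;O2 1 1 0.0610
#>  (+)811.6693>184.0739@33.0V (+)813.6200>184.0700@33.0V SM_42:3;O2 2 0 0.1109
#>  (+)812.6169>184.0739@33.0V (+)813.6200>184.0700@33.0V    PC_38:3 1 0 0.4532
```

Nine interference relations are discovered, including the chain
PC 38:4 → SM 42:3;O2 → PC 38:3 → monitor. The before/after report shows how
much of each channel's area was genuine:

```r
rep <- deisotoping_report(sim$contaminated, res$dataset)
data.frame(channel = rep$channel_id, remaining = round(rep$percent_remaining, 1))
#>                     channel remaining
#>  (+)810.6013>184.0739@33.0V     100.0
#>  (+)811.6693>184.0739@33.0V      39.8
#>  (+)812.6169>184.0739@33.0V      66.8
#>  (+)811.6000>185.0700@33.0V       0.0
#>  (+)812.6000>185.0700@33.0V       0.0
#>  (+)813.6200>184.0700@33.0V       0.0
```

The SM channel was 60% isotopic contamination; the blank monitor channels
were pure interference and are wiped to baseline. The corrected dataset
matches the simulator's interference-free ground truth to < 1e-6 relative.

The transition-level distributions themselves are plain function calls —
here the protonated PC 34:2 → phosphocholine transition (precursor
C42H81O8NP, product C5H15O4NP):

```r
signif(isotope_pattern("C42H81O8NP", 4)$r, 2)
#> [1] 1.0000 0.4700 0.1200 0.0240 0.0037
tp <- transition_pattern("C42H81O8NP", "C5H15O4NP", "ConstantProduct")
signif(tp$factors[1:4, 1:4], 2)   # rows i = 0..3, cols j = 0..3
#>       [,1]   [,2]   [,3]    [,4]
#> [1,] 1.000 0.0000 0.0000 0.00000
#> [2,] 0.410 0.0610 0.0000 0.00000
#> [3,] 0.090 0.0250 0.0098 0.00000
#> [4,] 0.014 0.0055 0.0040 0.00052
```

f(1,0) = 0.41 is the M1-precursor signal landing on the monoisotopic
product channel one Dalton up in Q1 — the dominant PC → SM contamination.

A ready-made head-group compound library ships in
`inst/extdata/phospholipid_library.tsv`, and everything is also exposed as
a CLI (`exec/mrmtool`): `simulate`, `annotate`, `deisotope`, `align`,
`integrate`, `report`.

## Limitations

No saturation compensation: when a source peak clips at the detector
ceiling, the subtraction under-corrects and residual interference remains
around the saturated region (the simulator reproduces this). Singly charged
ions only; no isotope-labelled (e.g. deuterated) standards; annotation
marks possible detection targets, never identifications.
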