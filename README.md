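# isodrift

Metabolite extracts are usually treated as chemically frozen once the
protein has been "removed" by organic solvent. In practice, enough active
enzyme survives extraction that dried-and-resuspended extracts keep
metabolizing on the autosampler: transaminases run a glutamate ⇌
α-ketoglutarate futile cycle that scrambles isotope labels, glutathione
pools are remodeled, and repeat injections of the same vial drift over
tens of hours. `isodrift` is an R toolkit for detecting, simulating and
quantifying these in-extract interconversions. It is aimed at
metabolomics methods developers and core labs who need to decide whether
a labeled internal standard can be trusted, whether a feature's time
trend is chemistry or chromatography, and how much enzymatic activity a
given extraction protocol leaves behind.

## What is in the box

**Isotopologue exact-mass arithmetic.** Monoisotopic masses from a
hard-coded CODATA constants table, label mass shifts for
¹³C/¹⁵N/²H substitutions, singly charged [M−H]⁻/[M+H]⁺ m/z
(proton mass 1.007276 Da, electron accounted), ppm errors, and peptide
condensation. The dipeptide null model is the discrete self-convolution
of a residue pool's isotopologue distribution: for a free glutamate pool
that is 50 % unlabeled, 25 % D₄ and 25 % D₅, a dipeptide sourced
entirely from that pool must carry both labels (M+8/M+9/M+10) with
probability

    (0.25 + 0.25)² = 0.25,

so the *absence* of those species is evidence that one residue comes
from elsewhere (e.g. protein hydrolysis).

**A label-resolved futile-cycle simulator.** Mass-action kinetics of
Glu + OAA ⇌ αKG + Asp over the restricted label space of the tracer
experiment, d[P]/dt = E(t)·k·[donor]·[acceptor] summed over label
channels, integrated with fixed-step RK4. The transition rules are the
chemistry of transamination: ¹⁵N travels with the amine, ¹³C₅ stays
with the C5 skeleton, and an α-carbon deuterium is lost to solvent on
deamination. Scenarios mirror the bench interventions: `active`,
`filtered` (3 kDa ultrafiltration, E = 0) and `AOA` (aminooxyacetic
acid, E(t) = E₀·e^(−t/τ)). The simulator carries a hidden counter of
true transamination events, the ground truth that label-based cycling
estimates provably underestimate.

**Quantitation.** OLS internal-standard calibration curves, the
label-ratio workaround for analytes whose ISTD is itself interconverted
(labeled/unlabeled area ratio × reference endogenous concentration), and
tracer-atom molar balance tables (skeleton-equivalents per element,
doubly labeled species counted once per element).

**Drift statistics.** Natural-cubic-spline trend tests of
log₁₀(area+1) against time (F-test, df = 4), MetaboAnalyst-style PCA
(log₁₀, center, autoscale), accumulated path length of the injection
trajectory in the PC1–PC2 plane, UpSet-style exclusive set
intersections, QC-CV deduplication, and Spearman LogP-vs-log₂FC
recovery correlation.

**Screening.** Chromatographic peak detection with width/intensity
filters (defaults: base width > 6 s, apex ≥ 1×10⁵), MS2 screening for
precursors carrying the diagnostic glutathione-conjugate fragment
(m/z 308.0912) with ±2 ppm isobaric precursor grouping, coeluting
light/heavy label-pair search, and blank filtering.

All of it is exercisable end-to-end on synthetic data: the generator
also emulates an untargeted background catalogue with protein-dependent
drift and MS2 fixtures with planted conjugates, so every downstream
stage is testable without any instrument files.

## Worked example

```r
library(isodrift)

# m/z of the doubly labeled glutamate tracer, negative mode
round_half_up(ion_mz("C5H9NO4", label_spec(n_13C = 5, n_15N = 1)))
#> [1] 152.0597

# simulate 84 h of in-extract cycling in an active extract
cfg <- simulation_config("active", seed = 1)
tc  <- simulate_timecourse(build_transaminase_system(cfg), seq(0, 84, by = 0.5))

# label scrambling vs the simulator's hidden truth
label_based_cycle_estimate(tc)
#> $estimate_uM
#> [1] 81.71874
#> $true_events_uM
#> [1] 1997.539

# total 15N is conserved across the run
range(tracer_totals(tc)$n15_uM)
#> [1] 82 82

# dipeptide null model for a half-labeled free glutamate pool
dipeptide_label_distribution(
  isotopologue_distribution(c(0, 4, 5), c(0.5, 0.25, 0.25)))
#> <isotopologue distribution>
#>    M+0    M+4    M+5    M+8    M+9   M+10
#> 0.2500 0.2500 0.2500 0.0625 0.1250 0.0625
```

The estimate (≈82 µM of singly labeled glutamate formed) reads as
roughly one visible round trip per tracer molecule, while the hidden
counter shows ~2000 µM-equivalents of transamination events: label
scrambling sees only the small fraction of round trips that swap
partners, which is why singly labeled glutamate underestimates futile
cycling.

A complete run — simulation, injection series, trend tests, PCA drift
summary, molar balance and MS2 screen — is one call:

```r
run_pipeline(system.file("extdata/demo-config.yaml", package = "isodrift"),
             out_dir = "demo_run")
```

There is also a thin command-line wrapper in
`inst/scripts/isodrift-cli.R` with `masscalc` and `run` subcommands.

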