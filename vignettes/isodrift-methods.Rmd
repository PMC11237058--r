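---
title: "Models and methods behind isodrift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind isodrift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isodrift)
```

`isodrift` models what happens to small molecules inside a
"protein-free" metabolomics extract that still contains active enzyme:
isotope labels scramble through a transaminase futile cycle, and the
composition of the vial drifts across repeat injections. This vignette
explains the models, their assumptions, the tunable parameters, and the
design choices made where the design was genuinely open. No empirical
claim is made here beyond what the package's own test suite and
`scripts/acceptance.R` compute.

## Exact-mass arithmetic

All masses derive from one hard-coded table of CODATA monoisotopic
atomic masses (¹H 1.007825, ²H 2.014102, ¹²C 12, ¹³C 13.003355,
¹⁴N 14.003074, ¹⁵N 15.000109, ¹⁶O 15.994915, ³²S 31.972071,
³¹P 30.973762, carried internally at full precision). Ion m/z for the
only supported adducts, singly charged [M−H]⁻ and [M+H]⁺, adds or
subtracts the *proton* mass 1.007276 Da — i.e. the electron mass is
accounted for. That convention reproduces the targeted glutamate and
glutathione m/z values at four decimals, which is how instrument
software prints them; reported values use round-half-up
(`round_half_up()`) because `base::round()`'s round-half-even differs
at exact ties. Multiply charged ions and other adducts are rejected
rather than silently mishandled.

Labels are tracked as substitution *counts* (`n_13C`, `n_15N`, `n_D`),
not atom positions, with one exception: a boolean `alpha_D` flag marks
whether a deuterium occupies the amino-acid α-carbon. That is the only
position-specific chemistry the transamination model needs, because the
α-hydrogen is lost to solvent during deamination.

The dipeptide null model (`dipeptide_label_distribution()`) is the
discrete self-convolution of a residue pool's isotopologue
distribution: it answers "if both residues of a dipeptide were drawn
independently from the free pool, what fraction would be doubly
labeled?" For a pool of 50 % unlabeled / 25 % D₄ / 25 % D₅ glutamate
the doubly labeled (M+8, M+9, M+10) mass sums to exactly 25 %. The
implementation is validated against brute-force enumeration over all
label pairs.

Two caveats are deliberate. Printed literature values for measured
species can deviate from theory by ~0.1–1 mDa (measurement error); the
package always computes theoretical values and treats measured m/z as
observations. And natural-abundance isotope fine structure is out of
scope — distributions here describe *label* states only.

## The transaminase futile cycle

The reaction is Glu + OAA ⇌ αKG + Asp, resolved over the label space
reachable in a tracer experiment: glutamate with ¹³C₅ ∈ {0,5},
¹⁵N ∈ {0,1}, D ∈ {0,4,5} (α-deuterium present only on the added D₅
tracer), α-ketoglutarate with ¹³C₅ and D ∈ {0,4}, aspartate with
¹⁵N ∈ {0,1}, and unlabeled oxaloacetate — 19 species. The transition
rules are:

* the amine ¹⁵N moves from donor amino acid to product amino acid;
* the ¹³C₅ skeleton stays with the C5 backbone (Glu ↔ αKG);
* a donor α-deuterium is lost to solvent (product αKG has one fewer D),
  and re-amination installs an unlabeled α-hydrogen.

These rules make two conservation laws hold *by construction*: total
¹³C₅ skeletons (Glu + αKG pools) and total ¹⁵N (Glu + Asp pools) are
constant, and the α-deuterium pool is non-increasing. The test suite
checks both to relative 1e−8 over 84 h; RK4 preserves linear
invariants, so the observed error is at floating-point level.

Kinetics are deterministic mass action,
d[P]/dt = E(t)·k·[donor]·[acceptor] summed over label channels,
integrated with classical fixed-step RK4 (`deSolve`, step 0.01 h by
default). Pool sizes are µM-scale, so stochastic fluctuations are
irrelevant. A step that drives any concentration below −1e−9 µM raises
an error asking for a smaller step rather than returning garbage. The
integrator also carries the cumulative number of forward (Glu → αKG)
transamination events. That hidden counter is the package's oracle for
the central claim about label-based flux estimates: a
[¹³C₅,¹⁵N] round trip that reunites skeleton and amine regenerates the
original tracer and is invisible, so the amount of singly labeled
glutamate (`label_based_cycle_estimate()`) is a lower bound on true
cycling — strict whenever reverse flux exists.

### Default parameters

No kinetic constants are available for in-extract transamination, so
defaults are a documented modeling choice, anchored on stated
experimental quantities: tracer input 82 µM; an endogenous unlabeled
glutamate pool of the same size (the deuterated species end up near
half of the free pool); αKG at 1/100 of glutamate (1.6 µM); an OAA
pool sized like the αKG pool (the in-extract acceptor availability is
unknown — this is an assumption, not a measurement); aspartate 300 µM.
With k_fwd = k_rev = 0.07 µM⁻¹h⁻¹ and E₀ = 1, ~80 % of the dual-label
tracer is consumed by 24 h, in the reported 80–90 % band. The
interventions are `filtered` (E = 0) and `AOA`, modeled as
exponential-onset total inhibition E(t) = E₀·e^(−t/τ) with τ = 0.01 h
to allow the brief catalytic window before inhibition takes hold; that
window is what lets a trace of αKG turnover survive AOA while
3 kDa filtration abolishes it.

A `clamp_acceptors` switch holds the OAA and aspartate pools constant,
turning the skeleton exchange into an exactly linear two-pool system.
It exists because solver accuracy should be judged against a
closed-form solution: in clamped mode the RK4 trajectory matches the
analytic exponential to < 1e−6 µM. Clamping intentionally breaks the
C4-skeleton conservation law, so conservation tests apply only to
unclamped runs.

## The LC-MS observation model

`observe_injection_series()` samples a time course at the injection
schedule (default 25 injections over 0–84 h, i.e. every 3.5 h) and
applies: area = concentration × response factor (default 10⁴
counts/µM) × lognormal noise with unit mean and configurable CV
(default 5 %, a typical targeted-LCMS repeatability); observed
m/z = theoretical × (1 + ε·10⁻⁶) with ε ~ N(0, 2 ppm); RT = canonical
± N(0, 0.02 min). One seed fixes everything.

The 19 reaction species alone are too narrow to emulate an untargeted
experiment — their trend structure is nearly rank-one, which distorts
PCA-based diagnostics. `background_features()` therefore generates a
catalogue of synthetic matrix features (default 300, the scale of a
post-filter untargeted table) of which 90 % drift when protein is
active: c(t) = c₀·10^(s·A·a·(1−e^(−t/τ))) with random sign s,
amplitude A ∈ [0.2, 1.2] log₁₀ units, τ ∈ [5, 40] h, and a = the
scenario's mean enzyme activity, so the same features are flat in
filtered or inhibited extracts. The catalogue is a property of the
sample matrix: build it once and pass the same object to every scenario
you intend to compare, with per-scenario seeds controlling only noise.

What the generator does **not** emulate: chromatographic peak-shape
effects beyond Gaussians, ionization suppression and matrix effects,
missing values, batch effects, or the additional enzyme systems
(glutathione reductase / transferases are represented only through
drifting background features, not mechanistically). Tests passing on
this generator show the statistics behave as designed under their
stated model; they do not certify performance on any particular real
dataset.

## Quantitation

Calibration (`fit_calibration()`) is unweighted OLS of area ratio on
known concentration — the choice when no weighting scheme is stated —
with optional 1/x and 1/x² weighting hooks. Interpolation clamps
negative concentrations to zero with a flag (never silently drops
them) and flags extrapolation beyond the standard range.

When the ISTD itself is enzymatically interconverted, calibration
against it is circular. The label-ratio method
(`quantify_by_label_ratio()`) instead multiplies the labeled/unlabeled
area ratio by the mean endogenous concentration measured in a
protein-free reference set. It is scale-invariant in the areas and, on
simulated data with 5 % noise CV and n = 3, recovers a known spike
within twice the CV.

`mole_balance()` accounts in skeleton-equivalents, not atoms: a
molecule carrying any ¹³C₅ skeleton counts once for ¹³C, a molecule
carrying ¹⁵N counts once for ¹⁵N, and a doubly labeled molecule counts
once for *each* element. Totals are reported per replicate and as the
group mean — whether conservation is judged within replicate or on
means is a user decision, so both are emitted.

## Drift statistics

The trend test fits a natural cubic regression spline (df = 4) of
log₁₀(area+1) on time and F-tests against the intercept-only model. A
fixed-df spline was chosen over a penalized GAM because the smoother is
then fully specified, dependency-light and exactly calibrated: under
Gaussian null noise the F p-values are uniform, and the empirical
type-I error at α = 0.05 on 2000 null features sits inside
[0.03, 0.07]. The df is exposed; 4 is enough to catch the biphasic
(rise-then-fall) kinetics the futile cycle produces. Significance is
called at raw p < 0.05 per group, with a Benjamini–Hochberg column
emitted alongside for stricter use. Constant series return p = 1 with
a flag rather than an error.

PCA follows the common metabolomics recipe — log₁₀(x+1), mean-center,
autoscale — each step independently switchable, since published
analyses often leave the scaling unstated. Because autoscaling is
undefined for flat features, zero-variance features are dropped with a
warning (they are kept when scaling is off). Drift is summarized as the
accumulated Euclidean path length of a group's injection trajectory in
the PC1–PC2 plane (`dims` exposed). Path length is invariant to score
rotation and translation and scales linearly with scaling — properties
the tests assert. Note the *absolute* path length depends on the
scaling convention, so only comparisons within one PCA are meaningful;
the package always computes scenario contrasts (active vs filtered)
inside a shared score space, where active extracts out-drift filtered
ones by roughly 3–4× under generator defaults.

Deduplication by pooled-QC CV keeps, per compound, the method with the
smallest CV, breaking ties lexicographically by method name so results
are reproducible. Set intersections use UpSet semantics (exclusive
membership patterns), validated against a brute-force tally. The
hydrophobicity–recovery analysis takes LogP as an input column and
computes Spearman's r_s on log₂ fold changes of *mean* pool size
(mean-of-replicates, not mean of ratios), p-value by the t
approximation with average-rank ties.

## Screening

Peak detection delimits each local maximum at, on each side, the nearer
of (a) the trace minimum toward the adjacent candidate apex and (b) the
first point below `boundary_frac` × apex (default 0.05). A pure
valley-to-valley rule is ill-posed on flat or noisy baselines — a zero
baseline has no interior minima and a noisy one has them everywhere —
so the fractional cutoff acts as the base-of-peak definition on open
flanks while true valleys still split overlapping peaks;
`boundary_frac = 0.5` gives FWHM-style widths. Retention filters
default to base width > 6 s and apex ≥ 1×10⁵ counts. Raising the width
threshold can only reduce the peak count, and rescaling intensity
together with the intensity threshold leaves results unchanged.

The fragment screen selects MS2 records containing a fragment within
10 ppm (separate, exposed tolerance) of the diagnostic m/z and groups
the selected precursors by single-linkage within ±2 ppm — the printed
grouping tolerance for isobaric precursors. On fixtures with 14
planted conjugates and 50 decoys the screen attains perfect precision
and recall; decoy fragments are generated with a 50 ppm exclusion
window around the diagnostic m/z, so this is a correctness check of
the matching/grouping logic, not a claim about discrimination of
near-isobaric interferences. The blank filter keeps features whose
sample mean is ≥ 3× the blank mean (threshold a convention, exposed);
vendor-specific "peak rating" metrics are not reimplemented.

## Pipeline, units, determinism

Units are fixed package-wide to avoid the s/min/h traps of LC-MS data:
concentrations µM, retention times minutes, chromatogram time seconds,
simulation time hours, masses Da, areas arbitrary counts.
`run_pipeline()` executes simulate → drift/quantify/screen from a
single YAML (or list) config, validates scenario and stage names before
running anything, propagates one seed to every stochastic stage, and
writes a JSON report echoing all parameters with md5 checksums of every
output; the same config and seed give byte-identical outputs. Feature
tables round-trip CSV at 17 significant digits (full double precision).
MS2 fixtures are written and read as MGF with a minimal reader/writer.

## Problem sizes and limitations

Default analysis sizes — 19 species + 300 background features ×
25 injections, 2000-feature null calibrations, 50 random-rate
simulations — were chosen as the smallest sets that exercise each
statistical property cleanly; all of them run in seconds on one core.
Known limitations: single transaminase pair only (no competing amino
acid acceptors), no enzyme mechanism (ping-pong/PLP intermediates), no
acceptor-pool measurements to constrain OAA, observation noise is
feature-independent lognormal, and absolute PCA path lengths are
convention-dependent as discussed above.
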