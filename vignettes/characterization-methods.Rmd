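---
title: "Models and methods behind trypknot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind trypknot}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trypknot)
```

`trypknot` bundles the in-silico stages of characterizing a cysteine-rich,
tight-binding serine-peptidase inhibitor. This vignette records the models,
their assumptions, the defaults that matter, and the design decisions taken
where the underlying procedures are conventionally under-specified.

## The tight-binding equilibrium

A reversible inhibitor is *tight-binding* when its dissociation constant
$K_D$ is comparable to the enzyme concentration, so the enzyme depletes the
free-inhibitor pool and the usual $[I]_{free} \approx [I]_{total}$
simplification fails. Mass balance on $E + I \rightleftharpoons EI$ gives
the fractional residual activity

$$a = 1 - \frac{(E + I + K) - \sqrt{(E + I + K)^2 - 4\,E\,I}}{2E},$$

implemented in `morrison_activity()` (concentrations in nM throughout; the
CSV reader converts a declared micromolar column on input). Assumptions:
one binding site (1:1 stoichiometry), activity proportional to free enzyme,
equilibrium reached — which for slow-onset inhibitors requires
pre-incubation; `preincubation_plateau()` locates the settling time of a
residual-activity time course (default tolerance 0.02 activity fraction).

### The stoichiometric titration estimator

The classical titration construction: plot residual activity against total
inhibitor, extrapolate the *rectilinear* (upper) limb to its x-intercept
$X$, read the interpolated activity $a_{eq}$ there, and use

$$K_D = \frac{[E][I]}{[EI]}, \qquad [E] = [I] = a_{eq} E_t,\quad
[EI] = (1 - a_{eq}) E_t .$$

Two choices here are conventionally left vague and are fixed as follows:

* **Rectilinear region.** Replicate-averaged points with activity at or
  above `rect_floor` (default 0.5) — the upper limb, which is closest to
  the straight stoichiometric line. The fit is a straight line
  (`degree = 1`); the intercept-selection rule is configurable.
* **Activity at the equivalence point.** Linear interpolation between the
  bracketing observed points.

A plain single-pass reading has a *deterministic* bias: the titration curve
is convex, so any chord (and in the limit, the tangent at zero inhibitor)
extrapolates to $X \ge E_t + K_D$, not $E_t$. The species bookkeeping at
that inflated intercept then underestimates $K_D$ by roughly 20% when
$K_D/E_t \approx 0.06$, *independent of grid density* — making the naive
recipe adequate only when $K_D \ll E_t$. `kd_stoichiometric()` therefore
applies, by default (`refine = TRUE`), a model-based calibration: it seeks
the $(E_t, K_D)$ pair whose noise-free tight-binding curve, sampled on the
same inhibitor grid and pushed through the identical rectilinear read-out,
reproduces the observed read-out (a fixed-point iteration on the
two-parameter match). On noiseless data this recovers the generating
parameters exactly, on any grid; under noise only stochastic error remains.
`refine = FALSE` preserves the literal single-pass recipe for comparison.
The returned species always satisfy $K_D = [E][I]/[EI]$ identically.

Uncertainty is reported as a nonparametric bootstrap over replicates
(`n_boot`, resampling whole replicate titrations), since titration
uncertainties are conventionally quoted without a stated method.

`fit_morrison()` is the companion nonlinear estimator: weighted
least-squares of the Morrison curve over $(K_D, E_t)$, weights
$1/a^2$ by default to match the multiplicative error of
control-normalised rate assays.

### Simulated study conditions

`titration_sim_spec()` defaults encode the conditions the estimators are
meant for: $E_t = 515$ nM (a 12 ng/µL trypsin assay at MW 23,300 Da —
`enzyme_molarity_nM(12)`), ground-truth $K_D = 30.25$ nM, a dilution-series
grid from 0.25 to 4 µM in 250 nM steps plus the uninhibited control,
triplicates, and 2% multiplicative Gaussian noise clipped to $[0, 1.05]$
(rate read-outs normalised to a control can slightly exceed 1). Noise is
multiplicative because these assays report relative fluorescence rates.
The parameter-recovery checks in the test suite run 200 such titrations
(and 60 in the faster unit test); "dense" noiseless checks use a 10 nM
grid step. What the generator does *not* emulate: systematic pipetting
drift, substrate depletion over the read window, slow-binding kinetics
during the assay itself, and inner-filter effects — so passing recovery
tests demonstrate estimator correctness under idealised noise, not
robustness to instrument artefacts.

## Charge-envelope deconvolution

Electrospray puts one molecule at several consecutive protonation states;
each peak obeys $M = z\,(m/z) - z\,m_{adduct}$. `assign_charges()` searches
every run of consecutive descending charges in `[z_min, z_max]` (defaults 1
and 30; ascending m/z peaks carry descending z) and keeps the assignment
minimising the variance of the implied neutral masses; the envelope is
accepted only when the relative spread (SD/mean) of those masses is below
1% (configurable). `deconvolve()` then reports the unweighted mean
(intensity weighting is available but off by default, since peak heights
carry ionisation bias, not mass information). The default adduct is the
proton, 1.007276 Da; MALDI-style "minus 1 u / minus 23 u" readings are
treated as rounded H+/Na+ via `adduct_candidates()`.

Note that consistency pruning has limits: *two* peaks ~100 Th apart are
genuinely consistent with some molecule near 3 kDa at consecutive charges,
so two-peak envelopes only fail in a restricted charge window. Three or
more peaks constrain the assignment sharply.

## Sequence physicochemistry

* **Masses.** ExPASy residue masses; average water 18.01528 Da,
  monoisotopic 18.010565 Da. `X` residues are rejected unless explicitly
  skipped (`allow_x = TRUE`).
* **Isoelectric point.** Charge-balance root found by bisection on
  `[0, 14]` to 1e-4 pH. The default pKa set (`pka_bjellqvist()`) is the
  Bjellqvist set used by the ExPASy Compute pI tool, including its
  residue-specific N- and C-terminal values; the set is a plain list and
  swappable. Unlike some implementations, the bisection is not clamped to
  a minimum pH, so strongly acidic peptides report their true root.
* **Identity.** Needleman–Wunsch global alignment via Biostrings, BLOSUM62,
  gap open 10 / extend 0.5. The identity denominator is the number of
  alignment columns including gaps (the alignment-viewer convention);
  `"shortest"` and `"aligned"` denominators are exposed because published
  identity percentages rarely state their convention.
* **Coverage.** Exact-substring mapping of peptides; coverage is the union
  of matched spans over protein length. Unmatched peptides warn and
  contribute nothing (no tolerant matching — proteomics identifications
  are exact once post-processed).
* **Gel migration.** $\log_{10}$ mass is fitted linearly in relative
  migration over the standards; two standards suffice and interpolation
  through them is exact.

## PEST scoring

Candidate PEST regions are maximal stretches between positively charged
flanks (K/R/H; sequence termini also bound a stretch) whose core is at
least 12 residues and contains at least one P, one D/E and one S/T. The
score is

$$\mathrm{score} = 0.55 \cdot \mathrm{DEPST} - 0.5 \cdot \mathrm{HI},$$

with HI the mole-fraction-averaged Kyte–Doolittle hydropathy rescaled to
$[0, 90]$ via $10h + 45$. For DEPST, documented variants differ; all are
exposed in `pest_score()`:

* mass-weighted (w/w, default) vs mole-percent enrichment;
* correction by one obligatory equivalent each of D/E, P and S/T (default
  on; the lightest member present is subtracted, since the three required
  residues are the qualification, not the enrichment);
* flank handling: the displayed window conventionally includes the
  positive flank, but the flank is stripped before scoring (default).

The default combination (mass-weighted, equivalent-corrected,
flank-stripped) was selected by calibrating the variants on a published
13-residue digestive-inhibitor window and is the only combination that
lands within the published value's print precision; the alternatives
differ by 2–12 score units and remain available for cross-tool
comparisons.

## Cysteine frameworks and scaffold families

Cysteines are numbered C1..Cn by sequence order, independent of residue
numbering; connectivities are sets of ordinal pairs, canonicalised so that
bond order and (i, j) orientation never matter. The registry covers ICK
(C1–C4, C2–C5, C3–C6), Kunitz (C1–C6, C2–C4, C3–C5), Kazal (C1–C5, C2–C4,
C3–C6), the ten-cysteine colipase-like/MIT1 fold (C1–C4, C2–C5, C3–C7,
C6–C9, C8–C10), HAND (six cysteines, pairing unsettled — participates only
in the count pre-screen), and DDH. The DDH pattern circulates in the
literature as "C1–C2, C2–C4", which reuses C2 and cannot be a valid
pairing; rather than silently guessing the intended pattern it is stored
verbatim with `valid = FALSE` and excluded from exact matching.
`classify_connectivity()` falls back to nearest-template by bond-set
Jaccard similarity, reporting ties as ambiguous.

## Structure interfaces

Models predicted or docked in silico rarely carry hydrogens, so
`find_hbonds()` works heavy-atom-only: donors are N/O atoms that bear
hydrogens in standard residue templates (backbone N except proline; side
chains of R, N, Q, H, K, S, T, W, Y), acceptors are backbone O/OXT and the
usual side-chain N/O lone-pair carriers; a hydrogen bond is a
donor–acceptor pair within the distance cutoff, default 3.5 Å
(PIC-style). Longer "weak contact" distances can be studied by raising the
cutoff explicitly. Residue numbering is taken verbatim from the input file
— serine-protease literature mixes enzyme-native and chymotrypsinogen
numbering, and renumbering silently would corrupt cross-references.
`reactive_loop_candidates()` approximates surface exposure by the
coil/inter-cysteine-segment heuristic rather than solvent accessibility:
on a disulfide-knotted scaffold the inter-cysteine stretches are the
exposed loops, and candidate P1-bearing loops for a trypsin target are
those containing Lys/Arg.

## Pipeline and numerical choices

`run_characterization()` executes the enabled stages in dependency order,
isolates failures per stage, and serialises a deterministic report
(`write_report()`: stable key order, no timestamps) — given identical
inputs and seed the JSON is byte-identical. The package's interface is R
functions plus this orchestrator; there is no shell wrapper, since users
of an analysis package of this kind work from R scripts and the
reproducibility entry point is the report itself.

Degenerate inputs fail loudly and early: titrations need at least 4 grid
points, a decreasing profile and a negative rectilinear slope; an
equivalence point outside the observed grid, or residual activity at
equivalence outside (0, 1), raises a degenerate-titration error rather
than returning an extrapolated guess. Envelope assignment requires at
least two peaks. All generators take one explicit seed per specification
and touch no global RNG state (`withr::with_seed`).

## Known limitations

* The stoichiometric estimator assumes the activity at zero inhibitor is
  an adequate normalisation; systematic control error translates directly
  into $K_D$ error.
* PEST scoring reproduces one documented variant family; other published
  implementations (different hydropathy rescalings, unweighted cores)
  can differ by several units.
* Interface analysis is purely geometric — no angular hydrogen-bond
  criteria, no solvent accessibility, no energetics.
* The pI model treats ionisable groups as independent (no electrostatic
  coupling), as all Henderson–Hasselbalch pI calculators do.
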