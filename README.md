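# trypknot

Characterization toolkit for tight-binding, cysteine-rich serine-peptidase
inhibitors — the kind of small disulfide-stabilised proteins found in spider
venoms and, more recently, in spider digestive fluids, where they are thought
to inactivate the trypsin of ingested prey.

The package is aimed at protein biochemists who have isolated such an
inhibitor and want to run the full in-silico side of its characterization in
one place:

* **Tight-binding kinetics.** An inhibitor whose K_D approaches the enzyme
  concentration depletes the free-inhibitor pool, so classical
  Michaelis–Menten inhibition analysis fails. The residual activity follows
  the Morrison mass-balance quadratic

  *a* = 1 − [(E + I + K) − √((E + I + K)² − 4·E·I)] / (2E),

  with E, I the total enzyme and inhibitor concentrations and K the
  dissociation constant. `trypknot` provides the forward model
  (`morrison_activity()`), a nonlinear fit (`fit_morrison()`), and the
  classical *stoichiometric titration* estimator (`kd_stoichiometric()`):
  extrapolate the rectilinear limb of the activity-vs-inhibitor plot to its
  x-intercept (the equivalence point, an estimate of total enzyme), read the
  residual activity *a* there, and apply K_D = [E][I]/[EI] with
  [E] = [I] = a·E_t and [EI] = (1 − a)·E_t. A model-based calibration step
  removes the deterministic bias of the straight-line extrapolation (see the
  methods vignette).
* **Mass spectrometry.** Charge-state envelope deconvolution
  (`deconvolve()`): assign consecutive charges to the m/z peaks by
  minimising the variance of the implied neutral masses
  M = z·(m/z) − z·m_adduct, then average. MALDI adduct interpretation via
  `adduct_candidates()`.
* **Sequence physicochemistry.** Average/monoisotopic mass, Bjellqvist-pKa
  isoelectric point, signal-peptide maturation, PEST-motif scoring
  (0.55·DEPST − 0.5·hydrophobicity), global-alignment percent identity
  (BLOSUM62), peptide coverage, and SDS-PAGE mass from relative migration
  (log10 mass linear in Rm).
* **Disulfide scaffolds.** Cysteine-framework extraction and classification
  of connectivity patterns (in C1..Cn ordinal space) against the ICK, DDH,
  Kunitz, Kazal, HAND and MIT1/colipase family templates.
* **Structure interfaces.** PDB parsing (via bio3d), heavy-atom
  hydrogen-bond detection across a two-chain interface, interface residue
  reports, and reactive-site loop candidates (Laskowski-mechanism P1
  residues).
* **Synthetic data.** Generators with known ground truth for every input
  class (`gen_titration()`, `gen_envelope()`, `gen_framework_sequence()`,
  `gen_toy_complex()`), so the whole pipeline is testable offline.

## Worked example

Simulate a triplicate titration of a 515 nM enzyme with a K_D = 30.25 nM
inhibitor (2% assay noise) and recover the constant:

```r
library(trypknot)

ts  <- gen_titration(titration_sim_spec(seed = 1))
est <- kd_stoichiometric(ts, n_boot = 100, seed = 1)
est
#> Tight-binding estimate (stoichiometric method)
#>   K_D            : 27.6 nM (SE 1.96)
#>   enzyme total   : 528.4 nM
#>   [E] = [I] free : 107.7 nM
#>   [EI] complex   : 420.7 nM
```

The estimate (27.6 nM, bootstrap SE over the three replicates) recovers the
simulated 30.25 nM within the assay noise; the equivalence point estimates
the total enzyme, and the free/complex concentrations satisfy
K_D = [E][I]/[EI] exactly.

Deconvolve a three-peak electrospray envelope:

```r
deconvolve(c(1102.4051, 1239.9110, 1417.0741))
#> Deconvolved neutral mass: 9912.0927 Da (sd 0.7494, n = 3 peaks)
#>   charges: 9, 8, 7
```

The three peaks are consistent with one neutral molecule of ~9912.1 Da seen
at charges 9+, 8+ and 7+; the 0.75 Da spread is the peak-to-peak scatter of
the implied masses.

Score a PEST motif and classify a disulfide scaffold:

```r
pest_score("KCQQDSGEEPSEE")
#> [1] 13.32798

classify_connectivity(list(c(1, 4), c(2, 5), c(3, 7), c(6, 9), c(8, 10)))
#> <family_match> MIT1-colipase (exact, Jaccard 1.00)
```

A PEST score above +5 flags a likely rapid-turnover motif; the five-bond
pattern is the colipase-like/MIT1 fold.

## Package layout

* `R/` — kinetics, titration estimators, mass spectrometry, sequence
  properties, PEST, cysteine frameworks, structure contacts, synthetic-data
  generators, I/O, pipeline.
* `vignettes/characterization-methods.Rmd` — the models, assumptions,
  parameter defaults and design decisions.
* `tests/testthat/` — unit, property and end-to-end suites (all fixtures
  generated in code).
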