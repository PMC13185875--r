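---
title: "Local models and genetic algorithms for helicene inverse design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local models and genetic algorithms for helicene inverse design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helidesign)
```

## The problem

Substituting the 16 peripheral positions of the carbo[6]helicene scaffold
with up to six groups drawn from a 16-substituent inventory spans roughly
7 × 10^10 distinct molecules (after folding mirror-equivalent substitution
patterns). Chiroptical properties — the rotatory strengths and wavelengths
of the main electronic circular dichroism (ECD) bands, the transition
moments of the lowest-energy excitation, and the absorption dissymmetry
factor `g_abs` — are expensive to compute per molecule and essentially
impossible to intuit across such a space. `helidesign` implements a
locality-driven strategy: represent each molecule as the vector of Hammett
σ~p~ constants of its 16 positions, predict any query molecule from a
random forest trained only on its nearest neighbours in that descriptor
space, and couple the predictor to a constrained genetic algorithm (GA) so
that properties can be *specified first* and molecules found afterwards.

## Representation

A molecule is an occupancy vector over positions 1..16 plus a helical
sense. Canonical Position-Substituent names (`"1-SH_3-F_8-OH"`) are the
identity used for de-duplication everywhere. The descriptor is the per-
position σ~p~ (Hansch–Leo–Taft compilation values shipped as an editable
CSV; H is exactly 0). Two caveats follow from this choice, both deliberate:

* the encoding is degenerate where two groups share a σ~p~ (SMe/H at 0.00,
  Cl/Br at 0.23); `sigma_degeneracies()` audits the active table, identity
  stays with the code sequence, and an optional integer code channel
  (`encode(..., code_channel = TRUE)`) is available for distance
  tie-breaking, off by default because the electronic descriptor alone is
  the representation of record;
* all training data refer to the P enantiomer; M-enantiomer records are
  obtained by `enantiomer_flip()`, which inverts the chiroptical signs and
  swaps the roles of the maximum-positive and maximum-negative bands so
  sign invariants (R~+~ ≥ 0 ≥ R~–~) are preserved.

Mirror-image substitution patterns (position i ↔ 17−i) are physically
equivalent placements; `count_space()` folds them with Burnside's lemma
(the orbit count is the average of the total pattern count and the count of
mirror-fixed patterns). All counts are integer-exact in double precision
(< 2^53); the 16-position, 16-type, ≤6-substituent space is
139,053,725,953 unfolded and 69,526,981,313 folded.

## The dissymmetry factor

For an isotropic absorbing sample the two-vector expression
g~abs~ = 4|m||µ|cosθ / (|µ|² + |m|²) is evaluated with |µ| stored in
10^−18 esu·cm and |m| in 10^−20 erg·G^−1 (the units every tabulated value
uses) and converted internally; the implementation factors the electric
unit out of numerator and denominator, which makes the matched-moment limit
(|µ| = |m| in absolute units, θ = 0) return exactly ±2 in floating point.
The typical three-orders-of-magnitude disparity between the moments yields
the familiar g ≈ 10^−3..10^−4 regime; large g requires either a large |m|
or — the more exotic route — a strongly suppressed |µ|.

## The synthetic oracle

No machine-readable DFT dataset for this family is available, so the
package ships a seeded surrogate (`default_oracle_params()`,
`oracle_properties()`) whose role is to *emulate the statistical structure*
local modelling relies on, never to reproduce DFT numbers for specific
non-parent molecules:

* the parent helicene anchors at the literature values R~+~ = 694,
  R~–~ = −514 (10^−40 esu·cm·erg·G^−1), λ~+~ = 342.6 nm, λ~–~ = 254 nm and
  |m~1~| = 0.36 (10^−20 erg·G^−1). The parent's λ~1~ (330 nm), |µ~1~|
  (1.0 × 10^−18 esu·cm), R~1~ (−25) and moment angle (cosθ = 0.3) are not
  published values; they are fixed stand-ins chosen once at plausible
  magnitudes for a helicene S~0~→S~1~ transition and flagged as such.
* each latent channel (band strengths and wavelengths; |µ|, |m|, θ)
  responds linearly to the 16 σ~p~ values plus mirror-pair and
  adjacent-pair products, passed through a tanh saturation so cumulative
  shifts stay physical. Rotatory strengths and moments respond on the log
  scale (positivity plus long tails); wavelengths additively. Position
  effects are drawn once from a fixed stream with larger magnitudes at the
  terminal positions (1–3, 14–16), and the λ~1~ directions at the terminal
  positions are oriented red-shifting so an EWG-rich corner of the space
  reaches the sparse 550–600 nm region the iterative-loop scenario needs.
* `g_abs` is *never sampled*: |µ|, |m| and θ are generated and g is
  computed from them, so every record is internally consistent (the angle
  is attached to each record for exact verification). The log-scale |µ|
  channel has a wide saturation bound, so rare substituent combinations
  suppress |µ| toward ~0.01 and create the small high-g regime a g-hunt
  should be able to find.
* noise is Gaussian and heteroscedastic per channel (log-scale s.d. 0.04–
  0.05 for strengths and moments, 2.5–6 nm for wavelengths), drawn from a
  stream derived from the seed and the molecule's canonical name, making
  every record reproducible in isolation.
* `regime_switch = TRUE` cuts descriptor space into 16 cells by the signs
  of four positional-group σ~p~ sums (positions 1–4, 5–8, 9–12, 13–16) and
  rescales — with random sign, magnitude between 1 and 2.5 — the
  moment-channel response in each cell, making the g response piecewise
  while the band properties stay smooth: the controlled analogue of the
  heterogeneity that makes a global g model uninformative while local
  neighbourhoods, which rarely straddle a cell boundary, remain coherent.
* `plant_optimum()` adds a compact-support bump (radius δ = 0.05 in
  descriptor space, linear kernel) to one property, sized above the
  landscape's noiseless upper bound by a requested margin, giving search
  benchmarks an exact known optimum. Because Cl and Br share σ~p~, a
  planted pattern and its halogen twin are descriptor-identical; recovery
  is judged by value, not by name.

What passing tests on this oracle demonstrate is that the *machinery* —
neighbourhood retrieval, local fitting, constrained search, iterative
retraining — behaves correctly on a landscape with the right smoothness,
coupling and heterogeneity. They say nothing about DFT-level accuracy for
real substituted helicenes, which depends on the real dataset.

`generate_dataset()` samples distinct molecules stratified uniformly over
substituent counts 1..6 (equal shares, remainder to the lowest counts,
capped by stratum size for small families); `generate_study_dataset()`
mixes the six families (halogens, donors, acceptors, carbon-based, the
four-representative mixed family, all-16) in equal shares, de-duplicating
across overlapping families and topping up from the full inventory.

## Local models

Per query, the k nearest training molecules under the weighted Euclidean
distance are retrieved (ties broken by canonical name, the query excluded
from its own neighbourhood) and one `ranger` random forest per property is
fitted on the neighbourhood only. Defaults: k = 100 (a neighbourhood size
that balances locality against fit stability for datasets of 10^3–10^4
molecules; tune per case where needed), uniform distance weights (the
argument accepts any per-position weights), 300 trees, √16 = 4 features per
split, minimum node size 5, all seeded and single-threaded for exact
reproducibility. Degenerate neighbourhoods (constant target or constant
features) fall back to the neighbourhood mean. Predicted g~abs~ is clamped
to [−2, 2]; the predictor does not otherwise enforce the moment coupling —
one independent regressor per property is the deliberate reading of the
protocol.

Evaluation follows the held-out protocol: a seeded 80/20 split, one local
model per test molecule against the training pool only, MAE and RMSE per
property, and outlier flagging at 2.5 × the scaled median absolute
deviation (MAD × 1.4826, the normal-consistency constant — the natural
reading of "scaled MAD") of the residuals.

## Genetic algorithm

Individuals are occupancy vectors. Variation is uniform crossover over the
16 positions followed by per-position code mutation (rate 0.05) and
add/drop/relocate-substituent moves (rate 0.2 each); selection is
tournament (size 3) with 5 elites; the default population is 1000 with 100
generations (benchmarks in the test suite scale these down to their
enumerable spaces). Offspring are *repaired* rather than killed: forbidden
codes re-rolled, forbidden positions cleared, symmetry restored by copying
the lower position of each pair onto its partner, excess substituents
dropped uniformly at random. Objectives are scalarized (weighted sum;
maximize → +value, minimize → −value, target → −|value − target|,
threshold → −weighted deficit) rather than Pareto-ranked, matching the
single-ranked-list reporting style of the scenarios. Hard property windows
(e.g. |µ| ∈ [0.5, 2] with g~abs~ > 10^−2) act on selection as a dominant
feasibility penalty and on reporting as a hard audit: every reported
candidate must pass an independent re-check of symmetry, bans, substituent
count and windows. The best-of-generation trace is monotone non-decreasing
whenever elitism ≥ 1 and the predictor is deterministic.

## Iterative loop

Sparse property regions (say, λ~1~ near 600 nm when the dataset stops at
520 nm) defeat a one-shot model because the local neighbourhoods simply do
not contain the target region. `iterate_design()` alternates: GA with the
current local model → ground-truth evaluation of the top novel candidates
(batch default 20) → append to the dataset (canonical-name novelty check)
→ retrain. Appended rows always come from the evaluator, never from the
predictor, so the loop cannot launder its own predictions into training
data. The history (best true value and gap per round) is seeded and replays
exactly.

## Interpretability

`pattern_summary()` reduces any candidate set to per-position substitution
frequency, mean σ~p~ of the occupying groups, and the top codes — the
tabular form of the bubble-plot reading from which design rules ("position
1 wants a strong acceptor, position 2 sits near σ~p~ ≈ 0.3") are read off.
The mean is taken over substituted instances only by default; counting H
as σ~p~ = 0 is available behind a flag since both conventions are
defensible and the original figure does not say which it uses.

## Numerical and design choices

* Seed fan-out: every stochastic component derives its seed from a master
  seed and a text label via a 31-bit string hash (`derive_seed()`), so one
  integer reproduces a whole pipeline and sub-streams are decoupled.
* Chemical-space counts use exact integer arithmetic in doubles (all
  intermediate values < 2^53); the brute-force orbit enumerator cross-
  checks the closed form on all small instances in the tests.
* CSV serialization uses 17 significant digits, so dataset round trips are
  bit-exact.
* Distance ties, archive ordering and candidate ranking all break ties by
  canonical name; GA runs, splits, forests and datasets are byte-
  reproducible under fixed seeds (`num.threads = 1` for the forests).
* ECD curve synthesis uses Gaussian broadening in wavelength space,
  default width 15 nm, config-overridable; curves are a rendering aid,
  not a modelling surface.

## Problem sizes used in the shipped checks

The test suite and the acceptance script exercise the pipeline at desk
scale, chosen as the smallest sizes at which each scientific claim is
meaningful: a 3000-molecule six-family study dataset (80/20 split, k = 100)
for the outlier-regime check; 2000 train / 400 test molecules across five
seeds for the local-versus-global comparison on the regime-switch
landscape; the exhaustively enumerable ≤2-substituent five-halogen/nitro
space (3081 molecules) for GA recovery benchmarks; and 60–200 population
GAs for the constraint scenarios. The full-scale defaults (population 1000,
100 generations, k = 100 on 10^4-row datasets) remain the production
settings.

## Limitations

* The oracle is a surrogate: its position-effect magnitudes, couplings and
  noise levels are emulation choices, not fitted to DFT data.
* σ~p~ is a scalar electronic summary; steric and conformational effects
  are invisible to the representation by construction.
* The predictor treats the nine properties independently; predicted
  records need not satisfy the g/moment coupling exactly (the oracle and
  all ground-truth records do).
* `max_substituents` is a hard bound (default 6, the training-set limit);
  searching beyond it is possible only by raising the bound explicitly.
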