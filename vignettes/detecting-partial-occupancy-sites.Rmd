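---
title: "Detecting partially occupied anomalous scatterer sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting partially occupied anomalous scatterer sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anomsite)
```

## The problem

Disordered or transiently bound protein segments occupy any given position
in only a fraction of the unit cells of a crystal.  Conventional model
building fails on such states: their electron density is weak and
amorphous.  A site-specific anomalous label — here iodine, introduced as
para-iodophenylalanine — turns the problem into one of detecting weak
anomalous difference density.  An iodine site with occupancy 0.1–0.5 and a
large displacement parameter produces a peak of a few σ in a phased
anomalous difference Fourier map, which must be distinguished from the
crystal's other anomalous scatterers (Zn, Cl, ordered methionine S) and
from noise.

`anomsite` implements the full decision chain for this experiment on
synthetic data: a simulator producing Friedel-paired structure-factor
amplitudes for a paper-like tetragonal crystal, anomalous difference map
synthesis with σ-normalized peak search, multi-energy and multi-orientation
validation logic, multi-start occupancy/B estimation, dose-decay checks,
and ensemble selection of disordered-segment conformers against the
observed sites.

## The physics in brief

Near an absorption edge an atom's scattering factor acquires an
energy-dependent complex correction,

$$ f(s, E) = f_0(s) + f'(E) + i\,f''(E), $$

and any nonzero $f''$ breaks Friedel symmetry: $|F(h)| \neq |F(-h)|$.
The package bundles Cromer–Mann $f_0$ coefficients and a discrete
$f'/f''$ table per element (C, N, O, S, Cl, Zn, I) over 2.3–6.2 keV, with
samples a few eV on either side of each in-range edge; interpolation is
linear in $\log E$ and never crosses an edge.  The iodine samples at the
two working energies carry the experimentally determined values
($f''$ = 13.41 e⁻ at 5.2 keV, 3.42 e⁻ at 4.5 keV), the standard practice
when a measured edge scan is available; all other samples are standard
Cromer–Liberman values.  The resulting above/below edge contrast for
iodine is a factor of ≈3.9, while S, Cl and Zn scatter as strongly (or
more strongly) below the iodine edges — that asymmetry is the entire basis
of the classification.

The phased anomalous difference Fourier map uses coefficients
$\Delta F(h) = |F^+(h)| - |F^-(h)|$ with model phases shifted by −90°,
Hermitian-completed so the map is real, and divided by the cell volume.
Peak heights are reported in units of the map rms over the whole unit cell
("σ"); the rms convention is stated because alternatives (asymmetric-unit
rms) exist and would shift all thresholds.

## The simulator and what it does (not) emulate

`build_paper_like_crystal()` places 300–600 light atoms (C/N/O plus
methionine-like S) self-avoidingly in a compact blob inside a
P4₁22 cell of 42.80 × 42.80 × 253.78 Å, adds fully occupied Zn and Cl
marker sites, and iodine probes ~3.25 Å from the nearest scaffold atom.
The presets mirror the three studied complexes: four probes with
occupancies 0.31/0.49/0.27/0.12 and B 87/164/106/80 Å² ("L19"), one probe
at 0.33/55 ("K20"), one at 0.20/47 ("L18").

Noise is Gaussian on amplitudes with a single width
$\sigma(F) = \bar F / t + 0.005\,\bar F$, where $t$ is the target mean
F/σ(F).  The default $t = 15$ was calibrated once so that a fully occupied
Zn marker peaks at 10–15σ in the 5.2 keV map, matching the magnitude of
the strongest non-iodine signals such an experiment reports; it is not a
per-test dial.  Radiation damage is modelled as a pure exponential decay
of probe occupancies with half-dose `d_half` (default 6 MGy, chosen so a
~8 MGy pass roughly halves probe peak heights); scaffold and marker
damage is not modelled.  Orientations ("κ angles") are modelled as
independent noise realizations only — the statistical role κ replication
plays in the real experiment — with no diffraction-geometry differences.
Consequences for interpretation: passing tests show the decision logic is
sound against counting-type noise and dose decay, not that it is robust to
scaling artefacts, absorption errors, radiation chemistry beyond C–I
cleavage, or misindexed origins between crystals (in-simulation datasets
share one indexing, so alternative-origin matching is deliberately not
implemented).

Doses are campaign inputs (MGy per dataset), never computed from beam
parameters: the dose bookkeeping follows whatever schedule the plan
states, accumulating per crystal.

## Classification logic and thresholds

Peaks from all datasets are clustered by single linkage under the
symmetry-aware minimum distance with a 1.5 Å cutoff (slightly above the
1.3 Å separation at which two independent studies' peaks were still
considered the same site).  A consensus site is called **iodine** when

* its strongest above-edge height is ≥ `strong_sigma` (default 6σ, the
  confidence cutoff used once refined phases are available),
* it appears (≥ `absent_sigma`, default 4σ — the initial screening cutoff)
  in at least `min_support` = 2 distinct above-edge datasets, and
* every below-edge height is below `max(absent_sigma,
  max_below_ratio × above)`.

The last clause needs the ratio term because a high-occupancy iodine site
does not vanish below the edge: its signal drops by the f'' contrast
(≈3.9×), so a 30σ site legitimately retains ~8σ.  Non-iodine scatterers
keep at least their above-edge strength below the edge (f'' ratios ≈1.3
for S/Cl/Zn across 4.5→5.2 keV), so `max_below_ratio = 0.5` separates the
two regimes with margin on both sides of the 4σ noise floor.  Sites
present on both sides without an iodine-like drop are
**non_iodine_scatterer**; everything else is **unconfirmed** with a stated
reason (no below-edge data, insufficient replication, sub-threshold
height).

Dose decay is summarized as the later/earlier height ratio at fixed
energy; ratios below 0.8 flag a site as decayed.  The 0.8 cutoff sits
conservatively between observed carbon-bound iodine ratios (~0.4–0.5 over
~8 MGy) and ordered-sulfur ratios (~0.85–0.9).

## Multi-start occupancy/B estimation

Occupancy and B of one site trade off almost perfectly against amplitude
data: the two-parameter normal matrix is nearly singular along a curved
valley.  The estimation protocol embraces this: thousands of random
$(occ, B)$ starts are each refined for exactly 50 bounded Gauss–Newton
cycles (no early stopping), and the 2D histogram of endpoints is the
readout — its mode is the estimate, and the ridge it traces *is* the
degeneracy, deliberately exposed rather than hidden.

Numerically, an exact two-parameter Gauss–Newton step would converge every
start to the same point in a handful of cycles, collapsing the histogram.
The refinement therefore applies Levenberg damping of $10^{-4}$ × the
normal-matrix trace: the well-determined direction still converges almost
immediately, while motion along the near-singular valley is slow, so after
the fixed cycle count the endpoint cloud traces the ridge while the mode
still lands on the truth for noiseless data (within the histogram's bin
width: 0.02 in occupancy, 6 Å² in B).  Steps are clamped to 0.5 in
occupancy and 75 Å² in B per cycle, parameters to occ ∈ [0, 1],
B ∈ [1, 300] Å².  Start ranges default to occ ∈ [0.01, 1],
B ∈ [10, 250] Å² and are configurable and recorded.  The target is
weighted least squares on amplitudes over both Friedel mates (weights
1/σ²; unit weights for noiseless data) — a simplification relative to a
full maximum-likelihood refinement target, adequate because only two
parameters of a single site are free.

## Ensemble selection and cross-validation

`select_ensemble()` picks N conformers from a pool so that each observed
anomalous site is close to a matching-residue probe of some member:
per-site error is the minimum symmetry-aware distance, and the fit error
is the peak-height-weighted mean (the unweighted mean is reported
alongside, since a height-weighted average is a choice, not a given).
Greedy selection with lowest-id tie-breaking is followed, optionally, by
single-swap hill climbing ("exchange"), whose error is never worse than
greedy's.  Hold-one-out back-prediction reruns the selection without one
site and reports that site's distance to the chosen ensemble — the
package's cross-validation of whether the sites carry mutually consistent
information.  Density terms are intentionally out of scope: the selection
objective here is anomalous-position-only, which is the part of the
procedure the reported error statistics (fractions of an Ångström)
measure.  Pool generation is likewise external; `make_synthetic_pool()`
plants conformers at a stated Gaussian width around the truth so that
recoverability is controlled in tests.

## Numerical choices

* Reflections: symmetry-unique set under the Laue group to `d_min`
  (default 2.0 Å, the best crystals' limit); representative is the
  lexicographically largest index in the orbit.
* Map grid: ≥ 3 samples per `d_min` per axis, rounded up to sizes with
  factors 2/3/5/7; peak positions refined by per-axis three-point
  parabolas, then merged under symmetry within 1.0 Å.
* Missing Friedel mates are dropped (and counted), not imputed.
* Reproducibility: every stochastic stage takes a seed; campaign datasets
  derive sub-seeds from the master seed and their labels, so any stage can
  be reproduced in isolation and a full pipeline run is a pure function of
  its configuration.
* Problem sizes in the test-suite: the default scaffold is ~320 atoms and
  detection/purity properties are checked over 20 and 50 reseeded noise
  campaigns on shared noiseless amplitudes; occupancy recovery uses 500
  starts (the histogram structure is stable well below the protocol's
  10,000).

## A minimal run

```{r, eval = FALSE}
cfg <- campaign_config("K20", seed = 1)
rep <- run_pipeline(cfg)
rep$sites[, c("classification", "max_above", "max_below", "n_above_support")]
rep$occupancy
```

The K20-like campaign yields exactly one iodine call whose multi-start
occupancy mode falls on the simulated truth (0.33, 55 Å²); the L19-like
preset yields four calls, the weakest from a 12%-occupancy, B = 80 Å²
site — the regime the data-collection strategy was designed to reach.

## Known limitations

* Amplitude-level simulation only: no frame-level integration, scaling
  statistics, or absorption/geometry modelling.
* Two bundled space groups (P4₁22 and P1); arbitrary operator lists are
  accepted but not parsed from symbol tables.
* f' values come from the same standard tables as f'' but are not
  validated against experiment.
* The least-squares occupancy target and the position-only selection
  objective are documented simplifications of their full-featured
  counterparts.
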