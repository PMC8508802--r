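---
title: "Methods: descriptors and bridge dynamics in quinbridge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: descriptors and bridge dynamics in quinbridge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quinbridge)
library(dplyr)
```

quinbridge analyses substituent effects in 1,4-naphthoquinone-type
compounds that carry one or two intramolecular O–H...O hydrogen bridges —
naphthazarin (5,8-dihydroxy-1,4-naphthoquinone) being the archetype of the
twin-bridge case. The package covers both sides of such a study: static
descriptors computed from optimised geometries and charge populations
(aromaticity, substituent charge transfer, proton-transfer energetics),
and dynamical statistics computed from molecular-dynamics trajectories
(proton possession, transfer events, inter-bridge synchrony, vibrational
power spectra). Because published ab initio trajectories of these systems
are generally not redistributable, the package also ships a stochastic
twin-bridge generator with closed-form ground truth, so the whole
trajectory pipeline is testable end to end.

## Aromaticity: the HOMA index

For a ring with $n$ carbon–carbon bonds of lengths $d_i$,

$$\mathrm{HOMA} = 1 - \frac{\alpha}{n}\sum_{i=1}^{n} (d_\mathrm{opt} - d_i)^2,$$

with the standard C–C parameterisation $\alpha = 257.7$ and
$d_\mathrm{opt} = 1.388$ Å. A fully bond-equalised aromatic ring scores 1;
strong bond-length alternation drives the score towards 0 and below, which
is where the quinoid (carbonyl-bearing) ring of these compounds lives.
Only the C–C parameterisation is shipped: rings containing heteroatoms —
including the quasi-rings closed by the hydrogen bridges — are rejected
with an error rather than silently approximated, because mixing
heteroatom reference lengths into the same formula changes the meaning of
the score. Bond lengths enter either from a delimited table
(`read_bond_table()`, one column per compound, dash-marked absences) or
measured off a Cartesian geometry along a `ring_def()` cycle.

```{r homa}
tab <- read_bond_table(system.file("extdata", "parent_bond_lengths.tsv",
                                   package = "quinbridge"))
homa_table(filter(tab, bond %in% naphthoquinone_ring_bonds("II")))
```

Full floating precision is kept internally; printed summaries round to
four decimals, and headline comparisons to the two decimals customary for
this index.

## Charge descriptor: cSAR

For a substituent $X$ attached at an ipso carbon,
$\mathrm{cSAR}(X) = q(X) + q(C_\mathrm{ipso})$ — the summed partial
charges of the substituent's atoms plus the ipso carbon. The formula is
independent of how the charges were obtained; Hirshfeld populations are
the usual source for these compounds, and the reader functions accept any
scheme. Unsubstituted ring positions are treated as one-atom hydrogen
groups so a profile covers all positions uniformly. The profile carries
the total molecular charge as a diagnostic attribute (a sum rule the
caller may check, not an enforced constraint).

## Proton-transfer scan profiles

A relaxed scan along one O–H distance, typically on a 0.05 Å increment,
yields an energy profile whose two headline numbers are the barrier
height and the energy of the second minimum (the proton-transferred
tautomer), both relative to the global minimum. `analyze_profile()`
reports grid extrema as sampled: scan tables are published without
interpolation, and a sampled maximum can only underestimate the true
barrier, so nested grid refinement converges to it from below — a
property the tests exercise directly. An optional three-point parabolic
refinement (`refine = TRUE`) is available when off-grid stationary points
are wanted. Ties (plateaus) collapse deterministically to their leftmost
grid index. Energies are kcal/mol internally; hartree input is converted
with 1 hartree = 627.5095 kcal/mol.

## Trajectory analytics

A trajectory is a long tibble (one row per atom per frame) with the
sampling interval `dt` and an equilibration window carried as attributes;
every analysis drops the equilibration span first. The default generator
stride, 1.452 fs, corresponds to a 0.0726 fs integration step recorded
every 20 steps — the usual Car–Parrinello bookkeeping for these systems —
and production runs of ~25 ps with the first 0.7 ps discarded are the
scale the defaults anticipate. The synthetic generator starts its proton
chain in the stationary distribution, so generated trajectories need no
equilibration cut and default to none.

**Possession.** Each frame assigns the bridging proton to the closer
oxygen; exact ties go to the donor (a deterministic rule; ties have
measure zero in real dynamics). Donor and acceptor fractions sum to one
exactly by construction, and swapping donor/acceptor roles maps a
possession fraction $p$ to $1-p$ exactly.

**Transfer events.** Events are detected on the signed asymmetry
$\delta(t) = d_\mathrm{OH} - d_\mathrm{HO}$ with a hysteresis threshold
(default 0.05 Å, below the O–H vibrational amplitude scale): a crossing
of zero counts once it is confirmed by $|\delta|$ exceeding the threshold
on the new side before recrossing, so barrier-top chatter cannot inflate
the event count. Directions alternate by construction, and with zero
hysteresis the event-segment decomposition reproduces frame-wise
possession exactly.

**Synchrony.** Events of the two bridges are paired greedily by smallest
time difference within a window (default 500 fs, comfortably above the
sub-0.1 ps delays of strongly coupled bridges). The match fraction is
matched pairs over the larger event count — a conservative choice that
penalises unpaired events on either side.

## Velocity power spectra

Spectra follow the Wiener–Khinchin route: biased velocity
autocovariance per atom and Cartesian component, truncated at a maximum
lag (default 2 ps, which sets the intrinsic line width), Hann-tapered,
cosine-transformed on a zero-padded power-of-two grid, and summed over
the selection. The axis is wavenumber, capped at the Nyquist limit
$1/(2\,\mathrm{d}t\,c)$ (≈ 11 486 cm⁻¹ at dt = 1.452 fs); with the
default lag and padding the bin width is ≈ 2.8 cm⁻¹. Intensities are a
density per wavenumber normalised so the one-sided integral equals the
selection's mean squared velocity (Parseval); the small negative
sidelobes a truncated taper can produce are clipped at zero, which is why
the Parseval identity is guaranteed only to a couple of percent rather
than exactly. Spectra are per-proton and not mass-weighted — the
bridge-to-bridge comparison divides out any common weighting, and the
νOH barycenter (intensity-weighted mean over a window, default
2200–3400 cm⁻¹) is scale-invariant anyway. For position-only
trajectories, `estimate_velocities()` provides central-difference
velocities behind an explicit call; the finite-difference transfer
function damps intensity near Nyquist, which barely moves barycenters in
the νOH region but is documented for completeness.

## The synthetic twin-bridge generator

The generator replaces unavailable ab initio trajectories with a model
chosen for exact tractability rather than physical fidelity: the joint
proton configuration evolves as a four-state continuous-time Markov chain
(DD, DA, AD, AA), and each proton adds a deterministic stretching
oscillation plus Gaussian noise on top of its current side.

* Per-bridge hopping rates `k_fwd`, `k_rev` (ps⁻¹) set the marginal
  donor/acceptor balance; independent bridges recover the two-state
  stationary fraction $k_\mathrm{rev}/(k_\mathrm{fwd}+k_\mathrm{rev})$.
* A single coupling knob $\gamma \ge 1$ multiplies rates into concordant
  joint states (DD/AA) and divides rates out of them, so one parameter
  spans independent ($\gamma = 1$) to locked bridges
  ($\gamma \to \infty$, concordance $\to 1$).
* Geometry defaults mirror the compounds the package targets: O...O
  2.585 Å (the observed 2.58–2.60 Å range), O–H 1.00 Å, stretching
  wavenumber 2750 cm⁻¹ (between dynamically red-shifted and
  harmonic-like νOH bands), amplitude 0.05 Å, positional noise 0.01 Å,
  dt 1.452 fs, duration 25 ps. The two bridges are laid out in separate
  non-interacting frames: only bridge atoms enter any analysis, so no
  molecular skeleton is generated.

`bridge_ground_truth()` solves the chain's stationary distribution from
its generator matrix — analytically, never by simulation — giving exact
expectations for possession, concordance and the injected wavenumbers.
A Langevin walker on a genuine two-dimensional double-well surface would
be more physical but has no closed-form stationary statistics; it is a
possible extension, not a testing requirement.

What the generator deliberately does not emulate: anharmonic coupling
between the stretch and the transfer coordinate, frequency shifts upon
transfer, thermostat artefacts, and the chemistry that maps substituent
patterns to rates. Passing recovery tests therefore demonstrates that the
analytics are correct on data with known structure — not that real
trajectories satisfy the Markov-switching model.

## Validation conditions and problem sizes

The test suite's stochastic checks run at preregistered conditions chosen
for statistical informativeness:

* Possession recovery: five rate settings (`k_fwd`, `k_rev`, γ) =
  (1,1,1), (1,3,1), (3,1,1), (1,3,10), (2,2,5), seeds 1–10, 25 ps each;
  each bridge's empirical fraction must fall within three standard errors
  $\sqrt{p(1-p)/n_\mathrm{soj}}$ of the analytic value, with
  $n_\mathrm{soj}$ the observed sojourn count (events + 1) — the
  effective number of independent observations for an occupation
  fraction.
* Coupling monotonicity: γ ∈ {1, 3, 10, 100} at k = 4 ps⁻¹, 50 ps,
  30 fs matching window, seeds 1–10, with match fractions pooled (total
  matched over total events) across seeds. Rates out of concordant states
  scale as $1/\gamma$, so γ = 100 produces only a handful of transfers
  per run; pooling and the longer duration keep the estimator
  informative where a per-run mean would be dominated by empty trains.
* Spectral recovery: noise-free runs at 2600, 2750 and 3000 cm⁻¹ must
  place the band barycenter within one bin width of the injection.

## Known limitations

* HOMA is C–C only; heteroatom rings need a different parameterisation.
* Event stamping is frame-quantised: sub-`dt` excursions of the proton
  are invisible, which at very strong coupling hides some transient
  recrossings (and is precisely why the synchrony test pools).
* The barycenter depends on the window when bands overlap its edges;
  the default 2200–3400 cm⁻¹ brackets the νOH features these compounds
  show but is configurable.
* Rank correlations over small compound series are descriptive; no
  significance testing is attached, deliberately, for n ≈ 7 series.
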