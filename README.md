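# quinbridge

Descriptor and trajectory analysis of twin intramolecular O–H...O
hydrogen bridges in quinonoid compounds.

Substituted 1,4-naphthoquinones — naphthazarin and its halogenated
relatives above all — pack an unusual amount of physical chemistry into
one small skeleton: an antiaromatic quinoid ring fused to a benzenoid
ring, one or two short intramolecular hydrogen bridges (O...O ≈
2.58–2.60 Å), low proton-transfer barriers, and proton motions in the two
bridges that are strongly correlated. quinbridge is for computational
chemists who study such systems: it turns optimised geometries, charge
populations, relaxed-scan profiles and molecular-dynamics trajectories
into the standard descriptors of this literature, and ships a stochastic
twin-bridge trajectory generator with analytic ground truth so the whole
pipeline can be validated without access to the original ab initio runs.

## What it computes

* **HOMA aromaticity** — for a ring with *n* C–C bonds of length *dᵢ*,
  HOMA = 1 − (α/n) Σ (d_opt − dᵢ)², with α = 257.7 and d_opt = 1.388 Å;
  1 for ideal aromatic bond equalisation, ≤ 0 for localised rings.
* **cSAR** — charge of the Substituent Active Region,
  cSAR(X) = q(X) + q(C_ipso), from per-atom partial-charge tables.
* **Proton-transfer energetics** — barrier height and second-minimum
  energy of 1-D relaxed-scan profiles, reported from grid extrema.
* **Bridge dynamics** — donor-proton / proton-acceptor distance series,
  proton-possession fractions (closer-oxygen rule), hysteresis-filtered
  transfer events, and inter-bridge synchrony statistics.
* **Vibrational spectra** — atomic-velocity power spectra
  (autocorrelation + Hann taper + FFT) and intensity-weighted νOH band
  barycenters, per bridge proton.
* **Series reports** — Spearman rank correlations linking quinoid-ring
  HOMA, barrier, second-minimum energy and νOH across a compound series.
* **Synthetic data** — a four-state Markov model of the coupled proton
  pair (rates k_fwd, k_rev; coupling γ skews the chain towards concordant
  states) with oscillation and noise on top; stationary possession and
  concordance come in closed form from the generator matrix.

## Worked example

HOMA of the benzenoid ring from a bond-length table (X-ray and DFT
columns for the three parent compounds ship with the package):

```r
library(quinbridge)
library(dplyr)

tab <- read_bond_table(system.file("extdata", "parent_bond_lengths.tsv",
                                   package = "quinbridge"))
homa_table(filter(tab, bond %in% naphthoquinone_ring_bonds("II")))
#> # A tibble: 6 × 3
#>   compound n_bonds  homa
#>   <chr>      <int> <dbl>
#> 1 1a_dft         6 0.995
#> 2 1a_xray        6 0.984
#> 3 2a_dft         6 0.952
#> 4 2a_xray        6 0.834
#> 5 3a_dft         6 0.878
#> 6 3a_xray        6 0.524
```

The DFT columns show the progression the descriptors are built to track:
an unsubstituted benzenoid ring is essentially fully aromatic (0.995),
one hydroxyl/hydrogen-bridge lowers it to 0.95, and the twin-bridge
dihydroxy compound to 0.88.

A synthetic twin-bridge trajectory, analysed end to end:

```r
m <- coupled_bridge_model(k_fwd = 1, k_rev = 3, coupling = 10,
                          duration = 25, seed = 42)
g <- generate_bridge_trajectory(m)
g$truth$stationary_donor_fraction
#>   bridge1   bridge2
#> 0.8976143 0.8976143

bridge_dynamics_report(g$trajectory)
#> <qb_dynamics_report>
#> # A tibble: 2 × 4
#>   bridge   donor_percent n_events barycenter
#>   <chr>            <dbl>    <int>      <dbl>
#> 1 O1-H1-O3          88.5        9      2750.
#> 2 O2-H2-O4          88.6        5      2751.
#> # A tibble: 1 × 4
#>   n_matched match_fraction mean_delay max_delay
#>       <int>          <dbl>      <dbl>     <dbl>
#> 1         3          0.333       1.94      2.90
#> barycenter split: 0.2 cm^-1
```

The analytic stationary donor fraction is 0.898; the 25 ps sample lands
at 88.5–88.6% possession for both bridges, the matched transfer events
lag each other by under 3 fs (the bridges are strongly coupled at
γ = 10), and the two proton barycenters sit within a fraction of a
spectral bin of the injected 2750 cm⁻¹ stretching wavenumber.

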