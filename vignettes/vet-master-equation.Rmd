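---
title: "Modelling vibrational energy transport in a β-hairpin: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling vibrational energy transport in a β-hairpin: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vetflow)
```

## The model and its assumptions

`vetflow` describes the flow of excess vibrational energy through a peptide
as a continuous-time linear master equation on a residue-level network,

$$\frac{dE_j}{dt} = \sum_i \left[k_{ij} E_i(t) - k_{ji} E_j(t)\right],$$

where $E_j$ is the mean kinetic energy of residue $j$ per degree of freedom,
normalized to the injected quantum. The underlying physical assumptions are:

* **Diffusive transport.** Energy hops incoherently between residues; there
  is no ballistic component. On a uniform backbone chain this makes the
  energy-weighted mean-squared displacement grow linearly in time, which the
  test suite verifies ($R^2 > 0.99$ on an 80-residue chain over 2–40 ps).
* **Structure-determined rates.** Inter-residue rates depend only on
  geometry and two transport coefficients: backbone rates
  $k = D_B/d^2$ with $d$ the Cα–Cα distance of sequence neighbours, and
  contact rates $k = D_C/r^p$ with $r$ the minimum relevant heavy-atom
  distance and $p$ a configurable exponent (default 2). The inverse-power
  form keeps the stated proportionality to $D_B$ and $D_C$, makes the units
  explicit (Å²/ps), and reduces to plausible transfer times at canonical
  β-sheet geometry. The exponent is exposed in `transport_params()` rather
  than hard-coded because distance scaling laws for contact transport are an
  empirical matter.
* **Symmetric intramolecular rates.** Since energies are tracked per degree
  of freedom, detailed balance at equipartition requires $k_{ij} = k_{ji}$,
  making the uniform per-DOF energy distribution an exact fixed point (a
  property test). An alternative parameterization with DOF-ratio asymmetric
  rates would track total residue energies instead; we chose the per-DOF
  convention because the observable (a local temperature rise reported by a
  band shift) is intensive.
* **Single heater and single sink.** Photoexcitation and sub-picosecond
  internal conversion are collapsed into one first-order injection channel
  (rate $k_h$) from a heater pool into the heater residue; solvent
  dissipation is one first-order channel per residue (rate $k_s$). No other
  solvent physics is modelled.

## Edge classes

Edges carry one of five labels. `BB` joins sequence neighbours. `HB` joins
backbone-hydrogen-bonded pairs, detected by a donor–acceptor N···O distance
cutoff (default 3.5 Å) and an N–H···O angle minimum (default 120°) with the
amide hydrogen inferred from the N, Cα and preceding-carbonyl geometry;
pairs closer than three residues in sequence are excluded so the turn's
local geometry does not masquerade as an interstrand contact. `HC` joins the
heater's side chain to residues whose heavy atoms approach it within 4.5 Å
(again $|i-j|\ge 3$); only heater-emanating contacts are considered because
the heater's transient excess energy is what makes otherwise inefficient
van der Waals contacts relevant. A residue pair may carry both an HB and an
HC edge. `HEAT` and `COOL` are the source and sink channels.

## Parameters, units, defaults

| parameter | unit | default | rationale |
|---|---|---|---|
| `D_B` | Å²/ps | 58 | backbone transfer time ≈ 0.25 ps per peptide bond at d = 3.8 Å |
| `D_C` | Å²/ps | 2.5 | contact transfer time ≈ 3.6 ps at r = 3.0 Å, inside the 2–10 ps range typical of contact transport |
| `k_h` | 1/ps | 1 | sub-ps–to–ps heater equilibration |
| `k_s` | 1/ps | 1/6 | experimental solvent dissipation time ≈ 6 ps; taken from experiment, never fitted |
| `Q` | – | 1 (classical) | quantum-corrected analyses use the globally fitted value; a synthetic-truth fit recovers Q = 3.1 to <2% |
| `hb_cutoff` / `hb_angle_min` | Å / ° | 3.5 / 120 | standard backbone H-bond criteria |
| `hc_cutoff` | Å | 4.5 | heavy-atom van der Waals contact range |
| `contact_exponent` | – | 2 | see above |

The heater pool's temperature jump is derived, not set: with the default
2 eV excitation shared over 39 heater degrees of freedom,
$\Delta T = E_{exc}/(k_B n_{dof}) \approx 595$ K on a 300 K baseline —
a ≈600 K jump.

The quantum correction multiplies `k_h`, all `BB`, `HB` and `HC` rates and
leaves `COOL` untouched: an intramolecular hop is fast and strongly affected
by quantum fluctuations of the transporting modes, while dissipation into
the solvent is slow, essentially classical, and anyway taken from
experiment. `Q` is fitted by minimizing the summed squared difference
between model and experimental *sensor peak times* over all variants with
equal weights — peak times rather than full transients because the
experimental observable whose timing is trusted quantitatively is the peak
of the summed-|ΔA| transient, and equal weights because no variant is a
priori more informative.

## Exact integration and peak metrics

The master equation is a small linear constant-coefficient system (≤ ~20
nodes; ~60 states after pathway augmentation), so it is propagated exactly
with matrix exponentials — one `expm` per distinct grid step, then
matrix–vector stepping. This avoids any stiffness issues from the wide rate
ratios ($k_h$ vs $k_s$) and makes grid independence a testable property
(solutions on different grids agree at shared times to 1e-9; total energy
including the sink is conserved to 1e-9 on random symmetric networks).

Peak times are extracted in two ways, which exist for two different jobs:

* `peak_metrics()` interpolates a parabola through the discrete maximum and
  its neighbours — the right tool for *measured or gridded* transients, and
  the same rule is applied to model trajectories and synthetic TRIR
  transients so the two sides are compared like for like. Ties break toward
  the earlier time; a maximum at the first grid point (monotone decay)
  reports peak time 0.
* `refine_peak_time()` maximizes the exact continuous-time solution
  $E(t) = e^{At}E_0$ by golden-section search after bracketing on a coarse
  grid (tolerance 1e-9 ps). This is used where peak times are needed beyond
  grid resolution, e.g. verifying the closed form
  $t^\ast = \ln(k_h/k_s)/(k_h-k_s)$ of the heater–residue–solvent chain to
  1e-6 and generating synthetic "experimental" peak times for the Q-fit
  recovery tests.

## Pathway decomposition

"Energy arriving at the sensor on a class of pathway" is operationalized as
**first passage**: a quantum of energy is attributed to the path it took
until its first arrival at the sensor, and recrossings afterwards are not
counted. The class of a path is `HC` if it traversed any heater contact,
else `HB` if it traversed any hydrogen bond, else `BB`. The precedence is a
convention for mixed paths; we put `HC` first because heater contacts
emanate from the heater and therefore occur at the start of a path. `HEAT`
and `COOL` edges are transparent to classification.

Two independent routes compute the class-resolved arrival fractions:

* **Exact.** Every node is duplicated over the two path flags (seen-HB,
  seen-HC) and the sensor is made absorbing per flag combination; the
  augmented system is still linear and is integrated exactly. By
  construction BB + HB + HC = 1 wherever any energy has arrived, and the
  summed arrival equals the plain absorbing-chain arrival probability
  (tested to 1e-9).
* **Monte Carlo.** The jump chain embedded in the master equation is
  sampled: a walker waits at node $i$ an exponential time with rate
  $\sum_j k_{ij}$, jumps with probability $\propto k_{ij}$, and terminates
  at the sensor, the solvent, or the time horizon. Because the master
  equation is linear, independent unit-energy walkers sample the energy
  flow without bias. The kernel is implemented in C++ (Rcpp) using R's RNG,
  so runs are reproducible under `set.seed`; 10⁶ walkers on a hairpin-sized
  network take a few seconds. The test suite checks the sampler against the
  exact decomposition (3 binomial σ at 10⁶ walkers), against closed-form
  first-passage laws (Kolmogorov–Smirnov), and for the expected
  $1/\sqrt{n}$ shrinkage of the standard error.

The test oracles additionally include an exhaustive depth-limited
enumeration of the embedded discrete chain (dynamic programming over
node × flags), which agrees with the exact method to 1e-6 on small toys.

## Calibration

`fit_transport_coefficients()` minimizes the summed squared residuals of all
residue traces over a coarse logarithmic grid scan (5 points per decade
range per free parameter) followed by Nelder–Mead in log-parameter space
with box projection (bounds $D_B, D_C \in (10^{-3}, 10^3]$ Å²/ps,
$k_h \in (10^{-3}, 10^2]$ /ps). The cooling rate is always held fixed. The
pre-scan matters: the objective has a spurious basin near
(large $D_B$, vanishing $D_C$) under ensemble noise, which a too-coarse scan
can fall into. With the default scan, noise-free truth is recovered to
<1% and 5000-trajectory-noise data to <10% (median over seeds); the
objective profile in $Q$ is verified unimodal over [1, 10] on the hairpin
fixtures.

`fit_cooling_rate()` is a log-linear least-squares fit of a post-peak tail;
it refuses tails that start before the peak or contain non-positive values.

## The synthetic-data generator

`make_idealized_hairpin()` builds a flat antiparallel two-strand geometry:
3.5 Å Cα spacing along strands, strands 5 Å apart, residue $i$ registered
against $n+1-i$, and amide/carbonyl positions arranged so the cross-strand
N···O distances are 3.0 Å with near-linear inferred N–H···O angles — the
hydrogen-bond ladder of a β-sheet as seen by the package's own detector.
The donor carries two dummy side-chain heavy atoms reaching toward the
opposite strand so heater contacts exist. The construction is deterministic.

What it emulates: the topology that drives the science — a long backbone
route in competition with short interstrand shortcuts, donor contacts to
the opposite strand, and variant placements V1 (1→12, opposite strands) and
V4 (1→5, same strand) as designed; V2 (1→10) and V3 (1→8) are assumptions
of this package, placed on the opposite strand with backbone separations
between V1's and V4's. What it does not emulate: real side chains and their
packing, strand twist, turn geometry, conformational heterogeneity, and the
actual contact distances of a real structure. Passing tests on the
idealized scaffold therefore validate the machinery and the qualitative
phenomenology (shortcut timing, contact-rupture delay, quantum speed-up),
not the quantitative pathway percentages of any real peptide — real
structures enter through `parse_pdb()` and are processed identically.

`simulate_noisy_ensemble()` adds i.i.d. Gaussian noise of standard
deviation $E_{scale}/\sqrt{n_{traj}}$ to the exact traces — the
central-limit behaviour of an ensemble average of independent trajectories
(default 5000 trajectories × 50 ps). Real MD noise is correlated in time
and across residues; the i.i.d. model is deliberately the simplest member
of the right scaling family, and the $1/\sqrt{n}$ law itself is tested.

## TRIR forward model

The azide reporter band is a Gaussian (center 2120 cm⁻¹) whose center
red-shifts linearly with sensor energy; the difference spectrum is the
shifted minus the unshifted band on ~32 detector pixels, plus optional
white noise. In the small-shift regime (shift ≪ width) the summed |ΔA| is
proportional to the shift — tested to <2% when doubling the shift
coefficient — and its peak time equals the driving energy's peak time
within a delay step. A Gaussian was chosen because no lineshape is imposed
by the analysis; only the *difference* signal's linearity and timing matter,
and those are lineshape-robust. The "pixels carrying the VET signal" are
selected automatically as all pixels whose time-averaged |ΔA| exceeds 10%
of the maximal pixel's, a quantified stand-in for the experimental manual
window choice.

## Reproducibility and problem sizes

A single global seed fans out into per-stage seeds through a deterministic
hash (`stage_seed()`), so any stage can be rerun in isolation. The test
suite and the acceptance script run on deliberately modest problem sizes —
12-residue hairpins (14-node networks, ~60 augmented states), 10⁶ Monte
Carlo walkers, 10–20 noise seeds for recovery medians, 0.05–0.1 ps grids
over 25–50 ps — chosen so the full suite completes in minutes while every
tolerance stated above is met; all of them scale up by configuration
(e.g. `n_walkers`, `ensemble_spec()`, grid arguments).

## Known limitations

* Rates are constant in time: no temperature-dependent transport, no
  time-dependent structural change. Partial unfolding is represented only
  as pruning of contact edges.
* The scaling-rule exponents and the single-distance dependence are a
  modelling choice; atom-contact-count refinements would slot into
  `assemble_network()` but are not implemented.
* The pathway decomposition counts first passages; occupation-weighted
  accounting after first arrival would require a different augmentation.
* Only the first model of an NMR ensemble and the first chain of a PDB file
  are used; hydrogens are always re-inferred geometrically.
* The TRIR model omits pump scatter, cross-phase modulation, polarization
  effects and absolute amplitude calibration.
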