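---
title: "Modelling carotenoid quenching of the phycobilisome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling carotenoid quenching of the phycobilisome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbsquench)
```

## The model

Cyanobacteria harvest light with the phycobilisome (PBS), a megadalton
antenna in which phycocyanobilin (PCB) chromophores funnel excitation from
six peripheral rods into a tri-cylindrical allophycocyanin core. Under
excess light, the activated orange carotenoid protein (OCP) binds the core
and its canthaxanthin (CAN) drains the excitation as heat through the
optically dark carotenoid S1 state. pbsquench models this process as
incoherent Förster hopping of a single exciton on a network of chromophore
sites, and asks the quantitative question: given the electronic couplings
and energies of the pigments, how fast does an excitation started in a rod
reach a carotenoid and die there?

The model has four layers.

**Sites.** Each chromophore is a point site with a position, a unit
transition-dipole direction, a dipole magnitude $\mu$ (debye), a 0-0 site
energy $E$ (cm$^{-1}$), an intrinsic decay rate (ps$^{-1}$) and a
lineshape. Bilins carry the ~1.6 ns fluorescence lifetime; the carotenoid
S1 state is a fast sink (4 ps by default, configurable, including an
effectively perfect sink by raising its decay rate).

**Couplings.** Bilin–bilin couplings use the point-dipole approximation,

$$V = s\,C\,\kappa\,\frac{\mu_1\mu_2}{R^3},\qquad
\kappa = \hat\mu_1\cdot\hat\mu_2 -
3(\hat\mu_1\cdot\hat R)(\hat\mu_2\cdot\hat R),$$

with $C = 5034\ \mathrm{cm^{-1}\,\mathring A^3\,D^{-2}}$ derived from
CODATA constants (not hard-coded; see `physical_constants()`) and a
screening factor $s$ (default 1, vacuum) exposed in configuration.
Carotenoid–bilin couplings are *not* dipolar — at 10–15 Å separation the
point-dipole approximation is unjustified — so they are either computed by
the TrEsp method from atomic transition charges,
$V_{AB} = K\sum_{i\in A}\sum_{j\in B} q_i q_j / r_{ij}$, or taken as
sampled values on an explicit whitelist of carotenoid–ApcA pairs. All
other carotenoid couplings are exactly zero, reflecting that couplings
beyond the two nearest ApcA bilins (below ~8 cm$^{-1}$) contribute
negligibly to quenching.

**Rates.** For each coupled pair, the energetically downhill direction
gets the Förster rate

$$k = 1.18\, V^2 J \quad
[\,k\,] = \mathrm{ps^{-1}},\ [\,V\,] = \mathrm{cm^{-1}},\
[\,J\,] = \mathrm{cm},$$

where $J$ is the overlap integral of the donor's *mirror-image* emission
lineshape and the acceptor's absorption lineshape, both normalized to unit
area. The uphill direction is obtained from detailed balance,
$k_\mathrm{up} = k_\mathrm{down}\,e^{-\Delta E/k_BT}$, applied to the 0-0
site-energy gap. Applying detailed balance to 0-0 energies (rather than
band maxima) gives each pigment a single unambiguous energy and makes the
closed-network stationary state exactly Boltzmann, which the test suite
verifies against an eigen-solver.

**Dynamics.** A single excitation is propagated with the Gillespie
algorithm: exponential waiting times at the total exit rate, channels
chosen proportionally to their rates, termination at a decay event. An
ensemble redraws the carotenoid parameters (S1 energy and both whitelisted
couplings) independently for each of the four carotenoids in every run and
starts each run from a uniformly chosen rod bilin. A deterministic
master-equation solver (`deSolve::lsoda`, tolerances $10^{-10}$) provides
survival curves, mean lifetimes and terminal-flux splittings as the oracle
against which the stochastic engine is tested.

## Parameters and defaults

| Parameter | Default | Why |
|---|---|---|
| Rod PCB site energy | 16130 cm$^{-1}$ (620 nm) | phycocyanin absorption band |
| ApcA/ApcB energy | 15152 cm$^{-1}$ (660 nm) | core emitters quenched by OCP |
| ApcD/ApcE energy | 14706 cm$^{-1}$ (680 nm) | terminal low-energy emitters |
| PCB decay | 1/1600 ps$^{-1}$ | ~1.6 ns bilin fluorescence lifetime |
| PCB dipole | 13 D | typical phycocyanobilin value |
| CAN S1 vertical energy | 2.00 eV mean, sd 0.07 eV | reported MD-average for OCP-bound CAN |
| CAN S1 dipole | 7 D (metadata) | reported environment-enhanced mean |
| CAN–ApcA couplings | 54 / 27 cm$^{-1}$ means, sd 40% | reported means for the two nearest ApcA bilins |
| CAN S1 decay | 1/4 ps$^{-1}$ | typical keto-carotenoid S1 lifetime |
| Temperature | 300 K | ambient |

The coupling and energy *spreads* are configuration, not measured values:
the underlying distributions are known to be broad but are published only
as figures, so the defaults (truncated normals, energy sd 0.07 eV,
coupling sd 40% of the mean, truncated at zero) are the package's own
choice and should be replaced with empirical samples
(`can_parameter_spec(distribution = "empirical_samples", ...)`) when the
user has them.

### The carotenoid energy convention

The reported 2.00 eV carotenoid energy is a *vertical* (Franck–Condon)
excitation energy — the centre of the absorption band — not a 0-0 energy.
Detailed balance in this package acts on 0-0 energies, so the sampler
carries an `e00_shift_cm1` field (default 1400 cm$^{-1}$, one dominant
C=C stretch vibronic quantum) that maps the sampled vertical energy to the
0-0 site energy: $E_{00} \approx 16131 - 1400 = 14731\ \mathrm{cm^{-1}}$,
just below the ApcA bilins. This matters. Carotenoid S1 bands are broad
and their 0-0 origin lies well below the band maximum; taking 2.00 eV
literally as a 0-0 energy would place the quencher ~980 cm$^{-1}$ *above*
ApcA, and the Boltzmann penalty ($e^{-980/208.5}\approx 0.009$ at 300 K)
would make quenching negligible — inconsistent with the ~100 ps quenched
lifetimes that motivate the model. With the shift, ApcA→CAN transfer is
the downhill direction and the quenching observed experimentally emerges
from the kinetics without further adjustment. Users who prefer a different
convention set `e00_shift_cm1 = 0` and supply their own band positions.

### Lineshapes

The empirical keto-carotenoid S1 emission profile used in the original
parametrization is not tabulated anywhere accessible, so the package ships
a clearly-labelled parametric surrogate: a 0-0 Gaussian plus two vibronic
satellites at +1400 and +2800 cm$^{-1}$ (weights 1.0/0.7/0.3, width
$\sigma = 600$ cm$^{-1}$). Bilins get a 0-0 band plus one +1300 cm$^{-1}$
satellite (weights 1.0/0.5, $\sigma = 500$ cm$^{-1}$). Both are editable
configuration (`default_lineshape_library()`), and measured band shapes
can be imported with `read_tabulated_spectrum()`. Overlap integrals use
the trapezoidal rule on a shared 1 cm$^{-1}$ grid; the suite checks the
integrator against the Gaussian-product closed form to 0.1%.

## The synthetic phycobilisome

`make_toy_pbs()` generates an idealized stand-in for the real complex: a
tri-cylindrical core (two basal cylinders and one top cylinder, eight
bilins each on two disks, alternating ApcA/ApcB with one ApcD and one ApcE
terminal emitter), six rods of six phycocyanin bilins at 25 Å spacing
radiating in the plane perpendicular to the cylinder axes, and four
carotenoids placed 12 Å outside their primary ApcA partner — within the
10–15 Å contact range of the real OCP binding site — and coupled only to
their two nearest ApcA bilins. Dipole directions are tangential with
seeded jitter.

What the toy emulates: the rod→core energy funnel (620 → 660 → 680 nm),
realistic inter-pigment distance scales, the number and wiring of the
quenchers, and the reported mean carotenoid parameters. What it does not:
the true pigment count and disk symmetry of the PBS, linker-protein
effects, structural disorder, and the real parametrization of site
energies and lineshapes. Consequently, passing tests demonstrate that the
kinetics stack is correct and that quenching of the right magnitude
emerges from the reported coupling/energy scales — not that the package
reproduces any particular measured lifetime. Reproducing the ~100 ps
quenched PBS lifetime quantitatively requires the deposited structure
coordinates and the original site-energy/lineshape parametrization as
inputs.

```{r example, eval = FALSE}
net  <- make_toy_pbs()                                   # 64 pigments
ens  <- run_ensemble(net, can_parameter_spec(),
                     n_runs = 1000, master_seed = 1)
mean_lifetime(ens)        # ~60-80 ps with four quenchers attached
quench_fraction(ens)      # ~0.95 of excitons die on a carotenoid

netu <- make_toy_pbs(toy_pbs_config(n_can = 0))
mean_lifetime(run_ensemble(netu, n_runs = 1000, master_seed = 1))
                          # ~1600 ps: the intrinsic bilin lifetime
```

## Numerical choices

- **Constants.** The TrEsp Coulomb constant
  ($1.1614\times10^5$ cm$^{-1}$ Å e$^{-2}$), the point-dipole constant
  (5034 cm$^{-1}$ Å$^3$ D$^{-2}$) and $k_B$ (0.6950348 cm$^{-1}$/K) are
  computed from CODATA values at definition and pinned by unit tests.
- **Tie-break.** For exactly equal site energies the lower-index pigment
  is treated as the donor when evaluating $J$; the reverse rate is then
  identical by detailed balance, so the choice only selects which overlap
  is evaluated directly.
- **Incremental rebuilds.** Per-run ensembles only re-derive the rate
  entries touching carotenoids (`build_rate_matrix(..., base, changed)`);
  a test asserts bit-level agreement with a full rebuild. Overlap
  integrals are memoized on (donor template, acceptor template, energy
  gap), exploiting the shift invariance of $J$.
- **Seeding.** Per-run seeds are drawn once from the master seed, so an
  ensemble is a pure function of (network, sampler, n_runs, master_seed)
  and any single run can be replayed from its recorded seed.
- **Master equation.** `lsoda` with rtol $10^{-10}$/atol $10^{-12}$;
  checked against `Matrix::expm` and closed-form solutions. Probability
  plus cumulative decayed mass stays within $10^{-8}$ of 1.
- **Degenerate inputs.** Zero-exit states raise an explicit
  non-terminating-state error rather than hanging; coincident atoms or
  pigments, disjoint spectral grids, unassigned properties and unknown
  configuration keys are all named errors.
- **Problem sizes.** The shipped checks use the 64-pigment toy network
  with $10^3$ trajectories per ensemble and $10^4$ trajectories for
  engine-vs-oracle comparisons on 6-pigment networks — sizes at which the
  binomial error bars are tight enough to be meaningful while a full suite
  run stays around a minute.

## Known limitations

Single-exciton transport only (no annihilation or light-driven source
terms); incoherent hopping only (no generalized Förster or Redfield
regimes — at 54 cm$^{-1}$ coupling the hopping picture is at the edge of
its validity and is used deliberately, matching the modelling tradition
for this system); geometric principal axes stand in for quantum-chemical
transition-dipole directions when extracting pigments from structures; and
the vacuum screening default ($s = 1$) overestimates couplings in a
protein by roughly the medium's screening factor — users modelling real
structures should set it explicitly.
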