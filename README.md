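# pbsquench

Förster energy transfer and stochastic exciton quenching in
phycobilisome–carotenoid networks.

## What this is for

The phycobilisome (PBS) is the main light-harvesting antenna of
cyanobacteria: hundreds of phycocyanobilin (PCB) chromophores organized
into six rods feeding a tri-cylindrical allophycocyanin core. Under
excess light, the orange carotenoid protein (OCP) binds the core and its
canthaxanthin (CAN) quenches the antenna through the carotenoid's dark S1
state. pbsquench is for photosynthesis researchers who want to turn
structural and quantum-chemical inputs — pigment geometry, transition
charges or sampled couplings, site energies, band shapes — into quenching
kinetics: how fast does an excitation started in a rod die, and on which
pigment?

The package covers the full chain:

1. **Extraction** — pigments (positions, dipole axes, classes) from
   PDB/mmCIF structures (`read_structure`), or a synthetic PBS-like
   network with no external files (`make_toy_pbs`).
2. **Couplings** — point-dipole approximation for bilin–bilin pairs,
   TrEsp Coulomb sums over transition charges or whitelisted sampled
   values for carotenoid–bilin pairs (`build_coupling_matrix`), plus the
   log fold-change metric for dipole perturbation analysis
   (`tdm_fold_change`).
3. **Rates** — Förster rates `k = 1.18 V² J` (V in cm⁻¹, J in cm, k in
   ps⁻¹) from mirror-image emission/absorption overlap integrals, uphill
   rates by detailed balance on the 0-0 energy gap
   (`build_rate_matrix`).
4. **Dynamics** — Gillespie single-exciton trajectories and ensembles
   with per-run resampled carotenoid parameters (`run_ensemble`),
   survival curves, lifetimes and quench fractions, all validated
   against a master-equation solver (`master_equation_solve`).

## Worked example

Four carotenoids, sampled at the reported statistics (mean S1 energy
2.00 eV; mean couplings 54 and 27 cm⁻¹ to the two nearest ApcA bilins),
versus the same network with the quenchers removed:

```r
library(pbsquench)

net <- make_toy_pbs()   # 6 rods, 3 core cylinders, 4 CAN quenchers
net
#> <pigment_network> 64 pigments (APCA_PCB:12, APCB_PCB:10, APCD_PCB:1,
#>   APCE_PCB:1, CAN:4, ROD_PCB:36), 1778 non-zero couplings

ens <- run_ensemble(net, can_parameter_spec(), n_runs = 500,
                    master_seed = 1)
ens
#> <decay_ensemble> 500 trajectories; mean lifetime 77.96 +/- 3.3 ps;
#>   quench fraction 0.958

netu <- make_toy_pbs(toy_pbs_config(n_can = 0))
run_ensemble(netu, n_runs = 500, master_seed = 1)
#> <decay_ensemble> 500 trajectories; mean lifetime 1513 +/- 70 ps;
#>   quench fraction 0

survival_curve(ens, c(0, 50, 100, 200, 400))
#>     t     P      ci_lo       ci_hi
#> 1   0 1.000 1.00000000 1.000000000
#> 2  50 0.522 0.47821632 0.565783683
#> 3 100 0.250 0.21204546 0.287954539
#> 4 200 0.064 0.04254685 0.085453147
#> 5 400 0.004 0.00000000 0.009532517
```

Reading: with four OCP carotenoids attached, the mean excited-state
lifetime collapses from ~1.5 ns (the intrinsic bilin fluorescence
lifetime) to ~80 ps — a ~20-fold quench, on the ~100 ps scale observed
for the fully quenched PBS — and 96% of excitations terminate on a
carotenoid (heat) rather than by bilin fluorescence. Ensembles are pure
functions of their seeds; rerunning with the same `master_seed`
reproduces every trajectory bit for bit.

A full configured pipeline (extract → couple → rate → simulate → report)
runs from a single YAML file:

```r
cmd_simulate("run.yaml")   # writes pigments/couplings/rates/decay CSVs
                           # + manifest JSON with config hash and summary
```

or from the shell via the thin wrapper `inst/scripts/pbsq.R`
(`simulate`, `couplings`, `extract`, `toy`, `validate` subcommands).
See the vignette (`vignettes/quenching-model.Rmd`) for the model, its
assumptions, parameter defaults and their rationale.

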