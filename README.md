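# gaswitch

Integrative biophysical analysis of G-protein α-subunit (Gα<sub>S</sub>)
variants, for structural biologists and spectroscopists comparing
disease-associated mutants against the native protein. Single point mutations
in Gα<sub>S</sub> switch regions perturb an allosteric network linking the
nucleotide-binding pocket to the switch-region interaction network; this
package quantifies that perturbation from three data streams:

* **MD trajectories** — hydrogen-bond occupancy matrices between switch
  regions (geometric criteria: H···A < 2.4 Å, ∠D–H···A > 120°, occupancy =
  fraction of frames), per-residue backbone RMSF about the trajectory mean,
  inter-region nonbonded energies (Coulomb `k_e q_i q_j/r` with
  k<sub>e</sub> = 332.0636 kcal·Å/(mol·e²), plus Lennard-Jones
  `4ε[(σ/r)¹² − (σ/r)⁶]`), normalized to a reference state, and
  nucleotide-proton contact profiles (proximity occupancy and
  closest-residue frequency within 6 Å of protons a–d).
* **STD-NMR** — amplification factors
  `A_STD = (I₀ − I_sat)/I₀ × [L]/[P]`, uncertainty
  `σ = A_STD / SNR_diff`, normalization to the reference proton "a" (in %),
  and interaction bins (≤50 weak, 50–100 weak-moderate, 100–150 moderate,
  >150 strong).
* **Stability / kinetics** — Boltzmann sigmoidal melts
  `Y = Bottom + (Top − Bottom)/(1 + exp((V₅₀ − X)/Slope))` (V₅₀ = T_m;
  triplicate mean ± SD; ΔT_m with SDs in quadrature) and one-phase
  association exchange traces `Y = Y₀ + (Plateau − Y₀)(1 − e^{−kx})`.

A seeded synthetic-data generator plants known H-bond/contact occupancies
(two-state telegraph processes), spectral attenuations, and curve parameters
into every input class, so the entire pipeline is testable without any
experimental download. A `run_pipeline()` / `compare_systems()` layer
assembles per-system reports and reference comparisons
(ΔT_m, gained/lost H-bonds, energy ratios, fingerprint bin shifts).

## Worked example

A synthetic reference/variant pair with three planted differences — a 9 °C
destabilization, a lost switch-II/switch-III hydrogen bond (R228→E259), and
a proton-b STD fingerprint shift from 90% to 160%:

```r
library(gaswitch)
# mk() builds one system: triplicate melt CSV, a 150-frame trajectory with
# an optional planted 228->259 H-bond, and an STD peak table (see
# vignettes/methods.Rmd for the full definition)
cfg <- list(systems = list(mk("WT:GTP", 71, 0.8,  90, 11),
                           mk("MUT:GTP", 62, 0,  160, 13)),
            reference = "WT:GTP")
cmp <- compare_systems(run_pipeline(cfg))
cmp[["MUT:GTP"]]$delta_tm
#> $delta_tm
#> [1] -8.99239
#> $sd
#> [1] 0.03142963
cmp[["MUT:GTP"]]$hbond[["switch_II-switch_III"]]$lost
#>   donor_resno donor_atom acceptor_resno acceptor_atom count occupancy
#> 1         228          N            259             O   113 0.7533333
cmp[["MUT:GTP"]]$stdaf_bins
#>   proton normalized_pct_ref       bin_ref normalized_pct_sys  bin_sys shifted
#> 1      a                100      moderate                100 moderate   FALSE
#> 2      b                 90 weak-moderate                160   strong    TRUE
```

Reading: the variant melts 9.0 ± 0.03 °C lower than the reference; the
R228→E259 hydrogen bond present in 75% of reference frames is absent in the
variant; and the proton-b amplification factor moves from the weak-moderate
bin (90% of proton a) to the strong bin (160%), i.e. a stronger local
interaction of the ribose H1' proton with the pocket.

A thin CLI wrapper ships in `inst/scripts/switch-allostery`
(`run`, `compare`, `melt-fit`, `kinetics-fit` subcommands).

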