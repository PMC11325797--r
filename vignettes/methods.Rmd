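---
title: "Methods: switch-region interaction networks, STD-NMR amplification factors, and stability fits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: switch-region interaction networks, STD-NMR amplification factors, and stability fits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaswitch)
```

# Scope

`gaswitch` analyses the biophysics of G-protein alpha-subunit (Gα~S~)
variants from three complementary data streams: molecular-dynamics
trajectories (hydrogen-bond networks between the switch regions, per-residue
backbone RMSF, inter-region nonbonded energies, and nucleotide-proton contact
profiles), saturation-transfer-difference (STD) NMR peak tables or spectra
(amplification factors), and thermal-unfolding / nucleotide-exchange curves
(Boltzmann and one-phase association fits). It does **not** run MD, model
missing loops, assign protonation states, or automate the biological
gain-/loss-of-function interpretation; those remain upstream or downstream of
this package.

# Trajectories and superposition

Structures are read from PDB files (author residue numbering preserved
throughout; HETATM ligand records retained), trajectories from CHARMM-style
DCD or multi-model PDB files. A minimal DCD *writer* is included so that
synthetic trajectories can round-trip through the standard format.

RMSF requires a common frame of reference, so `superpose()` fits every frame
onto an iteratively refined mean structure of the analysis selection
(Kabsch rotation + translation; at most 5 iterations, converged when the mean
moves < 1e-6 Å — in practice 2 iterations suffice). Hydrogen-bond and contact
geometry is invariant under rigid motion, so those analyses run on raw
frames. Per residue, RMSF is the unweighted mean over backbone atoms
N, CA, C and O of `sqrt(mean |x - mean(x)|²)`.

Note one statistical subtlety the test suite relies on: for synthetic frames
built as iid displacements about a fixed reference there is no rigid-body
motion to remove, and superposing such a trajectory absorbs roughly
`6/(3 n_sel)` of the variance into the fitted transforms. The analytic RMSF
check therefore runs without superposition.

# Hydrogen-bond networks

A bond D–H···A is counted in a frame when the **H-to-acceptor** distance is
below 2.4 Å and the D–H···A angle exceeds 120°. We read the conventional
"donor-H···acceptor distance" phrasing as the H···A distance (not the heavy
atom separation); both cut-offs are configurable. Donors are hydrogens
covalently attached to N or O (assignment by nearest heavy atom within
1.25 Å of the topology reference coordinates — connectivity does not change
along a trajectory); acceptors are all N and O atoms, backbone and
side-chain, with no additional angle criterion at the acceptor. A topology
without hydrogens raises an explicit error rather than silently returning an
empty network.

Occupancy is the per-frame indicator averaged over frames: a pair detected
through two different hydrogens in the same frame still counts once. Both
directions across a region pair are evaluated. Atom-level pairs are primary;
a residue-level aggregation connects a residue pair when any of its
atom-level pairs passes. Persistence tiers count how many of the (default
0.25 / 0.50 / 0.75, configurable) thresholds an occupancy meets, with
inclusive (≥) comparisons so boundary cases are deterministic. Network
comparisons classify pairs as gained/lost/shared by presence at a threshold
(default 0.5) in each matrix.

Switch-region definitions are configuration data, not code: the shipped YAML
gives switch I = 197–207, switch II = 219–236, switch III = 254–270
(author numbering), ranges chosen to contain the commonly discussed switch
residues (R201, S205, G226, Q227, R228, E230, R258, E259, R265, E268).

# Nonbonded interaction energies

Between two disjoint residue groups, per frame, the package sums the Coulomb
term `k_e q_i q_j / r` (k_e = 332.0636 kcal·Å/(mol·e²)) and Lennard-Jones
`4ε[(σ/r)¹² − (σ/r)⁶]` over all inter-group atom pairs, then averages over
frames. Combining rules: geometric mean for both σ and ε (OPLS convention)
by default, Lorentz–Berthelot optional. No distance cut-off is applied —
groups are tens of atoms, so exact summation is cheap, and this deliberately
differs from engine-side cut-off schemes. Energies are reported normalized to
a reference system (same region pair), because the ratios, not the absolute
values, carry the comparison; the reference row is exactly 1 by construction.

The bundled parameter CSV covers only the atoms of the synthetic toy systems
and is explicitly non-authoritative; production use requires a
force-field-derived table in the same format.

# Nucleotide-proton contact profiles

For each monitored nucleotide proton (labels a–d; defaults a = H8,
b = H1', c = H2', d = the two equivalent H5' protons, configurable), the
package measures per residue the fraction of frames with a residue hydrogen
inside a 6 Å radius (`proximity_occupancy`) and the fraction of frames in
which the residue is the closest (`closest_frequency`; ties go to the lower
residue number; frames with nothing in radius count toward no residue, so
closest frequencies may sum below 1). Distances are **proton-to-proton**
because saturation transfer is proton-mediated; the radius and the H–H
convention are configurable. Equivalent protons are measured independently
and merged by arithmetic averaging; a union-over-protons occupancy is also
emitted. Cross-system aggregation reports mean ± SEM in percent, counting a
residue absent from a system's profile as 0 there, and refuses to report an
SEM for fewer than two systems.

# STD-NMR amplification factors

The amplification factor of a signal is
`ASTD = (Idiff / I0) × [L]/[P]`, with `Idiff` the signal integral in the
difference spectrum (equivalently `I0 − Isat`), `I0` the reference
(off-resonance) integral, and `[L]/[P]` the molar excess of ligand over
protein. Its uncertainty is `σ = ASTD / SNRdiff`, with `SNRdiff` the
signal-to-noise ratio of the signal in the difference spectrum, measured as
peak height over **twice** the RMS noise of a declared signal-free region
(the common spectrometer "sino" convention; the divisor is configurable).
Per-proton values are normalized to a reference proton (default "a", the
guanine-base proton whose local environment is the most invariant) and
expressed in percent; relative errors propagate in quadrature,
`σ_norm/norm = sqrt((σ/A)² + (σ_ref/A_ref)²)`, the standard first-order
treatment for a ratio (the propagation rule is a package choice — the σ
formula itself does not prescribe one). Normalized percentages map to
interaction bins: ≤ 50 weak, (50, 100) weak–moderate, [100, 150] moderate
(closed at 100 because the reference proton itself sits there), > 150
strong — a total function on [0, ∞).

The primary input is an instrument-agnostic peak-table CSV. For array data
the package also provides FID processing (exponential apodization
`exp(−π·LB·t)` with LB = 3 Hz default, zero-filling, DFT, polynomial
baseline correction of degree ≤ 2 on declared signal-free regions),
difference spectra (axes must agree exactly — no silent interpolation), and
sign-preserving trapezoidal window integration. Vendor raw formats are out
of scope.

## Why the σ interval behaves like a 95% error bar

`σ = ASTD/SNRdiff` with the sino convention equals `2·RMS/height × ASTD`.
The sampling error of the windowed trapezoidal integral of the difference
spectrum is `SE ≈ sqrt(W)·s·Δ·(L/P)/I0` (W points of spacing Δ, noise SD s).
The ratio σ/SE is therefore `2πγ/(sqrt(W)Δ)` for a Lorentzian of half-width
γ whose area dominates the window. The synthetic-spectra defaults — 16384
points over 12 ppm (Δ ≈ 7.3·10⁻⁴ ppm), 6 Hz FWHM at 800 MHz
(γ ≈ 3.75·10⁻³ ppm), integration half-window 0.1 ppm (W ≈ 273) — put this
ratio at ≈ 1.95, i.e. σ approximates a 1.96-SE bound, so the interval
±σ covers the true value ~95% of the time. This is a design calculation,
not a fit: with other acquisition settings the σ interval keeps its
qualitative meaning but not the exact coverage.

# Stability and exchange-kinetics fits

Thermal unfolding follows the Boltzmann sigmoidal
`Y = Bottom + (Top − Bottom)/(1 + exp((V50 − X)/Slope))`, whose midpoint
`V50` is the melting temperature Tm. As printed the model *rises* with X
while a folded fraction *falls*; with normalization fixed (Top = 1,
Bottom = 0) the package therefore fits the printed model to the unfolded
fraction `1 − Y`, which is algebraically `Y = 1/(1 + exp((X − V50)/Slope))`
for the folded fraction, and reports V50 and Slope unchanged. Raw
ellipticity traces are first normalized to folded fraction via an
unconstrained pre-fit whose asymptotes define the folded (→ 1) and unfolded
(→ 0) plateaus; the map is idempotent on already-normalized input. For the
unconstrained fit the optimizer sees Y rescaled to unit range (raw
millidegree scales otherwise produce a numerically singular initial
gradient) and parameters are mapped back exactly.

Nucleotide exchange follows the one-phase association
`Y = Y0 + (Plateau − Y0)(1 − e^{−kx})`, with `k` in reciprocal x-axis time
units. Both fits use Levenberg–Marquardt least squares (`minpack.lm`) with
deterministic initialization: V50 at the half-range crossing, Slope =
range(X)/10; Plateau from the tail mean, Y0 from the first point, k from a
log-linear fit of `log(Plateau_est − Y)`. A fit whose V50 falls outside the
measured temperature range, or flat data (range below 5× a local noise
estimate), raise errors rather than returning nonsense; a fitted `1/k`
exceeding a third of the observation window triggers an identifiability
warning. Replicate Tm values aggregate as mean ± sample SD (the triplicate
convention by default, any n ≥ 2 accepted), and state differences as
`ΔTm = Tm_a − Tm_b` with SDs combined in quadrature.

# Synthetic data: what it emulates, and what it does not

The generators produce every input class with planted ground truth, because
estimators can only be validated against known truth:

* **Trajectories** — frames are a toy two-chain topology (grid-placed
  minimal residues plus a nucleotide-like ligand; small enough for O(N²)
  brute-force oracles) plus iid Gaussian displacements. Hydrogen bonds and
  contacts are planted by two-state telegraph processes (exponential dwell
  times, default correlation length 20 frames — chosen over iid coin flips
  so occupancy autocorrelation resembles real trajectories) that move the
  relevant atoms into or out of criteria geometry. Planted atoms are
  positioned deterministically (no jitter) so the analysis reproduces the
  ledger counts *exactly*; the ledger also records a 99% interval for the
  realized occupancy around the target under the autocorrelation-inflated
  binomial variance `p(1−p)/n × (1+λ)/(1−λ)`, `λ = exp(−1/corlen)`.
* **Spectra** — Lorentzian peaks at stated shifts; on-resonance areas are
  `(1 − α)` times off-resonance areas, so the difference spectrum holds
  exactly `α` per peak and the windowed `Idiff/I0` ratio is exactly α for
  any window (both integrals scale the same lineshape). Additive Gaussian
  noise; an optional broad background hump present identically in both
  spectra (it cancels in the difference, as a matched protein-only
  reference would).
* **Curves** — exact model evaluation plus Gaussian noise (additive or
  proportional), replicate-wise independent. Default schedules mirror
  standard acquisition: 65 temperatures over 25–89 °C; 1000 time points
  every 12 s out to 200 min.

Every generator takes a mandatory seed and is bit-reproducible. What the
generators do **not** emulate: force-field physics, solvent, correlated
multi-atom motions, spin diffusion, lineshape distortions, baseline drift.
Passing tests therefore demonstrate that the estimators are correct and
well-calibrated under the stated noise models — not that real trajectories
or spectra satisfy those models.

# Validation conditions and problem sizes

The package's acceptance checks run at these sizes, chosen to make
statistical tolerances meaningful while keeping the suite quick: 20 random
500-frame fixtures for oracle equivalence; planted occupancies
0.10/0.50/0.75/0.95 over 5000 frames; 10000 frames for the analytic RMSF
check (per-atom relative SE ≈ 0.4%, against a 2% band); 200 noisy spectra
for σ coverage (binomial SE ≈ 1.5% around 95%); 500 melt curves at
V50 = 55 °C, Slope = 2, noise SD 0.03; 300 kinetics traces at k = 0.02 min⁻¹
with 1% proportional noise.

# Known limitations

* XTC trajectories are not read (no reader in the R dependency stack); use
  DCD or multi-model PDB.
* Residue-level H-bond occupancy is reported as the maximum over atom-level
  pairs, a lower bound on the per-frame union occupancy (exact when one atom
  pair dominates, as in the planted fixtures).
* Nonbonded energies are bare pairwise sums: no solvent screening, cut-off,
  or long-range correction, so only normalized ratios should be compared
  across systems.
* The Fig-style interaction bins omit measurement uncertainty; a value whose
  σ interval straddles a bin boundary still maps to a single bin.
* No Kd estimation, STD build-up analysis, van 't Hoff thermodynamics, or
  two-state model testing.

# A worked example

```{r example}
set.seed(1)
# synthetic reference/variant pair: 9 C destabilization, one lost
# switch-II/III hydrogen bond, proton-b fingerprint 90% -> 160%
dir <- tempdir()
mk <- function(label, tm, occ, b_pct, seed) {
  melt <- generate_curves(curve_spec("boltzmann",
    list(V50 = tm, Slope = 2, Top = -8, Bottom = -1),
    seed = seed, noise_sd = 0.05, replicates = 3))
  melt_csv <- file.path(dir, paste0(gsub(":", "_", label), ".csv"))
  write.csv(data.frame(temperature = melt$curves$x,
                       ellipticity = melt$curves$y,
                       replicate = melt$curves$replicate),
            melt_csv, row.names = FALSE)
  plants <- if (occ > 0)
    list(list(donor_resno = 228, acceptor_resno = 259, occupancy = occ)) else list()
  traj <- generate_trajectory(trajectory_spec(n_frames = 150, seed = seed + 1,
                                              hbond_plants = plants))
  peaks <- data.frame(proton = c("a", "b"),
                      window_lo_ppm = c(8.0, 5.8), window_hi_ppm = c(8.2, 6.0),
                      I0 = 1000, Idiff = c(20, 20 * b_pct / 100), SNR = 30)
  list(label = label, melt_csv = melt_csv,
       stdaf = list(peaks = peaks, ligand_conc = 2000, protein_conc = 40),
       trajectory = list(object = traj$trajectory))
}
cfg <- list(systems = list(mk("WT:GTP", 71, 0.8, 90, 11),
                           mk("MUT:GTP", 62, 0, 160, 13)),
            reference = "WT:GTP")
cmp <- compare_systems(run_pipeline(cfg))
cmp[["MUT:GTP"]]$delta_tm
cmp[["MUT:GTP"]]$hbond[["switch_II-switch_III"]]$lost
cmp[["MUT:GTP"]]$stdaf_bins
```
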