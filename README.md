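# adsorbkit

Post-processing toolkit for quantum-mechanical studies of drug adsorption
on oxide surfaces — the analysis layer that sits downstream of periodic
DFT and ab-initio MD codes. The motivating system is a 1,4-benzodiazepine
hydrogen-bonded through its azomethine (C=N) nitrogen to a silanol of an
amorphous silica surface, where a proton transfer from the silanol to the
ring nitrogen is the first step of the drug's acid-catalysed degradation.
The package answers three questions about such a system, for anyone who
has the raw outputs in hand:

1. **How strongly, and why, does the drug bind?** Counterpoise (BSSE)
   interaction-energy decomposition from a ledger of total energies
   `E(X//Y)`:

   ```
   dE   = E(SN//SN) − [E_M(N//N) + E(S//S)]
   dE   = dE* + δE_S + δE_N,            δE_N = dE_N + dE_L
   dE^C = dE*^C + δE_S + dE_N + dE_L,   BSSE = dE^C − dE ≥ 0
   ```

   plus the dispersion split `Disp. = dE^D − dE` of energies computed
   with/without an empirical dispersion correction, and its fraction
   `Disp./dE^D`.

2. **What does the H-bond do at 300 K?** RMSD time series vs. a reference
   frame, atom-pair distance series (minimum-image aware), H-bond length
   histograms with Gaussian fits, and proton-transfer kinetics: a
   hysteretic two-distance state criterion, event counting, the
   characteristic time τ, the rate k = 1/τ, and the Eyring barrier
   `ΔG‡ = RT ln(k_B T / (h k))`.

3. **Would you see it in the IR?** Lorentzian/Gaussian broadening of
   harmonic mode tables (peak-normalized) and greedy nearest-frequency
   matching of gas vs. adsorbed bands into shift reports.

A seeded synthetic-data module (two-state Markov/Ornstein–Uhlenbeck
proton-transfer trajectories, energy ledgers with known decompositions,
random mode tables) makes the whole pipeline testable without any
electronic-structure run. See `vignette("adsorption-analysis")` for the
model details and design choices.

## Worked example

```r
library(adsorbkit)

# --- energetics: a ledger whose terms are known by construction
led <- energy_ledger(
  e_complex = -100, e_surface_relaxed = -40, e_molecule_relaxed = -30,
  e_surface_deformed = -38, e_molecule_deformed_periodic = -27,
  e_molecule_deformed_isolated = -28, e_surface_ghosted = -41,
  e_molecule_ghosted = -29, unit = "kJ/mol")
decompose_ledger(led)
#> Counterpoise interaction-energy decomposition [kJ/mol]
#>   dE       -30.0000
#>   dE*      -35.0000
#>   delta_S  2.0000
#>   delta_N  3.0000
#>   dE_N     2.0000
#>   dE_L     1.0000
#>   dE*^C    -30.0000
#>   dE^C     -25.0000
#>   BSSE     5.0000

# --- dispersion split of published interaction energies (hydrophilic
# 4.5 OH/nm2 silica): binding is >90% dispersion
dispersion_split(-10.1, -104.9)
#> Dispersion split [kJ/mol]
#>   dE (no disp.)     -10.10
#>   dE^D (disp.)     -104.90
#>   dispersion        -94.80
#>   fraction of dE^D   90.4%

# --- kinetics on a 50 ps synthetic proton-transfer trajectory
sim <- generate_two_state_trajectory(two_state_params(duration = 50,
                                                      seed = 11))
d_nh <- pair_distance_series(sim$trajectory, 3, 2)$distance
d_oh <- pair_distance_series(sim$trajectory, 1, 2)$distance
proton_transfer_kinetics(d_nh, d_oh, dt_fs = 0.5)
#> Proton-transfer kinetics @ 300 K
#>   forward events    23 in 50.00 ps
#>   tau (total/events)   2.174 ps  -> k = 4.600e+11 1/s
#>   tau (bound residence) 1.392 ps -> k = 7.186e+11 1/s
#>   Eyring barrier    6.51 kJ/mol

# --- gas -> adsorbed IR band shifts
band_shift(mode_table(c(1607, 3478), c(50, 80), "gas"),
           mode_table(c(1610, 3453), c(55, 70), "4.5 OH/nm2"),
           window = 100)
#> Band shifts (adsorbed - gas), window 100 1/cm
#>     1607.0 ->   1610.0   shift   +3.0 1/cm
#>     3478.0 ->   3453.0   shift  -25.0 1/cm
```

Reading the output: the ledger decomposes into a −30 kJ/mol interaction of
which 5 kJ/mol is basis-set artefact (BSSE); the dispersion split shows the
drug–silica attraction is 90.4% dispersion even though the H-bond drives
the chemistry; the kinetics block counts 23 proton-transfer events in
50 ps, giving τ ≈ 2.2 ps and a ~6.5 kJ/mol Eyring barrier (a short run —
both estimators carry ~20% sampling error at 23 events); and the band-shift
report shows the N–H stretch red-shifting by 25 cm⁻¹ on adsorption while
the reactive C=N band barely moves.

A command-line wrapper over the same functions is installed at
`exec/adsorbkit.R` (subcommands `energetics`, `traj`, `kinetics`,
`spectra`, `synth`, `demo`); `run_demo()` executes the full synthetic
pipeline and writes one JSON report.

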