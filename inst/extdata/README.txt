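interaction_energies.csv
  Published BSSE-corrected electronic interaction energies (kJ/mol) for
  nitrazepam adsorbed on two amorphous silica surface models (silanol
  densities 4.5 and 1.5 OH/nm2), computed with and without the empirical
  dispersion correction; the *_post_md column holds the re-optimized
  values after 12 ps of ab initio MD. Used as input for the dispersion
  split: Disp. = dE_disp - dE, fraction = Disp. / dE_disp.

gas_modes_synthetic.csv, adsorbed_modes_synthetic.csv
  Synthetic stand-in mode tables (full tables are not deposited): the two
  published marker bands of the gas-phase drug -- the azomethine C=N
  stretch at 1607 1/cm and the amide N-H stretch at 3478 1/cm -- and
  their published positions on the hydrophilic (4.5 OH/nm2) surface
  (1610 and 3453 1/cm), padded with identical low-intensity filler bands.
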