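schema: 1
compound: Oli
notes: >
  Olivetol toward the hydroperoxyl radical (HOO) in pentyl ethanoate and in
  water at pH 7.4. Activation free energies (kcal/mol) and tunneling
  corrections are the published one-decimal values; the published apparent
  rate constants are carried as fixed_rate so that table-level aggregation
  arithmetic (k_f, branching ratios, overall rate) reproduces the source
  table exactly. Mole fractions are the published two-state populations;
  the SET row stores the reported reorganization energy (no reaction free
  energy was reported, so the fixed rate is authoritative for that channel).
acid_base:
  pka_values: [9.9]
  state_labels: [Oli, Oli-]
media:
- name: pentyl ethanoate
  is_aqueous: false
  viscosity: 8.62e-4
- name: water
  is_aqueous: true
  ph: 7.4
  viscosity: 8.91e-4
states:
- {label: Oli, charge: 0, mole_fraction: 0.9968}
- {label: Oli-, charge: -1, mole_fraction: 0.0032}
channels:
- mechanism: FHT
  site: 1OH
  radical: HOO
  medium: pentyl ethanoate
  species_state: Oli
  activation_free_energy: 19.1
  tunneling: 145.8
  fixed_rate: 9.60
- mechanism: FHT
  site: 3OH
  radical: HOO
  medium: pentyl ethanoate
  species_state: Oli
  activation_free_energy: 19.1
  tunneling: 145.8
  fixed_rate: 9.60
- mechanism: FHT
  site: 7CH
  radical: HOO
  medium: pentyl ethanoate
  species_state: Oli
  activation_free_energy: 22.1
  tunneling: 55.2
  fixed_rate: 2.30e-2
- mechanism: SET
  site: e
  radical: HOO
  medium: water
  species_state: Oli-
  activation_free_energy: 1.4
  marcus: {reorganization_energy: 1.8}
  fixed_rate: 1.80e+9
- mechanism: FHT
  site: 1OH
  radical: HOO
  medium: water
  species_state: Oli
  activation_free_energy: 18.8
  tunneling: 2476.9
  fixed_rate: 2.70e+2
- mechanism: FHT
  site: 3OH
  radical: HOO
  medium: water
  species_state: Oli
  activation_free_energy: 18.8
  tunneling: 2476.9
  fixed_rate: 2.70e+2
- mechanism: FHT
  site: 7CH
  radical: HOO
  medium: water
  species_state: Oli
  activation_free_energy: 19.8
  tunneling: 47.3
  fixed_rate: 9.40e-1
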