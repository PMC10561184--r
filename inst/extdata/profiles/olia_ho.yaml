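schema: 1
compound: OliA
notes: >
  Olivetolic acid toward the hydroxyl radical (HO). Phenolic OH abstractions
  at the diffusion limit enter through per-radical medium overrides
  (2.60e+9 in pentyl ethanoate, 2.30e+9 in water). The water RAF rate is
  back-computed from the published weighted rate (1.65e+7 / 0.9977). The
  published tunneling entry "0.0" for the water 7CH channel is a
  not-reported marker and is omitted (kappa defaults to 1).
acid_base:
  pka_values: [4.4, 10.3]
  state_labels: [OliA, OliA-, OliA-2]
media:
- name: pentyl ethanoate
  is_aqueous: false
  viscosity: 8.62e-4
  diffusion_limit_override: {HO: 2.60e+9}
- name: water
  is_aqueous: true
  ph: 7.4
  viscosity: 8.91e-4
  diffusion_limit_override: {HO: 2.30e+9}
states:
- {label: OliA, charge: 0, mole_fraction: 0.0010}
- {label: OliA-, charge: -1, mole_fraction: 0.9977}
- {label: OliA-2, charge: -2, mole_fraction: 0.0013}
channels:
- mechanism: FHT
  site: 1OH
  radical: HO
  medium: pentyl ethanoate
  species_state: OliA
  barrierless: true
- mechanism: FHT
  site: 3OH
  radical: HO
  medium: pentyl ethanoate
  species_state: OliA
  barrierless: true
- mechanism: FHT
  site: 7CH
  radical: HO
  medium: pentyl ethanoate
  species_state: OliA
  activation_free_energy: 6.1
  tunneling: 0.3
  fixed_rate: 5.40e+7
- mechanism: RAF
  site: C1-C6
  radical: HO
  medium: pentyl ethanoate
  species_state: OliA
  fixed_rate: 1.04e+8
- mechanism: FHT
  site: 1OH
  radical: HO
  medium: water
  species_state: OliA-
  barrierless: true
- mechanism: FHT
  site: 3OH
  radical: HO
  medium: water
  species_state: OliA-
  barrierless: true
- mechanism: FHT
  site: 7CH
  radical: HO
  medium: water
  species_state: OliA-
  activation_free_energy: 4.5
  fixed_rate: 9.1e+7
- mechanism: SET
  site: e
  radical: HO
  medium: water
  species_state: OliA-2
  activation_free_energy: 0.2
  marcus: {reorganization_energy: 21.2}
  fixed_rate: 1.50e+9
- mechanism: RAF
  site: C1-C6
  radical: HO
  medium: water
  species_state: OliA-
  fixed_rate: 1.6538e+7
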