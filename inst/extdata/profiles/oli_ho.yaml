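schema: 1
compound: Oli
notes: >
  Olivetol toward the hydroxyl radical (HO). The phenolic OH abstractions
  proceed at the diffusion limit; the published diffusion constants
  (2.60e+9 in pentyl ethanoate, 2.30e+9 in water) enter as per-radical medium
  overrides because the underlying radii were not reported. The water RAF
  rate is back-computed from the published weighted rate (4.48e+7 / 0.9968);
  the published tunneling entry "0.0" for the water 7CH channel is a
  not-reported marker and is omitted here (kappa defaults to 1); the
  published apparent rate is carried as fixed_rate.
acid_base:
  pka_values: [9.9]
  state_labels: [Oli, Oli-]
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
- {label: Oli, charge: 0, mole_fraction: 0.9968}
- {label: Oli-, charge: -1, mole_fraction: 0.0032}
channels:
- mechanism: FHT
  site: 1OH
  radical: HO
  medium: pentyl ethanoate
  species_state: Oli
  barrierless: true
- mechanism: FHT
  site: 3OH
  radical: HO
  medium: pentyl ethanoate
  species_state: Oli
  barrierless: true
- mechanism: FHT
  site: 7CH
  radical: HO
  medium: pentyl ethanoate
  species_state: Oli
  activation_free_energy: 6.0
  tunneling: 0.6
  fixed_rate: 1.60e+8
- mechanism: RAF
  site: C1-C6
  radical: HO
  medium: pentyl ethanoate
  species_state: Oli
  fixed_rate: 5.81e+7
- mechanism: SET
  site: e
  radical: HO
  medium: water
  species_state: Oli-
  activation_free_energy: 0.1
  marcus: {reorganization_energy: 20.2}
  fixed_rate: 2.10e+9
- mechanism: FHT
  site: 1OH
  radical: HO
  medium: water
  species_state: Oli
  barrierless: true
- mechanism: FHT
  site: 3OH
  radical: HO
  medium: water
  species_state: Oli
  barrierless: true
- mechanism: FHT
  site: 7CH
  radical: HO
  medium: water
  species_state: Oli
  activation_free_energy: 4.3
  fixed_rate: 9.20e+7
- mechanism: RAF
  site: C1-C6
  radical: HO
  medium: water
  species_state: Oli
  fixed_rate: 4.4944e+7
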