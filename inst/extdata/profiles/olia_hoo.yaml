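schema: 1
compound: OliA
notes: >
  Olivetolic acid toward the hydroperoxyl radical (HOO). The pentyl
  ethanoate 7CH channel deliberately carries no fixed rate: its apparent
  rate constant is recomputed from the published activation free energy
  (21.4 kcal/mol) and tunneling correction (66.9) through the TST +
  Collins-Kimball path, exercising the computed route. The water channels
  carry the published apparent rates as fixed_rate. Known source
  inconsistency: the published weighted rate of the dianion SET channel
  (1.87e+6) does not equal f * k_app = 0.0013 * 1.20e+9 = 1.56e+6; this profile
  yields the self-consistent 1.56e+6.
acid_base:
  pka_values: [4.4, 10.3]
  state_labels: [OliA, OliA-, OliA-2]
media:
- name: pentyl ethanoate
  is_aqueous: false
  viscosity: 8.62e-4
- name: water
  is_aqueous: true
  ph: 7.4
  viscosity: 8.91e-4
states:
- {label: OliA, charge: 0, mole_fraction: 0.0010}
- {label: OliA-, charge: -1, mole_fraction: 0.9977}
- {label: OliA-2, charge: -2, mole_fraction: 0.0013}
channels:
- mechanism: FHT
  site: 7CH
  radical: HOO
  medium: pentyl ethanoate
  species_state: OliA
  activation_free_energy: 21.4
  tunneling: 66.9
- mechanism: FHT
  site: 7CH
  radical: HOO
  medium: water
  species_state: OliA-
  activation_free_energy: 16.3
  tunneling: 33.2
  fixed_rate: 2.50e+2
- mechanism: SET
  site: e
  radical: HOO
  medium: water
  species_state: OliA-2
  activation_free_energy: 1.5
  marcus: {reorganization_energy: 2.0}
  fixed_rate: 1.20e+9
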