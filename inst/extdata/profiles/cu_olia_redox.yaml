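schema: 1
metal: Cu2+
ligand: OliA-
ligand_fraction: 0.9977
notes: >
  Cu(II) chelation by the olivetolic acid monoanion (the only
  chelation-active state at pH 7.4) and the Marcus parameterization of the
  single-electron-transfer reactions of the resulting complexes with
  superoxide (O2-) and ascorbate (Asc-). The per-pair diffusion limits k_D
  are not reported in the source; they are back-solved here from the
  published (k, k_app) pairs through the Collins-Kimball relation
  k_D = 1 / (1/k_app - 1/k) and are therefore synthetic bookkeeping values
  (~3.8e+9 - 4.5e+9 M^-1 s^-1, the expected aqueous diffusion range).
complexation:
- {denticity: mono, delta_g: -9.2}
- {denticity: bi, delta_g: -12.3}
redox_steps:
- {complex: aquacomplex, reductant: O2-, lambda: 31.7, delta_g: -14.9, k_D: 3.8496e+9}
- {complex: monodentate, reductant: O2-, lambda: 37.9, delta_g: -23.4, k_D: 4.1484e+9}
- {complex: bidentate, reductant: O2-, lambda: 29.0, delta_g: -20.5, k_D: 4.4791e+9}
- {complex: aquacomplex, reductant: Asc-, lambda: 26.8, delta_g: -0.5, k_D: 4.5235e+9}
- {complex: monodentate, reductant: Asc-, lambda: 19.4, delta_g: -9.0, k_D: 3.8044e+9}
- {complex: bidentate, reductant: Asc-, lambda: 22.8, delta_g: -27.4, k_D: 4.3545e+9}
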