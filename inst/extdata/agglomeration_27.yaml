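schema: brownsim/1
box:
  L_nm:
  - 30.0
  - 30.0
  - 30.0
  modes:
  - periodic
  - periodic
  - periodic
config:
  timestep_ps: 10.0
  steps: 2000000.0
  stride: 1000
  kT: 0.0024361
  hi: no
  kappa_per_nm: 0.0
  eps_r: 80.0
  seed: 1
  record: full
  tensor_stride: 1
  propagation: auto
colour_pairs:
- colour_a: 1
  colour_b: 1
  epsilon_kT: 1.0
  sigma_nm: 0.68
  attractive: no
  cutoff_nm: 2.04
  r_lin_nm: 0.6
- colour_a: 1
  colour_b: 2
  epsilon_kT: 1.0
  sigma_nm: 0.68
  attractive: no
  cutoff_nm: 2.04
  r_lin_nm: 0.6
- colour_a: 2
  colour_b: 2
  epsilon_kT: 0.9
  sigma_nm: 0.4
  attractive: yes
  cutoff_nm: 1.2
  r_lin_nm: 0.35
templates:
- name: patchy
  gestalts:
  - geom:
      D_tr_nm2_ps: 0.00012
      D_rot_per_ps: 2.26e-05
      mass_kDa: 18.0
    origin_nm:
    - 0.0
    - 0.0
    - 0.0
    vdw:
    - offset_nm:
      - 0.0
      - 0.0
      - 0.5
      radius_nm: 1.7
      colour: 2
    - offset_nm:
      - 0.0
      - 0.0
      - -0.5
      radius_nm: 1.7
      colour: 1
    charges: []
    hydro: ~
  bonds: []
species:
- template: patchy
  count: 27.0
walls: []
interfaces: []
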