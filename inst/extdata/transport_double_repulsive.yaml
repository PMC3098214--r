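schema: brownsim/1
box:
  L_nm:
  - 30.0
  - 20.0
  - 20.0
  modes:
  - open
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
  record: none
  tensor_stride: 1
  propagation: auto
colour_pairs:
- colour_a: 1
  colour_b: 1
  epsilon_kT: 1.0
  sigma_nm: 0.8
  attractive: no
  cutoff_nm: 2.4
  r_lin_nm: 0.6
- colour_a: 1
  colour_b: 3
  epsilon_kT: 1.0
  sigma_nm: 0.8
  attractive: no
  cutoff_nm: 2.4
  r_lin_nm: 0.6
templates:
- name: bead
  gestalts:
  - geom:
      D_tr_nm2_ps: 0.0001
      D_rot_per_ps: 0.0
      mass_kDa: ~
    origin_nm:
    - 0.0
    - 0.0
    - 0.0
    vdw:
    - offset_nm:
      - 0.0
      - 0.0
      - 0.0
      radius_nm: 2.0
      colour: 1
    charges: []
    hydro: ~
  bonds: []
species: []
walls:
- spheres:
  - x_nm: 5.0
    y_nm: 3.333333333333333
    z_nm: 3.333333333333333
    radius_nm: 5.0
    colour: 3
  - x_nm: 25.0
    y_nm: 3.333333333333333
    z_nm: 3.333333333333333
    radius_nm: 5.0
    colour: 3
  - x_nm: 5.0
    y_nm: 10.0
    z_nm: 3.333333333333333
    radius_nm: 5.0
    colour: 3
  - x_nm: 25.0
    y_nm: 10.0
    z_nm: 3.333333333333333
    radius_nm: 5.0
    colour: 3
  - x_nm: 5.0
    y_nm: 16.666666666666668
    z_nm: 3.333333333333333
    radius_nm: 5.0
    colour: 3
  - x_nm: 25.0
    y_nm: 16.666666666666668
    z_nm: 3.333333333333333
    radius_nm: 5.0
    colour: 3
  - x_nm: 5.0
    y_nm: 3.333333333333333
    z_nm: 10.0
    radius_nm: 5.0
    colour: 3
  - x_nm: 25.0
    y_nm: 3.333333333333333
    z_nm: 10.0
    radius_nm: 5.0
    colour: 3
  - x_nm: 5.0
    y_nm: 10.0
    z_nm: 10.0
    radius_nm: 5.0
    colour: 3
  - x_nm: 25.0
    y_nm: 10.0
    z_nm: 10.0
    radius_nm: 5.0
    colour: 3
  - x_nm: 5.0
    y_nm: 16.666666666666668
    z_nm: 10.0
    radius_nm: 5.0
    colour: 3
  - x_nm: 25.0
    y_nm: 16.666666666666668
    z_nm: 10.0
    radius_nm: 5.0
    colour: 3
  - x_nm: 5.0
    y_nm: 3.333333333333333
    z_nm: 16.666666666666668
    radius_nm: 5.0
    colour: 3
  - x_nm: 25.0
    y_nm: 3.333333333333333
    z_nm: 16.666666666666668
    radius_nm: 5.0
    colour: 3
  - x_nm: 5.0
    y_nm: 10.0
    z_nm: 16.666666666666668
    radius_nm: 5.0
    colour: 3
  - x_nm: 25.0
    y_nm: 10.0
    z_nm: 16.666666666666668
    radius_nm: 5.0
    colour: 3
  - x_nm: 5.0
    y_nm: 16.666666666666668
    z_nm: 16.666666666666668
    radius_nm: 5.0
    colour: 3
  - x_nm: 25.0
    y_nm: 16.666666666666668
    z_nm: 16.666666666666668
    radius_nm: 5.0
    colour: 3
interfaces:
- axis: x
  side: low
  species: bead
  rho_per_nm3: 0.0004
- axis: x
  side: high
  species: bead
  rho_per_nm3: 0.0
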