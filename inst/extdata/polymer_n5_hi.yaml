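schema: brownsim/1
box:
  L_nm:
  - 0.0
  - 0.0
  - 0.0
  modes:
  - none
  - none
  - none
config:
  timestep_ps: 0.000199980002
  steps: 100000.0
  stride: 100
  kT: 0.0024361
  hi: yes
  kappa_per_nm: 0.0
  eps_r: 80.0
  seed: 1
  record: com_ee
  tensor_stride: 1
  propagation: auto
colour_pairs:
- colour_a: 1
  colour_b: 1
  epsilon_kT: 1.0
  sigma_nm: 0.4
  attractive: no
  cutoff_nm: 1.2
  r_lin_nm: 0.3
templates:
- name: polymer5
  gestalts:
  - geom:
      D_tr_nm2_ps: 1.0
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
      radius_nm: 1.0
      colour: 1
    charges: []
    hydro:
      a_nm: 1.0
      D_self_nm2_ps: 1.0
  - geom:
      D_tr_nm2_ps: 1.0
      D_rot_per_ps: 0.0
      mass_kDa: ~
    origin_nm:
    - 2.5
    - 0.0
    - 0.0
    vdw:
    - offset_nm:
      - 0.0
      - 0.0
      - 0.0
      radius_nm: 1.0
      colour: 1
    charges: []
    hydro:
      a_nm: 1.0
      D_self_nm2_ps: 1.0
  - geom:
      D_tr_nm2_ps: 1.0
      D_rot_per_ps: 0.0
      mass_kDa: ~
    origin_nm:
    - 5.0
    - 0.0
    - 0.0
    vdw:
    - offset_nm:
      - 0.0
      - 0.0
      - 0.0
      radius_nm: 1.0
      colour: 1
    charges: []
    hydro:
      a_nm: 1.0
      D_self_nm2_ps: 1.0
  - geom:
      D_tr_nm2_ps: 1.0
      D_rot_per_ps: 0.0
      mass_kDa: ~
    origin_nm:
    - 7.5
    - 0.0
    - 0.0
    vdw:
    - offset_nm:
      - 0.0
      - 0.0
      - 0.0
      radius_nm: 1.0
      colour: 1
    charges: []
    hydro:
      a_nm: 1.0
      D_self_nm2_ps: 1.0
  - geom:
      D_tr_nm2_ps: 1.0
      D_rot_per_ps: 0.0
      mass_kDa: ~
    origin_nm:
    - 10.0
    - 0.0
    - 0.0
    vdw:
    - offset_nm:
      - 0.0
      - 0.0
      - 0.0
      radius_nm: 1.0
      colour: 1
    charges: []
    hydro:
      a_nm: 1.0
      D_self_nm2_ps: 1.0
  bonds:
  - a: 1
    b: 2
    k2_kT_nm2: 1000.0
    k4_kT_nm4: 0.0
    L0_nm: 2.5
    hook_a_nm:
    - 0.0
    - 0.0
    - 0.0
    hook_b_nm:
    - 0.0
    - 0.0
    - 0.0
  - a: 2
    b: 3
    k2_kT_nm2: 1000.0
    k4_kT_nm4: 0.0
    L0_nm: 2.5
    hook_a_nm:
    - 0.0
    - 0.0
    - 0.0
    hook_b_nm:
    - 0.0
    - 0.0
    - 0.0
  - a: 3
    b: 4
    k2_kT_nm2: 1000.0
    k4_kT_nm4: 0.0
    L0_nm: 2.5
    hook_a_nm:
    - 0.0
    - 0.0
    - 0.0
    hook_b_nm:
    - 0.0
    - 0.0
    - 0.0
  - a: 4
    b: 5
    k2_kT_nm2: 1000.0
    k4_kT_nm4: 0.0
    L0_nm: 2.5
    hook_a_nm:
    - 0.0
    - 0.0
    - 0.0
    hook_b_nm:
    - 0.0
    - 0.0
    - 0.0
  - a: 1
    b: 3
    k2_kT_nm2: 0.1
    k4_kT_nm4: 0.0
    L0_nm: 5.0
    hook_a_nm:
    - 0.0
    - 0.0
    - 0.0
    hook_b_nm:
    - 0.0
    - 0.0
    - 0.0
  - a: 2
    b: 4
    k2_kT_nm2: 0.1
    k4_kT_nm4: 0.0
    L0_nm: 5.0
    hook_a_nm:
    - 0.0
    - 0.0
    - 0.0
    hook_b_nm:
    - 0.0
    - 0.0
    - 0.0
  - a: 3
    b: 5
    k2_kT_nm2: 0.1
    k4_kT_nm4: 0.0
    L0_nm: 5.0
    hook_a_nm:
    - 0.0
    - 0.0
    - 0.0
    hook_b_nm:
    - 0.0
    - 0.0
    - 0.0
species: []
walls: []
interfaces: []
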