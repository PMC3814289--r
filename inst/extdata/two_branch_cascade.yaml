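name: two_branch_cascade
system_size: 50.0
species:
- id: R
  name: R
  initial: 2.0
- id: A
  name: A
  initial: 4.0
- id: A_star
  name: A_star
  initial: 1.0
- id: B
  name: B
  initial: 4.0
- id: B_star
  name: B_star
  initial: 1.0
- id: D
  name: D
  initial: 4.0
- id: D_star
  name: D_star
  initial: 1.0
- id: OUT_star
  name: OUT_star
  initial: 1.0
parameters:
  s: 2.0
  dr: 1.0
  ka: 0.5
  kb: 0.5
  ia: 1.0
  ib: 1.0
  kd: 0.2
  id_: 1.0
  ko: 0.2
  io: 1.0
reactions:
- id: r_on
  products:
    R: 1.0
  rate:
    mass_action: s
- id: r_off
  reactants:
    R: 1.0
  rate:
    mass_action: dr
- id: a_act
  reactants:
    A: 1.0
    R: 1.0
  products:
    A_star: 1.0
    R: 1.0
  rate:
    mass_action: ka
- id: a_deact
  reactants:
    A_star: 1.0
  products:
    A: 1.0
  rate:
    mass_action: ia
- id: b_act
  reactants:
    B: 1.0
    R: 1.0
  products:
    B_star: 1.0
    R: 1.0
  rate:
    mass_action: kb
- id: b_deact
  reactants:
    B_star: 1.0
  products:
    B: 1.0
  rate:
    mass_action: ib
- id: d_act_a
  reactants:
    A_star: 1.0
    D: 1.0
  products:
    A_star: 1.0
    D_star: 1.0
  rate:
    mass_action: kd
- id: d_act_b
  reactants:
    B_star: 1.0
    D: 1.0
  products:
    B_star: 1.0
    D_star: 1.0
  rate:
    mass_action: kd
- id: d_deact
  reactants:
    D_star: 1.0
  products:
    D: 1.0
  rate:
    mass_action: id_
- id: out_act
  reactants:
    D_star: 1.0
  products:
    D_star: 1.0
    OUT_star: 1.0
  rate:
    mass_action: ko
- id: out_deact
  reactants:
    OUT_star: 1.0
  rate:
    mass_action: io

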