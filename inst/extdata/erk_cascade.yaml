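name: erk_cascade
system_size: 6.02214076
species:
- id: MKKK
  name: MKKK
  initial: 90.0
- id: MKKK_P
  name: MKKK_P
  initial: 10.0
- id: MKK
  name: MKK
  initial: 280.0
- id: MKK_P
  name: MKK_P
  initial: 10.0
- id: MKK_PP
  name: MKK_PP
  initial: 10.0
- id: MAPK
  name: MAPK
  initial: 280.0
- id: MAPK_P
  name: MAPK_P
  initial: 10.0
- id: MAPK_PP
  name: MAPK_PP
  initial: 10.0
parameters:
  V1: 2.5
  Ki: 45.0
  'n': 1.0
  K1: 10.0
  V2: 0.25
  K2: 8.0
  k3: 0.025
  K3: 15.0
  k4: 0.025
  K4: 15.0
  V5: 0.75
  K5: 15.0
  V6: 0.75
  K6: 15.0
  k7: 0.025
  K7: 15.0
  k8: 0.025
  K8: 15.0
  V9: 0.5
  K9: 15.0
  V10: 0.5
  K10: 15.0
reactions:
- id: mkkk_act
  reactants:
    MKKK: 1.0
  products:
    MKKK_P: 1.0
  rate: V1 * MKKK/((1 + (MAPK_PP/Ki)^n) * (K1 + MKKK))
- id: mkkk_deact
  reactants:
    MKKK_P: 1.0
  products:
    MKKK: 1.0
  rate: V2 * MKKK_P/(K2 + MKKK_P)
- id: mkk_p1
  reactants:
    MKK: 1.0
  products:
    MKK_P: 1.0
  rate: k3 * MKKK_P * MKK/(K3 + MKK)
- id: mkk_p2
  reactants:
    MKK_P: 1.0
  products:
    MKK_PP: 1.0
  rate: k4 * MKKK_P * MKK_P/(K4 + MKK_P)
- id: mkk_dp1
  reactants:
    MKK_PP: 1.0
  products:
    MKK_P: 1.0
  rate: V5 * MKK_PP/(K5 + MKK_PP)
- id: mkk_dp2
  reactants:
    MKK_P: 1.0
  products:
    MKK: 1.0
  rate: V6 * MKK_P/(K6 + MKK_P)
- id: mapk_p1
  reactants:
    MAPK: 1.0
  products:
    MAPK_P: 1.0
  rate: k7 * MKK_PP * MAPK/(K7 + MAPK)
- id: mapk_p2
  reactants:
    MAPK_P: 1.0
  products:
    MAPK_PP: 1.0
  rate: k8 * MKK_PP * MAPK_P/(K8 + MAPK_P)
- id: mapk_dp1
  reactants:
    MAPK_PP: 1.0
  products:
    MAPK_P: 1.0
  rate: V9 * MAPK_PP/(K9 + MAPK_PP)
- id: mapk_dp2
  reactants:
    MAPK_P: 1.0
  products:
    MAPK: 1.0
  rate: V10 * MAPK_P/(K10 + MAPK_P)

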