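name: michaelis_menten
system_size: 100.0
species:
- id: S
  name: substrate
  initial: 0.222222222222222
- id: SE
  name: enzyme-substrate complex
  initial: 1.0
- id: P
  name: product
  initial: 1.0
- id: E
  name: free enzyme
  initial: 9.0
parameters:
  k1: 1.0
  k2: 1.0
  k3: 1.0
  k4: 1.0
  k5: 1.0
reactions:
- id: influx
  products:
    S: 1.0
  rate:
    mass_action: k1
- id: binding
  reactants:
    E: 1.0
    S: 1.0
  products:
    SE: 1.0
  rate:
    mass_action: k2
- id: dissociation
  reactants:
    SE: 1.0
  products:
    E: 1.0
    S: 1.0
  rate:
    mass_action: k3
- id: catalysis
  reactants:
    SE: 1.0
  products:
    E: 1.0
    P: 1.0
  rate:
    mass_action: k4
- id: efflux
  reactants:
    P: 1.0
  rate:
    mass_action: k5

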