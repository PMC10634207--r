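# IV disposition model for benzylpenicillin in horses: 3-compartment
# mammillary model, "source of dataset" as a categorical covariate on
# plasma clearance, full log-scale covariance of the random effects.
# Units: volumes mL/kg, clearances mL/kg/h, concentrations mg/L.
units:
  volume: mL/kg
  clearance: mL/kg/h
  concentration: mg/L
theta:
  Vc: 106
  V2: 46.3
  V3: 50.4
  CL: 481
  CL2: 126
  CL3: 25.0
covariates:
  CL:
    France: 0.0
    Sweden: -0.68325471
    USA1: -0.12576635
    USA2: -0.13609778
omega:
  # full variance/covariance of the log-scale random effects
  order: [Vc, CL, V2, V3, CL2, CL3]
  matrix:
    - [0.4450]
    - [0.3552, 0.2944]
    - [0.4165, 0.3803, 0.6459]
    - [0.4298, 0.3614, 0.5405, 0.5219]
    - [0.4600, 0.4480, 0.8423, 0.6532, 1.1466]
    - [0.3975, 0.3508, 0.5711, 0.5091, 0.7254, 0.5207]
residual:
  sigma_add: 0.000713844   # mg/L
  sigma_prop: 0.152817042
fu: 0.4
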