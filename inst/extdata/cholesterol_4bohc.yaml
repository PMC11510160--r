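# Final cholesterol / 4beta-OHC model configuration.
# Units: MW g/mol, Vss L/kg, CLint uL/min/pmol (per_pmol) or uL/min/mg
# (per_mg), abundances pmol/mg microsomal protein, doses mg/kg/day
# (iv_infusion) or mg (oral), perpetrator PK: ka 1/h, v L, cl L/h.
compounds:
  - name: cholesterol
    molecular_weight: 386.65
    logP: 7.02
    blood_to_plasma: 0.55
    fu_plasma: 0.0021
    vss: 0.10
    kp_liver: 3.07
    binding_protein: "Apolipoprotein B"
    pathways:
      - enzyme: CYP3A4
        clint: 4.17e-7
      - enzyme: CYP3A5
        clint: 2.55e-8
      - enzyme: CYP3A7
        clint: 1.27e-8
      - enzyme: CYP27A1
        clint: 3.13e-3
      - enzyme: HLM
        clint: 0.350
        basis: per_mg
  - name: 4b-hydroxycholesterol
    molecular_weight: 402.35
    logP: 6.16
    blood_to_plasma: 0.55
    fu_plasma: 0.0051
    vss: 0.05
    kp_liver: 3.87
    binding_protein: "Apolipoprotein B"
    pathways:
      - enzyme: CYP27A1
        clint: 0.02
      - enzyme: HLM
        clint: 0.84
        basis: per_mg
physiology:
  body_weight: 67.5
  liver_weight: 1737.11
  mppgl: 39.79
  hepatic_blood_flow: 90
  hematocrit: 0.45
  sex: male
  age: 35
  abundances:
    CYP3A4: 137
    CYP3A5: 102
    CYP3A7: 2
    CYP27A1: 41.93
regimens:
  - compound: cholesterol
    route: iv_infusion
    dose: 1.73
    start_day: 0
    duration_days: 700
perpetrators:
  - compound:
      name: rifampicin-like
      molecular_weight: 822.9
      blood_to_plasma: 0.9
      fu_plasma: 0.2
      vss: 0.65
      kp_liver: 1
    interaction:
      mechanism: induction
      ind_max: 16
      ind_c50: 0.32
      target_enzymes: [CYP3A4, CYP3A5, CYP3A7]
    pk:
      ka: 1.0
      v: 46
      cl: 7
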