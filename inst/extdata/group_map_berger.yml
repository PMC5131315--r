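CA:
  CA: CA
CAL:
  CA: CA
CL:
  CL: CL
CLA:
  CL: CL
POPC:
  P: PHOS_P
  P8: PHOS_P
  'N': CHOL_N
  N4: CHOL_N
  O16: CARBONYL_O_SN1
  OA: CARBONYL_O_SN1
  O33: CARBONYL_O_SN2
  OB: CARBONYL_O_SN2
POPS:
  P: PHOS_P
  P8: PHOS_P
  'N': CHOL_N
  N4: CHOL_N
  O16: CARBONYL_O_SN1
  OA: CARBONYL_O_SN1
  O33: CARBONYL_O_SN2
  OB: CARBONYL_O_SN2
  OC1: COO_PS
  OC2: COO_PS
SOL:
  OW: WATER_O
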