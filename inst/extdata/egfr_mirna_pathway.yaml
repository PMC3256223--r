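genes:
  EGFR: []
  PIK3CA: []
  PIK3R1: []
  PDPK1: []
  AKT:
    members:
    - AKT1
    - AKT2
    - AKT3
  BAD: []
  MEK:
    members:
    - MAP2K1
    - MAP2K2
  ERK:
    members:
    - MAPK1
    - MAPK3
  ELK1: []
  MYC: []
  TP53: []
  PTEN: []
  MDM2: []
  CDKN1:
    members:
    - CDKN1A
    - CDKN1B
  MTOR: []
  RPS6KA5: []
  CAMK:
    members:
    - CAMK2A
    - CAMK2B
  PKC:
    members:
    - PRKCA
    - PRKCB
  TARBP2: []
  RNASEN: []
  DICER1: []
  DGCR8: []
mirnas:
  mir-192: []
  mir-181c: []
  mir-489: []
  mir-34a: []
  mir-TRDD:
    members:
    - mir-631
    - mir-608
    - mir-604
    - mir-492
    - mir-30a
entities:
  EGF:
    role: protein
    compartment: extracellular
  ATP:
    role: compound
    compartment: cytoplasm
  ADP:
    role: compound
    compartment: cytoplasm
  PIP2:
    role: compound
    compartment: plasma_membrane
  PIP3:
    role: compound
    compartment: plasma_membrane
  EGF:EGFR:
    role: complex
    compartment: plasma_membrane
    tags: ligand_receptor
  Active-PIK3CA:
    role: protein
    compartment: plasma_membrane
  Active-PDPK1:
    role: protein
    compartment: plasma_membrane
  Active-MEK:
    role: protein
    compartment: cytoplasm
    members:
    - MAP2K1
    - MAP2K2
  P-AKT-1:
    role: protein
    compartment: cytoplasm
  P-BAD-1:
    role: protein
    compartment: cytoplasm
  P-TP53-1:
    role: protein
    compartment: cytoplasm
  P-MDM2-1:
    role: protein
    compartment: cytoplasm
  P-CDKN1-1:
    role: protein
    compartment: cytoplasm
  P-ERK-1:
    role: protein
    compartment: cytoplasm
  P-ELK1-1:
    role: protein
    compartment: cytoplasm
  P-MYC-1:
    role: protein
    compartment: cytoplasm
reactions:
- rtype: complex_formation
  substrates:
  - EGF
  - EGFR-1
  products: EGF:EGFR
- rtype: activation
  substrates:
  - PIK3CA-1
  - PIK3R1-1
  products: Active-PIK3CA
  enzyme: EGF:EGFR
- rtype: other
  substrates: PIP2
  products: PIP3
  enzyme: Active-PIK3CA
- rtype: dephosphorylation
  substrates: PIP3
  products: PIP2
  enzyme: PTEN-1
  k: 0.15
- rtype: activation
  substrates: PDPK1-1
  products: Active-PDPK1
  enzyme: PIP3
- rtype: phosphorylation
  substrates:
  - AKT-1
  - ATP
  products:
  - P-AKT-1
  - ADP
  enzyme: Active-PDPK1
- rtype: phosphorylation
  substrates:
  - BAD-1
  - ATP
  products:
  - P-BAD-1
  - ADP
  enzyme: P-AKT-1
- rtype: dephosphorylation
  substrates: P-BAD-1
  products: BAD-1
- rtype: phosphorylation
  substrates:
  - TP53-1
  - ATP
  products:
  - P-TP53-1
  - ADP
  enzyme: P-AKT-1
- rtype: phosphorylation
  substrates:
  - MDM2-1
  - ATP
  products:
  - P-MDM2-1
  - ADP
  enzyme: P-AKT-1
- rtype: phosphorylation
  substrates:
  - CDKN1-1
  - ATP
  products:
  - P-CDKN1-1
  - ADP
  enzyme: P-AKT-1
- rtype: activation
  substrates: MEK-1
  products: Active-MEK
  enzyme: EGF:EGFR
- rtype: phosphorylation
  substrates:
  - ERK-1
  - ATP
  products:
  - P-ERK-1
  - ADP
  enzyme: Active-MEK
- rtype: phosphorylation
  substrates:
  - ELK1-1
  - ATP
  products:
  - P-ELK1-1
  - ADP
  enzyme: P-ERK-1
- rtype: phosphorylation
  substrates:
  - MYC-1
  - ATP
  products:
  - P-MYC-1
  - ADP
  enzyme: P-ERK-1
clamps:
  EGF: 1.0
  ATP: 1.0
  ADP: 1.0
  PIP2: 1.0
gene_level: 0.1
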