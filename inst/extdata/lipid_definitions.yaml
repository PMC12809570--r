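# Lipid-definition table: residue name -> atom-name roles.
# Atom naming follows CHARMM36 lipid conventions: sn-1 chain carbons C31..C3n
# (hydrogens HnX/HnY), sn-2 chain carbons C21..C2n (hydrogens HnR/HnS),
# cardiolipin chains CA/CB (saturated) and CC/CD (oleoyl) with HnA-style
# hydrogens (one suffix pair per chain, keeping names within the 4-character
# PDB atom-name field).  Unsaturation positions are the glycerol-proximal carbon of the
# C=C bond; all species here are Delta-9.  Tails are listed sn-1 first, so a
# Table-style descriptor "16:0/16:1" reads top to bottom.
# Copy and edit this file to add species; pass the copy to
# read_lipid_definitions().
PYPE:
  headgroup: PE
  phosphate_atoms: [P, O11, O12, O13, O14]
  tails:
  - descriptor: "16:0"
    carbon_prefix: C3
    hydrogen_prefix: H
    hydrogen_suffixes: ["X", "Y"]
    unsaturations: []
  - descriptor: "16:1"
    carbon_prefix: C2
    hydrogen_prefix: H
    hydrogen_suffixes: ["R", "S"]
    unsaturations: [9]
POPE:
  headgroup: PE
  phosphate_atoms: [P, O11, O12, O13, O14]
  tails:
  - descriptor: "16:0"
    carbon_prefix: C3
    hydrogen_prefix: H
    hydrogen_suffixes: ["X", "Y"]
    unsaturations: []
  - descriptor: "18:1"
    carbon_prefix: C2
    hydrogen_prefix: H
    hydrogen_suffixes: ["R", "S"]
    unsaturations: [9]
YOPE:
  headgroup: PE
  phosphate_atoms: [P, O11, O12, O13, O14]
  tails:
  - descriptor: "16:1"
    carbon_prefix: C3
    hydrogen_prefix: H
    hydrogen_suffixes: ["X", "Y"]
    unsaturations: [9]
  - descriptor: "18:1"
    carbon_prefix: C2
    hydrogen_prefix: H
    hydrogen_suffixes: ["R", "S"]
    unsaturations: [9]
PYPG:
  headgroup: PG
  phosphate_atoms: [P, O11, O12, O13, O14]
  tails:
  - descriptor: "16:0"
    carbon_prefix: C3
    hydrogen_prefix: H
    hydrogen_suffixes: ["X", "Y"]
    unsaturations: []
  - descriptor: "16:1"
    carbon_prefix: C2
    hydrogen_prefix: H
    hydrogen_suffixes: ["R", "S"]
    unsaturations: [9]
POPG:
  headgroup: PG
  phosphate_atoms: [P, O11, O12, O13, O14]
  tails:
  - descriptor: "16:0"
    carbon_prefix: C3
    hydrogen_prefix: H
    hydrogen_suffixes: ["X", "Y"]
    unsaturations: []
  - descriptor: "18:1"
    carbon_prefix: C2
    hydrogen_prefix: H
    hydrogen_suffixes: ["R", "S"]
    unsaturations: [9]
PVCL2:
  headgroup: CL
  phosphate_atoms: [P1, O11, O12, O13, O14, P3, O31, O32, O33, O34]
  tails:
  - descriptor: "16:0"
    carbon_prefix: CA
    hydrogen_prefix: H
    hydrogen_suffixes: ["A", "B"]
    unsaturations: []
  - descriptor: "16:0"
    carbon_prefix: CB
    hydrogen_prefix: H
    hydrogen_suffixes: ["C", "D"]
    unsaturations: []
  - descriptor: "18:1"
    carbon_prefix: CC
    hydrogen_prefix: H
    hydrogen_suffixes: ["E", "F"]
    unsaturations: [9]
  - descriptor: "18:1"
    carbon_prefix: CD
    hydrogen_prefix: H
    hydrogen_suffixes: ["G", "I"]
    unsaturations: [9]
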