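# Atomic and bond parameter tables for descriptor computation.
# sanderson_en: Sanderson electronegativities (raw scale; descriptors use the
#   carbon-normalized values, so only ratios matter).
# bond_dipole: bond dipole moments (Debye) keyed "El1-El2:order" with elements
#   sorted alphabetically; order is 1/2/3 or "ar" for aromatic. Values are a
#   reconstruction from published bond dipole tables; carbon-carbon bonds of
#   every order are apolar (weight 0). Users may copy, edit, and pass their
#   own file to ro_element_tables().
sanderson_en:
  "H": 2.592
  "C": 2.746
  "N": 3.194
  "O": 3.654
  "F": 4.000
  "P": 2.515
  "S": 2.957
  "Cl": 3.475
  "Br": 3.219
  "I": 2.778
bond_dipole:
  "C-C:1": 0.0
  "C-C:2": 0.0
  "C-C:3": 0.0
  "C-C:ar": 0.0
  "C-Cl:1": 1.47
  "Br-C:1": 1.42
  "C-I:1": 1.25
  "C-F:1": 1.41
  "C-O:1": 0.74
  "C-O:2": 2.33
  "C-O:ar": 0.74
  "C-N:1": 0.22
  "C-N:2": 0.90
  "C-N:3": 3.50
  "C-N:ar": 0.22
  "C-S:1": 0.90
  "C-S:ar": 0.90
  "N-O:1": 0.30
  "N-O:2": 2.00
  "O-S:2": 2.80
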