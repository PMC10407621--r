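# Operating constants of the reverse-osmosis filtration campaign behind the
# packaged rejection data (stored as metadata only; not used in any model).
membrane: Hydranautics ESPA2-LD
mass_transfer_coefficient_L_m2_h_bar: 4.50
concentration_polarization_beta: 1.2
net_transmembrane_pressure_bar: 10
response: percent rejection (0-100)
censored_note: >
  Experimental rejections printed as ">96" are stored as 96 with the
  censored flag set (compound ids 47 and 63).
smiles_note: >
  SMILES were authored from the compound names and reviewed against the
  structure drawings; they are not machine-exported from the original study.
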