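# Published bulk composition numbers for the JCVI-syn3A minimal cell,
# used as build defaults. Associated structures are synthetic stand-ins.
cell_diameter_nm: 400
genome_bp: 543000
n_protein_species: 452
localization_counts:
  cytosolic: 281
  transmembrane: 63
  peripheral: 42
  unknown: 66
n_ribosomes: 503
salt_molarity: 0.135
lipid_fractions:
  CHOL: 0.59
  SM: 0.18
  CDL: 0.17
  PC: 0.04
  PG: 0.02
membrane_zone_depth_nm: 30
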