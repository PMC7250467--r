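# Default parameter set for pepshift.
#
# random_coil: literature random-coil chemical shifts (ppm) per residue and
#   nucleus.  GLY has no CB and PRO no amide proton; their placeholder
#   entries are never used because the corresponding atoms do not exist.
# weights: per-nucleus multipliers of each descriptor family (dimensionless
#   defaults of 1; refit against observed shifts for quantitative use).
# fourier: phi/psi dihedral-term coefficients, layout [a1,a2,a3,b1,b2,b3]
#   per angle (default 0: the dihedral term is off until fitted).
# delta_chi: axially symmetric anisotropy constants (ppm A^3) per group kind.
# ring_scale / ring_intensity: Haigh-Mallion global scale B (ppm A^3) and
#   per-ring intensity factors I.
# cutoffs: geometric cutoffs in Angstroms / degrees.
format_version: 1
cutoffs:
  contact_radius: 8.0
  contact_min_seq_sep: 2
  hbond_max_da_dist: 3.5
  hbond_min_nho_angle: 120.0
  ani_max_dist: 12.0
  ring_max_dist: 8.0
ring_scale: 5.455
ring_intensity:
  PHE: 1.00
  TYR: 0.84
  HIS: 0.90
  TRP5: 1.04
  TRP6: 1.02
delta_chi:
  backbone: -12.9
  OCN: -11.5
  OCO: -10.0
  NCN: -8.0
ridge: 0.0
weights:
  "CA": {contact: 1.0, hbond: 1.0, ani: 1.0, ring: 1.0, dihedral: 1.0}
  CB: {contact: 1.0, hbond: 1.0, ani: 1.0, ring: 1.0, dihedral: 1.0}
  C:  {contact: 1.0, hbond: 1.0, ani: 1.0, ring: 1.0, dihedral: 1.0}
  HN: {contact: 1.0, hbond: 1.0, ani: 1.0, ring: 1.0, dihedral: 1.0}
  "N": {contact: 1.0, hbond: 1.0, ani: 1.0, ring: 1.0, dihedral: 1.0}
  HA: {contact: 1.0, hbond: 1.0, ani: 1.0, ring: 1.0, dihedral: 1.0}
fourier:
  CA: {phi: [0.0, 0.0, 0.0, 0.0, 0.0, 0.0], psi: [0.0, 0.0, 0.0, 0.0, 0.0, 0.0]}
  CB: {phi: [0.0, 0.0, 0.0, 0.0, 0.0, 0.0], psi: [0.0, 0.0, 0.0, 0.0, 0.0, 0.0]}
  C:  {phi: [0.0, 0.0, 0.0, 0.0, 0.0, 0.0], psi: [0.0, 0.0, 0.0, 0.0, 0.0, 0.0]}
  HN: {phi: [0.0, 0.0, 0.0, 0.0, 0.0, 0.0], psi: [0.0, 0.0, 0.0, 0.0, 0.0, 0.0]}
  "N": {phi: [0.0, 0.0, 0.0, 0.0, 0.0, 0.0], psi: [0.0, 0.0, 0.0, 0.0, 0.0, 0.0]}
  HA: {phi: [0.0, 0.0, 0.0, 0.0, 0.0, 0.0], psi: [0.0, 0.0, 0.0, 0.0, 0.0, 0.0]}
random_coil:
  ALA: {CA: 52.5, CB: 19.1, C: 177.8, HN: 8.24, "N": 123.8, HA: 4.32}
  ARG: {CA: 56.0, CB: 30.9, C: 176.3, HN: 8.23, "N": 120.5, HA: 4.34}
  ASN: {CA: 53.1, CB: 38.9, C: 175.2, HN: 8.40, "N": 118.7, HA: 4.74}
  ASP: {CA: 54.2, CB: 41.1, C: 176.3, HN: 8.34, "N": 120.4, HA: 4.64}
  CYS: {CA: 58.2, CB: 28.0, C: 174.6, HN: 8.32, "N": 118.8, HA: 4.55}
  GLN: {CA: 55.7, CB: 29.4, C: 176.0, HN: 8.32, "N": 119.8, HA: 4.34}
  GLU: {CA: 56.6, CB: 29.9, C: 176.6, HN: 8.42, "N": 120.2, HA: 4.35}
  GLY: {CA: 45.1, CB: 0.0,  C: 174.9, HN: 8.33, "N": 108.8, HA: 3.96}
  HIS: {CA: 55.0, CB: 29.0, C: 174.1, HN: 8.42, "N": 118.2, HA: 4.73}
  ILE: {CA: 61.1, CB: 38.8, C: 176.4, HN: 8.00, "N": 119.9, HA: 4.17}
  LEU: {CA: 55.1, CB: 42.4, C: 177.6, HN: 8.16, "N": 121.8, HA: 4.34}
  LYS: {CA: 56.2, CB: 33.1, C: 176.6, HN: 8.29, "N": 120.4, HA: 4.32}
  MET: {CA: 55.4, CB: 32.9, C: 176.3, HN: 8.28, "N": 119.6, HA: 4.48}
  PHE: {CA: 57.7, CB: 39.6, C: 175.8, HN: 8.30, "N": 120.3, HA: 4.62}
  PRO: {CA: 63.3, CB: 32.1, C: 177.3, HN: 0.0, "N": 128.1, HA: 4.42}
  SER: {CA: 58.3, CB: 63.8, C: 174.6, HN: 8.31, "N": 115.7, HA: 4.47}
  THR: {CA: 61.8, CB: 69.8, C: 174.7, HN: 8.15, "N": 113.6, HA: 4.35}
  TRP: {CA: 57.5, CB: 29.6, C: 176.1, HN: 8.25, "N": 121.3, HA: 4.66}
  TYR: {CA: 57.9, CB: 38.8, C: 175.9, HN: 8.12, "N": 120.3, HA: 4.55}
  VAL: {CA: 62.2, CB: 32.9, C: 176.3, HN: 8.03, "N": 119.2, HA: 4.12}
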