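# Minimal molecular-mechanics parameter set used by helixcm.
#
# charges:  partial charges (elementary charge units) keyed "RES:ATOM";
#           "*" wildcards the residue name, "*:*" is the final fallback.
# lj:       Lennard-Jones classes keyed by element: [epsilon kcal/mol, r_min A]
#           (r_min is the pair distance at the minimum for a like pair;
#           unlike pairs combine by arithmetic mean of r_min and geometric
#           mean of epsilon).
# torsions: cosine series per torsion class: [amplitude kcal/mol,
#           periodicity, phase deg]; E = sum A*(1 + cos(n*theta - delta)).
# dielectric: model "distance" (eps(r) = coefficient * r) or "constant"
#           (eps = coefficient).
charges:
  "*:N": -0.35
  "*:CA": 0.10
  "*:C": 0.51
  "*:O": -0.51
  "*:CB": 0.00
  "*:OG": -0.40
  "*:OG1": -0.40
  "*:OH": -0.40
  "*:SG": -0.20
  "*:SD": -0.10
  "*:OD1": -0.50
  "*:OD2": -0.50
  "*:OE1": -0.50
  "*:OE2": -0.50
  "*:ND1": -0.36
  "*:ND2": -0.47
  "*:NE2": -0.47
  "*:NE1": -0.35
  "*:NE": -0.40
  "*:NH1": 0.35
  "*:NH2": 0.35
  "*:NZ": 0.45
  "*:CZ": 0.20
  "ASP:CG": 0.45
  "GLU:CD": 0.45
  "ASN:CG": 0.42
  "GLN:CD": 0.42
  "*:*": 0.00
lj:
  "C": [0.090, 3.90]
  "N": [0.170, 3.45]
  "O": [0.160, 3.30]
  "S": [0.350, 3.95]
  "H": [0.022, 2.60]
torsions:
  phi:
    - [0.20, 3, 0.0]
  psi:
    - [0.20, 3, 0.0]
  omega:
    - [1.50, 2, 180.0]
  chi1:
    - [0.60, 3, 0.0]
dielectric:
  model: distance
  coefficient: 1.0
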