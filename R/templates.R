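# Ideal covalent geometry used for all internal->Cartesian rebuilds.  The
# sampler varies only dihedrals and the N-CA-C bond angle, so bond lengths and
# the remaining bond angles are fixed at standard values.

IDEAL_GEOM <- list(
  b_n_ca  = 1.458,   # N-CA bond, Angstrom
  b_ca_c  = 1.525,   # CA-C
  b_c_n   = 1.329,   # C-N (peptide)
  b_c_o   = 1.231,   # C=O
  a_n_ca_c  = 111.0, # backbone tau (the sampled bond-angle class)
  a_ca_c_n  = 116.2,
  a_c_n_ca  = 121.7,
  a_ca_c_o  = 120.5,
  d_cb      = 122.3, # dihedral C-N-CA-CB fixing the L configuration
  b_ca_cb   = 1.530,
  a_n_ca_cb = 110.5
)

AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
         "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL")
AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Convert one-letter to three-letter residue codes
#' @param seq character vector of one-letter codes, or a single string.
#' @return character vector of three-letter codes.
#' @export
aa_three <- function(seq) {
  if (length(seq) == 1 && nchar(seq) > 1) seq <- strsplit(seq, "")[[1]]
  idx <- match(toupper(seq), AA1)
  if (anyNA(idx)) {
    abort(sprintf("unknown residue code(s): %s",
                  paste(unique(seq[is.na(idx)]), collapse = ", ")))
  }
  AA3[idx]
}

# Side-chain Z-matrix rows: atom placed from reference atoms (a, b, c) of the
# same residue with the given bond length (to c), bond angle (b-c-atom) and
# dihedral a-b-c-atom.  Dihedral entries "chiK[+/-off]" resolve against the
# residue's chi angles at build time; bare numbers are fixed.
sc_row <- function(name, a, b, c, bond, angle, dih) {
  data.frame(name = name, ref_a = a, ref_b = b, ref_c = c,
             bond = bond, angle = angle, dih = as.character(dih),
             stringsAsFactors = FALSE)
}

.cb <- sc_row("CB", "C", "N", "CA", IDEAL_GEOM$b_ca_cb, IDEAL_GEOM$a_n_ca_cb,
              IDEAL_GEOM$d_cb)

SIDECHAIN_TEMPLATES <- list(
  GLY = NULL,
  ALA = .cb,
  SER = rbind(.cb, sc_row("OG",  "N", "CA", "CB", 1.417, 110.8, "chi1")),
  CYS = rbind(.cb, sc_row("SG",  "N", "CA", "CB", 1.808, 113.8, "chi1")),
  THR = rbind(.cb,
              sc_row("OG1", "N", "CA", "CB", 1.433, 109.5, "chi1"),
              sc_row("CG2", "N", "CA", "CB", 1.521, 110.5, "chi1-120")),
  VAL = rbind(.cb,
              sc_row("CG1", "N", "CA", "CB", 1.527, 110.5, "chi1"),
              sc_row("CG2", "N", "CA", "CB", 1.527, 110.5, "chi1+120")),
  ILE = rbind(.cb,
              sc_row("CG1", "N", "CA", "CB", 1.530, 110.4, "chi1"),
              sc_row("CG2", "N", "CA", "CB", 1.521, 110.5, "chi1-120"),
              sc_row("CD1", "CA", "CB", "CG1", 1.513, 113.8, "chi2")),
  LEU = rbind(.cb,
              sc_row("CG",  "N", "CA", "CB", 1.530, 116.3, "chi1"),
              sc_row("CD1", "CA", "CB", "CG", 1.521, 110.7, "chi2"),
              sc_row("CD2", "CA", "CB", "CG", 1.521, 110.7, "chi2+120")),
  ASP = rbind(.cb,
              sc_row("CG",  "N", "CA", "CB", 1.516, 112.6, "chi1"),
              sc_row("OD1", "CA", "CB", "CG", 1.249, 118.4, "chi2"),
              sc_row("OD2", "CA", "CB", "CG", 1.249, 118.4, "chi2+180")),
  ASN = rbind(.cb,
              sc_row("CG",  "N", "CA", "CB", 1.516, 112.6, "chi1"),
              sc_row("OD1", "CA", "CB", "CG", 1.231, 120.8, "chi2"),
              sc_row("ND2", "CA", "CB", "CG", 1.328, 116.4, "chi2+180")),
  GLU = rbind(.cb,
              sc_row("CG",  "N", "CA", "CB", 1.520, 114.1, "chi1"),
              sc_row("CD",  "CA", "CB", "CG", 1.516, 112.6, "chi2"),
              sc_row("OE1", "CB", "CG", "CD", 1.249, 118.4, "chi3"),
              sc_row("OE2", "CB", "CG", "CD", 1.249, 118.4, "chi3+180")),
  GLN = rbind(.cb,
              sc_row("CG",  "N", "CA", "CB", 1.520, 114.1, "chi1"),
              sc_row("CD",  "CA", "CB", "CG", 1.516, 112.6, "chi2"),
              sc_row("OE1", "CB", "CG", "CD", 1.231, 120.8, "chi3"),
              sc_row("NE2", "CB", "CG", "CD", 1.328, 116.4, "chi3+180")),
  MET = rbind(.cb,
              sc_row("CG",  "N", "CA", "CB", 1.520, 114.1, "chi1"),
              sc_row("SD",  "CA", "CB", "CG", 1.803, 112.7, "chi2"),
              sc_row("CE",  "CB", "CG", "SD", 1.791, 100.9, "chi3")),
  LYS = rbind(.cb,
              sc_row("CG",  "N", "CA", "CB", 1.520, 114.1, "chi1"),
              sc_row("CD",  "CA", "CB", "CG", 1.520, 111.3, "chi2"),
              sc_row("CE",  "CB", "CG", "CD", 1.520, 111.3, "chi3"),
              sc_row("NZ",  "CG", "CD", "CE", 1.489, 111.9, "chi4")),
  ARG = rbind(.cb,
              sc_row("CG",  "N", "CA", "CB", 1.520, 114.1, "chi1"),
              sc_row("CD",  "CA", "CB", "CG", 1.520, 111.3, "chi2"),
              sc_row("NE",  "CB", "CG", "CD", 1.461, 112.0, "chi3"),
              sc_row("CZ",  "CG", "CD", "NE", 1.329, 124.2, "chi4"),
              sc_row("NH1", "CD", "NE", "CZ", 1.326, 120.0, "0"),
              sc_row("NH2", "CD", "NE", "CZ", 1.326, 120.0, "180")),
  PHE = rbind(.cb,
              sc_row("CG",  "N", "CA", "CB", 1.502, 113.8, "chi1"),
              sc_row("CD1", "CA", "CB", "CG", 1.390, 120.7, "chi2"),
              sc_row("CD2", "CA", "CB", "CG", 1.390, 120.7, "chi2+180"),
              sc_row("CE1", "CB", "CG", "CD1", 1.390, 120.0, "180"),
              sc_row("CE2", "CB", "CG", "CD2", 1.390, 120.0, "180"),
              sc_row("CZ",  "CG", "CD1", "CE1", 1.390, 120.0, "0")),
  TYR = rbind(.cb,
              sc_row("CG",  "N", "CA", "CB", 1.502, 113.8, "chi1"),
              sc_row("CD1", "CA", "CB", "CG", 1.390, 120.7, "chi2"),
              sc_row("CD2", "CA", "CB", "CG", 1.390, 120.7, "chi2+180"),
              sc_row("CE1", "CB", "CG", "CD1", 1.390, 120.0, "180"),
              sc_row("CE2", "CB", "CG", "CD2", 1.390, 120.0, "180"),
              sc_row("CZ",  "CG", "CD1", "CE1", 1.390, 120.0, "0"),
              sc_row("OH",  "CD1", "CE1", "CZ", 1.376, 119.9, "180")),
  HIS = rbind(.cb,
              sc_row("CG",  "N", "CA", "CB", 1.497, 113.8, "chi1"),
              sc_row("ND1", "CA", "CB", "CG", 1.371, 122.7, "chi2"),
              sc_row("CD2", "CA", "CB", "CG", 1.356, 131.0, "chi2+180"),
              sc_row("CE1", "CB", "CG", "ND1", 1.319, 109.0, "180"),
              sc_row("NE2", "CB", "CG", "CD2", 1.374, 107.0, "180")),
  TRP = rbind(.cb,
              sc_row("CG",  "N", "CA", "CB", 1.498, 113.6, "chi1"),
              sc_row("CD1", "CA", "CB", "CG", 1.365, 126.9, "chi2"),
              sc_row("CD2", "CA", "CB", "CG", 1.433, 126.6, "chi2+180"),
              sc_row("NE1", "CB", "CG", "CD1", 1.374, 110.2, "180"),
              sc_row("CE2", "CB", "CG", "CD2", 1.409, 107.2, "180"),
              sc_row("CE3", "CB", "CG", "CD2", 1.398, 133.9, "0"),
              sc_row("CZ2", "CG", "CD2", "CE2", 1.394, 122.3, "180"),
              sc_row("CZ3", "CG", "CD2", "CE3", 1.382, 118.6, "180"),
              sc_row("CH2", "CD2", "CE2", "CZ2", 1.368, 117.5, "0")),
  PRO = rbind(.cb,
              sc_row("CG",  "N", "CA", "CB", 1.492, 104.5, "chi1"),
              sc_row("CD",  "CA", "CB", "CG", 1.503, 106.1, "chi2"))
)

# Ring-closure bonds not implied by the Z-matrix parent relation (needed only
# for bonded-pair exclusions).
RING_CLOSURES <- list(
  PHE = list(c("CE2", "CZ")),
  TYR = list(c("CE2", "CZ")),
  HIS = list(c("CE1", "NE2")),
  TRP = list(c("NE1", "CE2"), c("CZ3", "CH2")),
  PRO = list(c("CD", "N"))
)

# Default chi angles used when the caller does not supply them.  chi1 defaults
# to trans (180 deg); ring chi2 near-perpendicular; proline ring puckered.
DEFAULT_CHI <- function(residue_name) {
  switch(residue_name,
    PRO = c(chi1 = 30, chi2 = -35),
    PHE = , TYR = , TRP = , HIS = c(chi1 = 180, chi2 = 90),
    ASP = , ASN = c(chi1 = 180, chi2 = 0),
    GLU = , GLN = c(chi1 = 180, chi2 = 180, chi3 = 0),
    c(chi1 = 180, chi2 = 180, chi3 = 180, chi4 = 180)
  )
}

# Aromatic ring atom sets used by ring extraction.
AROMATIC_RINGS <- list(
  PHE = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TYR = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  HIS = list(c("CG", "ND1", "CD2", "CE1", "NE2")),
  TRP = list(six = c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
             five = c("CG", "CD1", "NE1", "CE2", "CD2"))
)

# Coerce a sequence given as a one-letter string, one-letter vector or
# three-letter vector into three-letter codes.  A single string that is
# itself a three-letter code (e.g. "ARG") is one residue.
as_seq3 <- function(sequence) {
  if (length(sequence) == 1 && nchar(sequence[1]) > 1 &&
      !toupper(sequence[1]) %in% AA3) {
    sequence <- strsplit(sequence, "")[[1]]
  }
  if (all(nchar(sequence) == 3)) toupper(sequence) else aa_three(sequence)
}

element_of <- function(atom_name) {
  # first alphabetic character of the PDB atom name
  substr(gsub("[^A-Za-z].*$", "", gsub("^[0-9]*", "", atom_name)), 1, 1)
}

resolve_dih <- function(dih, chi) {
  if (grepl("^chi", dih)) {
    k <- as.integer(substr(dih, 4, 4))
    off <- if (nchar(dih) > 4) as.numeric(substr(dih, 5, nchar(dih))) else 0
    base <- chi[paste0("chi", k)]
    if (is.na(base)) base <- 180
    wrap_angle(unname(base) + off)
  } else {
    as.numeric(dih)
  }
}
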