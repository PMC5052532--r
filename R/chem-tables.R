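# Chemistry dictionaries: donor/acceptor/charged-group atoms per residue
# type, aromatic ring templates, apolar carbons, backbone set, radii.
# These are versioned constants; detectors look atoms up by PDB atom name.

#' The nine fingerprint interaction classes, in fixed block order
#'
#' Block order is serialized with every fingerprint and never changes:
#' contact, backbone, sidechain, polar, aromatic, hydrophobic,
#' hbond_donor, hbond_acceptor, charged.  `hbond_donor` means the
#' *residue* donates to the ligand; `hbond_acceptor` means the residue
#' accepts from the ligand.
#'
#' @format Character vector of length 9.
#' @export
SIFT_KINDS <- c("contact", "backbone", "sidechain", "polar", "aromatic",
                "hydrophobic", "hbond_donor", "hbond_acceptor", "charged")

# backbone heavy atoms (PDB names)
.BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

# water residue names
.WATER_RESNAMES <- c("HOH", "WAT", "DOD", "H2O")

# Side-chain donor atoms with their heavy-atom antecedent (for the proxy
# D-A angle when no hydrogens are present).  Backbone N (antecedent CA)
# is a donor for every residue type except PRO and is added in code.
.SC_DONORS <- list(
  ARG = c(NE = "CZ", NH1 = "CZ", NH2 = "CZ"),
  LYS = c(NZ = "CE"),
  ASN = c(ND2 = "CG"),
  GLN = c(NE2 = "CD"),
  HIS = c(ND1 = "CG", NE2 = "CD2"),
  SER = c(OG = "CB"),
  THR = c(OG1 = "CB"),
  TYR = c(OH = "CZ"),
  TRP = c(NE1 = "CD1"),
  CYS = c(SG = "CB")
)

# Side-chain acceptor atoms with antecedent.  Backbone O (antecedent C)
# and OXT accept for every residue type and are added in code.
.SC_ACCEPTORS <- list(
  ASP = c(OD1 = "CG", OD2 = "CG"),
  GLU = c(OE1 = "CD", OE2 = "CD"),
  ASN = c(OD1 = "CG"),
  GLN = c(OE1 = "CD"),
  HIS = c(ND1 = "CG", NE2 = "CD2"),
  SER = c(OG = "CB"),
  THR = c(OG1 = "CB"),
  TYR = c(OH = "CZ"),
  MET = c(SD = "CG")
)

# Formally charged side-chain groups.  HIS is aromatic by default and only
# treated as cationic when the `his_charged` flag is on.
.CHARGED_GROUPS <- list(
  ARG = list(atoms = c("NE", "NH1", "NH2"), sign = +1L),
  LYS = list(atoms = "NZ", sign = +1L),
  ASP = list(atoms = c("OD1", "OD2"), sign = -1L),
  GLU = list(atoms = c("OE1", "OE2"), sign = -1L),
  HIS = list(atoms = c("ND1", "NE2"), sign = +1L)
)

# Aromatic ring atom templates (a residue may carry more than one ring).
.AROMATIC_RINGS <- list(
  PHE = list(c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")),
  TYR = list(c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")),
  HIS = list(c("CG", "ND1", "CE1", "NE2", "CD2")),
  TRP = list(c("CG", "CD1", "NE1", "CE2", "CD2"),
             c("CD2", "CE2", "CZ2", "CH2", "CZ3", "CE3"))
)

# Apolar carbons: side-chain carbons with no bonded N or O (standard
# amino-acid topology applied once, by hand).
.APOLAR_CARBONS <- list(
  ALA = "CB",
  VAL = c("CB", "CG1", "CG2"),
  LEU = c("CB", "CG", "CD1", "CD2"),
  ILE = c("CB", "CG1", "CG2", "CD1"),
  PRO = c("CB", "CG"),
  PHE = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CB", "CG", "CD1", "CD2", "CE1", "CE2"),
  TRP = c("CB", "CG", "CD2", "CE3", "CZ2", "CZ3", "CH2"),
  MET = c("CB", "CG", "CE"),
  CYS = "CB",
  THR = "CG2",
  ASP = "CB",
  GLU = c("CB", "CG"),
  ASN = "CB",
  GLN = c("CB", "CG"),
  LYS = c("CB", "CG", "CD"),
  ARG = c("CB", "CG"),
  HIS = "CB"
)

# First side-chain heavy atom past CB, for chi1 = N-CA-CB-gamma.
.GAMMA_ATOMS <- c(
  ARG = "CG", ASN = "CG", ASP = "CG", CYS = "SG", GLN = "CG", GLU = "CG",
  HIS = "CG", ILE = "CG1", LEU = "CG", LYS = "CG", MET = "CG", PHE = "CG",
  PRO = "CG", SER = "OG", THR = "OG1", TRP = "CG", TYR = "CG", VAL = "CG1"
)

# Bondi van der Waals radii (Angstrom), by element symbol.
.VDW_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
                P = 1.80, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98)

# Single-bond covalent radii (Angstrom) for bond inference.
.COV_RADII <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, S = 1.05,
                P = 1.07, F = 0.57, CL = 1.02, BR = 1.20, I = 1.39)

#' Chemistry lookup tables used by the interaction detectors
#'
#' Returns the package's versioned chemistry dictionaries: per-residue
#' H-bond donor and acceptor atoms (with heavy-atom antecedents used for
#' the proxy angle), formally charged side-chain groups, aromatic ring
#' atom templates, apolar-carbon sets, the backbone atom set, the chi1
#' gamma-atom table, and Bondi van der Waals plus covalent radii.
#'
#' @return A named list of constant tables.
#' @examples
#' chem_tables()$gamma_atoms[["PHE"]]
#' @export
chem_tables <- function() {
  list(kinds = SIFT_KINDS,
       backbone = .BACKBONE_ATOMS,
       water_resnames = .WATER_RESNAMES,
       sc_donors = .SC_DONORS,
       sc_acceptors = .SC_ACCEPTORS,
       charged_groups = .CHARGED_GROUPS,
       aromatic_rings = .AROMATIC_RINGS,
       apolar_carbons = .APOLAR_CARBONS,
       gamma_atoms = as.list(.GAMMA_ATOMS),
       vdw_radii = .VDW_RADII,
       cov_radii = .COV_RADII)
}

#' Van der Waals radius lookup
#'
#' @param element Character vector of element symbols (case-insensitive).
#' @return Numeric vector of Bondi radii in Angstrom.
#' @export
vdw_radius <- function(element) {
  key <- toupper(element)
  bad <- !key %in% names(.VDW_RADII)
  if (any(bad))
    stop("no van der Waals radius for element(s): ",
         paste(unique(element[bad]), collapse = ", "))
  unname(.VDW_RADII[key])
}

.cov_radius <- function(element) {
  key <- toupper(element)
  bad <- !key %in% names(.COV_RADII)
  if (any(bad))
    stop("no covalent radius for element(s): ",
         paste(unique(element[bad]), collapse = ", "))
  unname(.COV_RADII[key])
}
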