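## Residue topology: chi dihedral definitions, ideal internal-coordinate
## tables for side-chain construction, intra-residue bond lists (for 1-2 /
## 1-3 / 1-4 exclusions) and hydrogen-bond donor/acceptor chemistry.
##
## Bond lengths/angles are standard ideal values; the CB placement torsion
## C-N-CA-CB = -122.6 deg gives L-amino-acid chirality. Proline is absent
## from the construction table (its ring closure couples chi to the
## backbone and cannot be built from a fixed internal-coordinate chain);
## its chi angles can still be measured.

.aa3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL")

.aa1to3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
             Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
             L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
             S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

#' Canonical amino-acid codes
#' @return Character vector of the twenty 3-letter codes.
#' @export
amino_acids <- function() .aa3

#' Convert 1-letter to 3-letter amino-acid codes
#' @param x character vector of 1- or 3-letter codes (case-insensitive).
#' @return 3-letter codes.
#' @export
aa_three <- function(x) {
  x <- toupper(x)
  out <- ifelse(nchar(x) == 1, .aa1to3[x], x)
  bad <- is.na(out) | !(out %in% c(.aa3, "DEL"))
  if (any(bad)) stop("unknown amino acid code(s): ",
                     paste(x[bad], collapse = ", "), call. = FALSE)
  unname(out)
}

## chi dihedral definitions: for each amino acid, a list of 4-atom name
## vectors, chi1 first.
.chi_atoms <- list(
  ALA = list(),
  GLY = list(),
  ARG = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD"),
             c("CB","CG","CD","NE"), c("CG","CD","NE","CZ")),
  ASN = list(c("N","CA","CB","CG"), c("CA","CB","CG","OD1")),
  ASP = list(c("N","CA","CB","CG"), c("CA","CB","CG","OD1")),
  CYS = list(c("N","CA","CB","SG")),
  GLN = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD"),
             c("CB","CG","CD","OE1")),
  GLU = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD"),
             c("CB","CG","CD","OE1")),
  HIS = list(c("N","CA","CB","CG"), c("CA","CB","CG","ND1")),
  ILE = list(c("N","CA","CB","CG1"), c("CA","CB","CG1","CD1")),
  LEU = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD1")),
  LYS = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD"),
             c("CB","CG","CD","CE"), c("CG","CD","CE","NZ")),
  MET = list(c("N","CA","CB","CG"), c("CA","CB","CG","SD"),
             c("CB","CG","SD","CE")),
  PHE = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD1")),
  PRO = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD")),
  SER = list(c("N","CA","CB","OG")),
  THR = list(c("N","CA","CB","OG1")),
  TRP = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD1")),
  TYR = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD1")),
  VAL = list(c("N","CA","CB","CG1"))
)

#' Number of chi dihedrals for an amino acid
#' @param amino_acid 3-letter code.
#' @return Integer chi count (Gly/Ala 0, Lys/Arg 4, ...).
#' @export
chi_count <- function(amino_acid) {
  aa <- aa_three(amino_acid)
  vapply(aa, function(a) length(.chi_atoms[[a]]), integer(1), USE.NAMES = FALSE)
}

.chi_defs <- function(amino_acid) {
  aa <- aa_three(amino_acid)
  def <- .chi_atoms[[aa]]
  if (is.null(def)) stop("no chi definition for ", amino_acid, call. = FALSE)
  def
}

## Side-chain Z-matrix rows: atom placed from references a-b-c with
## torsion = chi[chi_index] + offset (offset alone when chi_index is NA).
## CB is placed first for every non-Gly residue with the common row below.
.zrow <- function(atom, a, b, c, bond, angle, chi = NA_integer_, offset = 0) {
  data.frame(atom = atom, a = a, b = b, c = c, bond = bond, angle = angle,
             chi = chi, offset = offset, stringsAsFactors = FALSE)
}

.cb_row <- .zrow("CB", "C", "N", "CA", 1.530, 110.4, NA, -122.6)

.sidechain_z <- list(
  ALA = NULL,  # CB only
  GLY = NULL,  # nothing
  SER = .zrow("OG",  "N", "CA", "CB", 1.417, 111.1, 1L),
  CYS = .zrow("SG",  "N", "CA", "CB", 1.808, 114.4, 1L),
  THR = rbind(.zrow("OG1", "N", "CA", "CB", 1.433, 109.6, 1L),
              .zrow("CG2", "N", "CA", "CB", 1.521, 110.5, 1L, -121.5)),
  VAL = rbind(.zrow("CG1", "N", "CA", "CB", 1.521, 110.5, 1L),
              .zrow("CG2", "N", "CA", "CB", 1.521, 110.5, 1L, 121.6)),
  ILE = rbind(.zrow("CG1", "N", "CA", "CB", 1.530, 110.4, 1L),
              .zrow("CG2", "N", "CA", "CB", 1.521, 110.5, 1L, -128.7),
              .zrow("CD1", "CA", "CB", "CG1", 1.513, 113.9, 2L)),
  LEU = rbind(.zrow("CG",  "N", "CA", "CB", 1.530, 116.3, 1L),
              .zrow("CD1", "CA", "CB", "CG", 1.521, 110.7, 2L),
              .zrow("CD2", "CA", "CB", "CG", 1.521, 110.7, 2L, 120.0)),
  ASP = rbind(.zrow("CG",  "N", "CA", "CB", 1.516, 112.6, 1L),
              .zrow("OD1", "CA", "CB", "CG", 1.249, 118.4, 2L),
              .zrow("OD2", "CA", "CB", "CG", 1.249, 118.4, 2L, 180)),
  ASN = rbind(.zrow("CG",  "N", "CA", "CB", 1.516, 112.6, 1L),
              .zrow("OD1", "CA", "CB", "CG", 1.231, 120.8, 2L),
              .zrow("ND2", "CA", "CB", "CG", 1.328, 116.4, 2L, 180)),
  GLU = rbind(.zrow("CG",  "N", "CA", "CB", 1.520, 114.1, 1L),
              .zrow("CD",  "CA", "CB", "CG", 1.516, 112.6, 2L),
              .zrow("OE1", "CB", "CG", "CD", 1.249, 118.4, 3L),
              .zrow("OE2", "CB", "CG", "CD", 1.249, 118.4, 3L, 180)),
  GLN = rbind(.zrow("CG",  "N", "CA", "CB", 1.520, 114.1, 1L),
              .zrow("CD",  "CA", "CB", "CG", 1.516, 112.6, 2L),
              .zrow("OE1", "CB", "CG", "CD", 1.231, 120.8, 3L),
              .zrow("NE2", "CB", "CG", "CD", 1.328, 116.4, 3L, 180)),
  MET = rbind(.zrow("CG",  "N", "CA", "CB", 1.520, 114.1, 1L),
              .zrow("SD",  "CA", "CB", "CG", 1.803, 112.7, 2L),
              .zrow("CE",  "CB", "CG", "SD", 1.791, 100.9, 3L)),
  LYS = rbind(.zrow("CG",  "N", "CA", "CB", 1.520, 114.1, 1L),
              .zrow("CD",  "CA", "CB", "CG", 1.520, 111.3, 2L),
              .zrow("CE",  "CB", "CG", "CD", 1.520, 111.3, 3L),
              .zrow("NZ",  "CG", "CD", "CE", 1.489, 111.9, 4L)),
  ARG = rbind(.zrow("CG",  "N", "CA", "CB", 1.520, 114.1, 1L),
              .zrow("CD",  "CA", "CB", "CG", 1.520, 111.3, 2L),
              .zrow("NE",  "CB", "CG", "CD", 1.460, 112.0, 3L),
              .zrow("CZ",  "CG", "CD", "NE", 1.329, 124.2, 4L),
              .zrow("NH1", "CD", "NE", "CZ", 1.326, 120.0, NA, 0),
              .zrow("NH2", "CD", "NE", "CZ", 1.326, 120.0, NA, 180)),
  PHE = rbind(.zrow("CG",  "N", "CA", "CB", 1.502, 113.8, 1L),
              .zrow("CD1", "CA", "CB", "CG", 1.384, 120.8, 2L),
              .zrow("CD2", "CA", "CB", "CG", 1.384, 120.8, 2L, 180),
              .zrow("CE1", "CB", "CG", "CD1", 1.382, 120.7, NA, 180),
              .zrow("CE2", "CB", "CG", "CD2", 1.382, 120.7, NA, 180),
              .zrow("CZ",  "CG", "CD1", "CE1", 1.382, 120.0, NA, 0)),
  TYR = rbind(.zrow("CG",  "N", "CA", "CB", 1.512, 113.9, 1L),
              .zrow("CD1", "CA", "CB", "CG", 1.389, 120.8, 2L),
              .zrow("CD2", "CA", "CB", "CG", 1.389, 120.8, 2L, 180),
              .zrow("CE1", "CB", "CG", "CD1", 1.382, 121.2, NA, 180),
              .zrow("CE2", "CB", "CG", "CD2", 1.382, 121.2, NA, 180),
              .zrow("CZ",  "CG", "CD1", "CE1", 1.378, 119.6, NA, 0),
              .zrow("OH",  "CD1", "CE1", "CZ", 1.376, 119.9, NA, 180)),
  HIS = rbind(.zrow("CG",  "N", "CA", "CB", 1.497, 113.8, 1L),
              .zrow("ND1", "CA", "CB", "CG", 1.378, 122.7, 2L),
              .zrow("CD2", "CA", "CB", "CG", 1.356, 131.1, 2L, 180),
              .zrow("CE1", "CB", "CG", "ND1", 1.321, 109.2, NA, 180),
              .zrow("NE2", "CB", "CG", "CD2", 1.374, 107.2, NA, 180)),
  TRP = rbind(.zrow("CG",  "N", "CA", "CB", 1.498, 113.6, 1L),
              .zrow("CD1", "CA", "CB", "CG", 1.365, 127.0, 2L),
              .zrow("CD2", "CA", "CB", "CG", 1.433, 126.6, 2L, 180),
              .zrow("NE1", "CB", "CG", "CD1", 1.374, 110.2, NA, 180),
              .zrow("CE2", "CB", "CG", "CD2", 1.409, 107.2, NA, 180),
              .zrow("CE3", "CB", "CG", "CD2", 1.398, 133.9, NA, 0),
              .zrow("CZ2", "CG", "CD2", "CE2", 1.394, 122.4, NA, 180),
              .zrow("CZ3", "CG", "CD2", "CE3", 1.382, 118.6, NA, 180),
              .zrow("CH2", "CD2", "CE2", "CZ2", 1.368, 117.5, NA, 180))
)

## Ring-closure bonds not expressed by Z-matrix parentage.
.closure_bonds <- list(
  PHE = list(c("CE2", "CZ")),
  TYR = list(c("CE2", "CZ")),
  HIS = list(c("CE1", "NE2")),
  TRP = list(c("NE1", "CE2"), c("CZ3", "CH2"))
)

#' Ideal side-chain geometry table
#'
#' Internal-coordinate (Z-matrix) rows used by
#' \code{\link{build_side_chain}}: each side-chain heavy atom beyond CB is
#' placed by a bond length, bond angle and a torsion that is either one of
#' the residue's chi angles (plus a fixed offset for branch atoms) or a
#' fixed value (planar ring atoms, guanidinium). Proline is not buildable.
#'
#' @param amino_acid 3-letter code.
#' @return Data frame with columns atom, a, b, c (reference atom names),
#'   bond (Angstrom), angle (degrees), chi (index or NA), offset (degrees).
#'   Zero rows for Ala/Gly (CB handled separately).
#' @export
sidechain_geometry <- function(amino_acid) {
  aa <- aa_three(amino_acid)
  if (aa == "PRO" || !(aa %in% names(.sidechain_z))) {
    stop("geometry table does not cover ", aa, call. = FALSE)
  }
  z <- .sidechain_z[[aa]]
  if (is.null(z)) {
    z <- .zrow("CB", "C", "N", "CA", 1, 1)[0, ]  # empty frame, right columns
  }
  z
}

## Side-chain atom names (beyond backbone) for each amino acid.
sidechain_atom_names <- function(amino_acid) {
  aa <- aa_three(amino_acid)
  if (aa == "GLY") return(character(0))
  if (aa == "PRO") return(c("CB", "CG", "CD"))
  c("CB", .sidechain_z[[aa]]$atom)
}

## Bond list (pairs of atom names) within one residue including backbone,
## used to derive 1-2/1-3/1-4 exclusions.
residue_bonds <- function(amino_acid) {
  aa <- aa_three(amino_acid)
  bonds <- list(c("N", "CA"), c("CA", "C"), c("C", "O"), c("C", "OXT"))
  if (aa != "GLY") bonds <- c(bonds, list(c("CA", "CB")))
  if (aa == "PRO") {
    bonds <- c(bonds, list(c("CB", "CG"), c("CG", "CD"), c("CD", "N")))
  } else if (!is.null(.sidechain_z[[aa]])) {
    z <- .sidechain_z[[aa]]
    bonds <- c(bonds, lapply(seq_len(nrow(z)),
                             function(i) c(z$c[i], z$atom[i])))
    bonds <- c(bonds, .closure_bonds[[aa]])
  }
  bonds
}

## ---- Hydrogen-bond chemistry ------------------------------------------

## donor atoms: name -> antecedent (heavy atom bonded to the donor), per
## amino acid; "*" marks the backbone amide shared by all residues.
.hb_donors <- list(
  "*"   = list(N = "CA"),
  SER = list(OG = "CB"), THR = list(OG1 = "CB"), TYR = list(OH = "CZ"),
  CYS = list(SG = "CB"),
  LYS = list(NZ = "CE"),
  ARG = list(NE = "CD", NH1 = "CZ", NH2 = "CZ"),
  ASN = list(ND2 = "CG"), GLN = list(NE2 = "CD"),
  HIS = list(ND1 = "CG", NE2 = "CD2"),
  TRP = list(NE1 = "CD1")
)

.hb_acceptors <- list(
  "*"   = c("O", "OXT"),
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"),
  ASN = "OD1", GLN = "OE1",
  SER = "OG", THR = "OG1", TYR = "OH",
  HIS = c("ND1", "NE2")
)

#' Hydrogen-bond donor atoms of a residue type
#' @param amino_acid 3-letter code.
#' @return Named character vector: donor atom name -> antecedent atom name
#'   (backbone N included).
#' @export
hbond_donors <- function(amino_acid) {
  aa <- aa_three(amino_acid)
  d <- c(.hb_donors[["*"]], .hb_donors[[aa]])
  stats::setNames(unlist(d), names(d))
}

#' Hydrogen-bond acceptor atoms of a residue type
#' @param amino_acid 3-letter code.
#' @return Character vector of acceptor atom names (backbone O included).
#' @export
hbond_acceptors <- function(amino_acid) {
  aa <- aa_three(amino_acid)
  unname(c(.hb_acceptors[["*"]], .hb_acceptors[[aa]]))
}
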