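#' @title Packaged residue reference tables
#' @description Constants shared across the label and feature modules: the
#'   canonical residue alphabet, maximum accessible surface areas for RSA
#'   normalisation, and the amino-acid property tables used as
#'   position-independent features.
#' @name sacon-tables
NULL

#' Canonical residue alphabet (PSI-BLAST column order)
#'
#' All profile matrices are reconciled to this 20-letter ordering before
#' feature assembly, so column permutations in input files never change the
#' encoded features.
#'
#' @return Character vector of the 20 standard one-letter residue codes in
#'   PSI-BLAST PSSM column order.
#' @export
canonical_residues <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

#' Maximum accessible surface area per residue type
#'
#' Rost--Sander normalisation values in square Angstroms, used as the
#' denominator when converting absolute ASA to relative solvent
#' accessibility.  Override with a two-column text file via
#' [solvent_config()].
#'
#' @return Named numeric vector (names are one-letter residue codes).
#' @export
max_asa_table <- function() {
  c(A = 106, R = 248, N = 157, D = 163, C = 135,
    Q = 198, E = 194, G = 84,  H = 184, I = 169,
    L = 164, K = 205, M = 188, F = 197, P = 136,
    S = 130, T = 142, W = 227, Y = 222, V = 142)
}

# Seven physicochemical scales, one row per residue type, canonical order.
# Columns: steric (graph-shape index), hydrophobicity (Kyte-Doolittle),
# volume (A^3, Zamyatnin), polarizability, isoelectric point, helix and
# sheet propensities (Chou-Fasman).
.physicochemical_matrix <- function() {
  aa <- canonical_residues()
  steric <- c(A = 1.28, R = 2.34, N = 1.60, D = 1.60, C = 1.77,
              Q = 1.56, E = 1.56, G = 0.00, H = 2.99, I = 4.19,
              L = 2.59, K = 1.89, M = 2.35, F = 2.94, P = 2.67,
              S = 1.31, T = 3.03, W = 3.21, Y = 2.94, V = 3.67)
  hydro <- c(A = 1.8,  R = -4.5, N = -3.5, D = -3.5, C = 2.5,
             Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
             L = 3.8,  K = -3.9, M = 1.9,  F = 2.8,  P = -1.6,
             S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)
  volume <- c(A = 88.6,  R = 173.4, N = 114.1, D = 111.1, C = 108.5,
              Q = 143.8, E = 138.4, G = 60.1,  H = 153.2, I = 166.7,
              L = 166.7, K = 168.6, M = 162.9, F = 189.9, P = 112.7,
              S = 89.0,  T = 116.1, W = 227.8, Y = 193.6, V = 140.0)
  polar <- c(A = 0.05, R = 0.29, N = 0.13, D = 0.11, C = 0.13,
             Q = 0.18, E = 0.15, G = 0.00, H = 0.23, I = 0.19,
             L = 0.19, K = 0.22, M = 0.22, F = 0.29, P = 0.00,
             S = 0.06, T = 0.11, W = 0.41, Y = 0.30, V = 0.14)
  pi <- c(A = 6.00, R = 10.76, N = 5.41, D = 2.77, C = 5.07,
          Q = 5.65, E = 3.22,  G = 5.97, H = 7.59, I = 6.02,
          L = 5.98, K = 9.74,  M = 5.74, F = 5.48, P = 6.30,
          S = 5.68, T = 5.60,  W = 5.89, Y = 5.66, V = 5.96)
  helix <- c(A = 1.42, R = 0.98, N = 0.67, D = 1.01, C = 0.70,
             Q = 1.11, E = 1.51, G = 0.57, H = 1.00, I = 1.08,
             L = 1.21, K = 1.16, M = 1.45, F = 1.13, P = 0.57,
             S = 0.77, T = 0.83, W = 1.08, Y = 0.69, V = 1.06)
  sheet <- c(A = 0.83, R = 0.93, N = 0.89, D = 0.54, C = 1.19,
             Q = 1.10, E = 0.37, G = 0.75, H = 0.87, I = 1.60,
             L = 1.30, K = 0.74, M = 1.05, F = 1.38, P = 0.55,
             S = 0.75, T = 1.19, W = 1.37, Y = 1.47, V = 1.70)
  m <- cbind(steric = steric[aa], hydrophobicity = hydro[aa],
             volume = volume[aa], polarizability = polar[aa],
             isoelectric = pi[aa], helix_prob = helix[aa],
             sheet_prob = sheet[aa])
  rownames(m) <- aa
  m
}

# Synthetic additive pairwise contact potential: e(a, b) = -(h(a) + h(b)) / 2
# on the Kyte-Doolittle scale.  Captures the dominant hydrophobic component
# of statistical residue-residue contact potentials; not a published matrix.
.contact_potential_matrix <- function() {
  aa <- canonical_residues()
  h <- .physicochemical_matrix()[, "hydrophobicity"]
  m <- -outer(h, h, "+") / 2
  dimnames(m) <- list(aa, aa)
  m
}

#' Amino-acid property table for position-independent features
#'
#' Bundles the 20-value contact-potential row and 7 physicochemical
#' properties per residue type, giving the 27 position-independent features
#' encoded per residue.  The physicochemical block uses standard published
#' scales; the contact potential is a synthetic additive
#' hydrophobicity-based surrogate (see the methods vignette).  Either block
#' can be overridden.
#'
#' @param contact_potential optional 20x20 numeric matrix with residue
#'   dimnames (canonical order enforced).
#' @param physicochemical optional 20x7 numeric matrix with residue rownames.
#' @return Object of class `amino_acid_table` with elements
#'   `contact_potential` (20x20) and `physicochemical` (20x7), rows in
#'   canonical residue order.
#' @export
amino_acid_table <- function(contact_potential = NULL, physicochemical = NULL) {
  aa <- canonical_residues()
  cp <- if (is.null(contact_potential)) .contact_potential_matrix() else {
    stopifnot(is.matrix(contact_potential), all(aa %in% rownames(contact_potential)))
    contact_potential[aa, aa, drop = FALSE]
  }
  pc <- if (is.null(physicochemical)) .physicochemical_matrix() else {
    stopifnot(is.matrix(physicochemical), ncol(physicochemical) == 7,
              all(aa %in% rownames(physicochemical)))
    physicochemical[aa, , drop = FALSE]
  }
  structure(list(contact_potential = cp, physicochemical = pc),
            class = "amino_acid_table")
}

# Three-letter <-> one-letter residue code maps used by the PDB reader/writer.
.aa_three_to_one <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

.aa_one_to_three <- stats::setNames(names(.aa_three_to_one),
                                    unname(.aa_three_to_one))
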