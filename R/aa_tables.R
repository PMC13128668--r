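# Amino-acid reference tables used by the descriptor families.
# All tables are ordered by the canonical one-letter alphabet below.

#' Canonical amino-acid alphabet
#'
#' The 20 standard amino acids in alphabetical one-letter order. Every
#' descriptor family, property scale, and feature name in the package uses
#' this order.
#'
#' @return Character vector of length 20.
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' Sense-codon multiplicities of the standard genetic code
#'
#' Number of sense codons encoding each amino acid (61 in total); the
#' expected dipeptide frequencies of the DDE descriptor are derived from
#' these counts.
#'
#' @return Named integer vector over [aa_alphabet()] summing to 61.
#' @export
codon_counts <- function() {
  c(A = 4L, C = 2L, D = 2L, E = 2L, F = 2L, G = 4L, H = 2L, I = 3L,
    K = 2L, L = 6L, M = 1L, N = 2L, P = 4L, Q = 2L, R = 6L, S = 6L,
    T = 4L, V = 4L, W = 1L, Y = 2L)
}

#' Per-residue physicochemical property scales
#'
#' Eight classical per-residue scales used by the Moran autocorrelation
#' descriptor and (a subset) by the physicochemical distance matrix:
#' Kyte-Doolittle hydropathy, Hopp-Woods hydrophilicity, Eisenberg consensus
#' hydrophobicity, average side-chain mass, Grantham polarity, Grantham
#' volume, isoelectric point, and approximate net charge at pH 7.
#'
#' @return Numeric matrix, properties in rows, the 20 residues
#'   ([aa_alphabet()]) in columns. Raw (unstandardized) values.
#' @export
aa_property_scales <- function() {
  aa <- aa_alphabet()
  m <- rbind(
    hydropathy = c(1.8, 2.5, -3.5, -3.5, 2.8, -0.4, -3.2, 4.5, -3.9, 3.8,
                   1.9, -3.5, -1.6, -3.5, -4.5, -0.8, -0.7, 4.2, -0.9, -1.3),
    hydrophilicity = c(-0.5, -1.0, 3.0, 3.0, -2.5, 0.0, -0.5, -1.8, 3.0, -1.8,
                       -1.3, 0.2, 0.0, 0.2, 3.0, 0.3, -0.4, -1.5, -3.4, -2.3),
    hydrophobicity = c(0.62, 0.29, -0.90, -0.74, 1.19, 0.48, -0.40, 1.38,
                       -1.50, 1.06, 0.64, -0.78, 0.12, -0.85, -2.53, -0.18,
                       -0.05, 1.08, 0.81, 0.26),
    side_chain_mass = c(71.0788, 103.1388, 115.0886, 129.1155, 147.1766,
                        57.0519, 137.1411, 113.1594, 128.1741, 113.1594,
                        131.1926, 114.1038, 97.1167, 128.1307, 156.1875,
                        87.0782, 101.1051, 99.1326, 186.2132, 163.1760) - 56.0436,
    polarity = c(8.1, 5.5, 13.0, 12.3, 5.2, 9.0, 10.4, 5.2, 11.3, 4.9,
                 5.7, 11.6, 8.0, 10.5, 10.5, 9.2, 8.6, 5.9, 5.4, 6.2),
    volume = c(31, 55, 54, 83, 132, 3, 96, 111, 119, 111,
               105, 56, 32.5, 85, 124, 32, 61, 84, 170, 136),
    isoelectric_point = c(6.00, 5.07, 2.77, 3.22, 5.48, 5.97, 7.59, 6.02,
                          9.74, 5.98, 5.74, 5.41, 6.30, 5.65, 10.76, 5.68,
                          5.60, 5.96, 5.89, 5.66),
    net_charge = c(0, 0, -1, -1, 0, 0, 0.1, 0, 1, 0,
                   0, 0, 0, 0, 1, 0, 0, 0, 0, 0)
  )
  colnames(m) <- aa
  m
}

#' Three-class physicochemical partitions for the CTD descriptor
#'
#' The standard seven attributes (hydrophobicity, normalized van der Waals
#' volume, polarity, polarizability, charge, secondary-structure propensity,
#' solvent accessibility), each splitting the alphabet into three disjoint
#' classes.
#'
#' @return Named list of seven attributes; each a list of three character
#'   vectors partitioning [aa_alphabet()].
#' @export
ctd_attributes <- function() {
  split3 <- function(a, b, cc) {
    lapply(list(a, b, cc), function(s) strsplit(s, "")[[1]])
  }
  list(
    hydrophobicity = split3("RKEDQN", "GASTPHY", "CLVIMFW"),
    vdw_volume = split3("GASCTPD", "NVEQIL", "MHKFRYW"),
    polarity = split3("LIFWCMVY", "PATGS", "HQRKNED"),
    polarizability = split3("GASDT", "CPNVEQIL", "KMHFRYW"),
    charge = split3("KR", "ANCQGHILMFPSTWYV", "DE"),
    secondary_structure = split3("EALMQKRH", "VIYCWFT", "GNPSD"),
    solvent_accessibility = split3("ALFCGIVW", "RKQEND", "MSPTHY")
  )
}

#' Pairwise physicochemical distance between residues
#'
#' Euclidean distance between residues in the space of standardized
#' hydropathy, hydrophilicity, and side-chain mass (each scale centred and
#' scaled to unit population variance over the 20 residues before taking
#' distances). Used by the sequence-order-coupling-number descriptor.
#'
#' @return Symmetric 20 x 20 numeric matrix with zero diagonal, rows and
#'   columns ordered and named by [aa_alphabet()].
#' @export
aa_distance_matrix <- function() {
  p <- aa_property_scales()[c("hydropathy", "hydrophilicity", "side_chain_mass"), ]
  z <- t(apply(p, 1, function(v) (v - mean(v)) / stats::sd(v) / sqrt(19 / 20)))
  d <- as.matrix(stats::dist(t(z)))
  dimnames(d) <- list(aa_alphabet(), aa_alphabet())
  d
}

# residues outside the 20-letter alphabet that have conventional meanings
non_standard_residues <- function() c("B", "J", "O", "U", "X", "Z")
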