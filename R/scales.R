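# Amino-acid alphabets, property scales, class partitions and distance
# matrices used throughout the feature encoders. All tables are keyed by the
# 20 standard one-letter codes in the fixed order of `AA_ALPHABET`.

#' The 20 standard amino acids
#'
#' One-letter codes, alphabetical, the canonical column/row order for every
#' per-residue table in the package.
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

aa_named <- function(x) stats::setNames(x, AA_ALPHABET)

# Kyte-Doolittle hydropathy
KD_HYDROPATHY <- aa_named(c(
  1.8, 2.5, -3.5, -3.5, 2.8, -0.4, -3.2, 4.5, -3.9, 3.8,
  1.9, -3.5, -1.6, -3.5, -4.5, -0.8, -0.7, 4.2, -0.9, -1.3
))

# Hopp-Woods hydrophilicity
HW_HYDROPHILICITY <- aa_named(c(
  -0.5, -1.0, 3.0, 3.0, -2.5, 0.0, -0.5, -1.8, 3.0, -1.8,
  -1.3, 0.2, 0.0, 0.2, 3.0, 0.3, -0.4, -1.5, -3.4, -2.3
))

# Average residue masses (Da), i.e. amino-acid mass minus one water
RESIDUE_MASS <- aa_named(c(
  71.0788, 103.1388, 115.0886, 129.1155, 147.1766, 57.0519, 137.1411,
  113.1594, 128.1741, 113.1594, 131.1926, 114.1038, 97.1167, 128.1307,
  156.1875, 87.0782, 101.1051, 99.1326, 186.2132, 163.1760
))

# Chou-Fasman conformational propensities (helix, strand) used by the
# baseline secondary-structure annotator; coil baseline is 1.0.
CF_HELIX <- aa_named(c(
  1.42, 0.70, 1.01, 1.51, 1.13, 0.57, 1.00, 1.08, 1.14, 1.21,
  1.45, 0.67, 0.57, 1.11, 0.98, 0.77, 0.83, 1.06, 1.08, 0.69
))
CF_STRAND <- aa_named(c(
  0.83, 1.19, 0.54, 0.37, 1.38, 0.75, 0.87, 1.60, 0.74, 1.30,
  1.05, 0.89, 0.55, 1.10, 0.93, 0.75, 1.19, 1.70, 1.37, 1.47
))

# Residues enriched in intrinsically disordered regions (baseline annotator)
DISORDER_PRONE <- c("D", "E", "K", "R", "S", "Q", "P", "G")

# pKa set (EMBOSS-style) for the isoelectric-point calculation
PKA_TABLE <- list(
  nterm = 8.6, cterm = 3.6,
  positive = c(K = 10.8, R = 12.5, H = 6.5),
  negative = c(D = 3.9, E = 4.1, C = 8.5, Y = 10.1)
)

# Grantham (1974) amino-acid properties: composition c, polarity p,
# side-chain volume v; distances recomputed from the published formula.
GRANTHAM_PROPERTIES <- data.frame(
  aa = AA_ALPHABET,
  c = c(0, 2.75, 1.38, 0.92, 0, 0.74, 0.58, 0, 0.33, 0,
        0, 1.33, 0.39, 0.89, 0.65, 1.42, 0.71, 0, 0.13, 0.20),
  p = c(8.1, 5.5, 13.0, 12.3, 5.2, 9.0, 10.4, 5.2, 11.3, 4.9,
        5.7, 11.6, 8.0, 10.5, 10.5, 9.2, 8.6, 5.9, 5.4, 6.2),
  v = c(31, 55, 54, 83, 132, 3, 96, 111, 119, 111,
        105, 56, 32.5, 85, 124, 32, 61, 84, 170, 136)
)

#' Grantham physicochemical distance matrix
#'
#' The 20x20 amino-acid distance matrix of Grantham (1974), recomputed from
#' the published composition/polarity/volume properties and scaling
#' constants and rounded to the printed integer values. Zero diagonal.
#'
#' @return A 20x20 numeric matrix with dimnames [AA_ALPHABET].
#' @export
grantham_matrix <- function() {
  pr <- GRANTHAM_PROPERTIES
  alpha <- 1.833; beta <- 0.1018; gamma <- 0.000399; rho <- 50.723
  d <- outer(seq_len(20), seq_len(20), function(i, j) {
    sqrt(alpha * (pr$c[i] - pr$c[j])^2 +
         beta  * (pr$p[i] - pr$p[j])^2 +
         gamma * (pr$v[i] - pr$v[j])^2) * rho
  })
  d <- round(d)
  dimnames(d) <- list(AA_ALPHABET, AA_ALPHABET)
  d
}

#' Physicochemical sequence-coupling distance matrix
#'
#' Package-defined Euclidean distance over three standardized amino-acid
#' scales (Kyte-Doolittle hydropathy, Hopp-Woods hydrophilicity, Grantham
#' side-chain volume). Used as the second coupling matrix of the
#' quasi-sequence-order descriptors alongside [grantham_matrix()]. Zero
#' diagonal, symmetric.
#'
#' @return A 20x20 numeric matrix with dimnames [AA_ALPHABET].
#' @export
physico_distance_matrix <- function() {
  std <- function(x) (x - mean(x)) / stats::sd(x)
  m <- cbind(std(KD_HYDROPATHY), std(HW_HYDROPHILICITY),
             std(aa_named(GRANTHAM_PROPERTIES$v)))
  d <- as.matrix(stats::dist(m)) / sqrt(3)
  dimnames(d) <- list(AA_ALPHABET, AA_ALPHABET)
  d
}

# ---- class partitions ------------------------------------------------------

split_groups <- function(groups) {
  # "ARN" style strings -> named class index vector over the 20 AAs
  out <- stats::setNames(rep(NA_integer_, 20), AA_ALPHABET)
  for (i in seq_along(groups)) {
    out[strsplit(groups[[i]], "")[[1]]] <- i
  }
  stopifnot(!anyNA(out))
  out
}

#' Five-class physicochemical amino-acid alphabet
#'
#' Partition into hydrophobic, hydrophilic, neutral, positively and
#' negatively charged residues; used for the grouped dipeptide composition
#' and the class-frequency features.
#'
#' @return Named integer vector (1..5) over the 20 amino acids, with class
#'   names in `attr(, "classes")`.
#' @export
five_class_alphabet <- function() {
  g <- split_groups(c(
    hydrophobic = "ACFILMVWY",
    hydrophilic = "NQST",
    neutral     = "GHP",
    positive    = "KR",
    negative    = "DE"
  ))
  attr(g, "classes") <- c("hydrophobic", "hydrophilic", "neutral",
                          "positive", "negative")
  g
}

#' Three-class amino-acid alphabet for grouped tripeptides
#'
#' Hydrophobic / hydrophilic / neutral partition (W assigned hydrophobic so
#' the classes cover all 20 residues).
#'
#' @return Named integer vector (1..3) with class names in
#'   `attr(, "classes")`.
#' @export
three_class_alphabet <- function() {
  g <- split_groups(c(
    hydrophobic = "FIMLVYCAW",
    hydrophilic = "RKNDEP",
    neutral     = "THGSQ"
  ))
  attr(g, "classes") <- c("hydrophobic", "hydrophilic", "neutral")
  g
}

#' Ten functional side-chain groups
#'
#' Partition of the 20 amino acids by side-chain functional group
#' (sulfhydryl, thiol, phenyl, carboxyl, guanidyl, imidazole, primary amino,
#' amido, hydroxyl, non-polar).
#'
#' @return Named integer vector (1..10) with group names in
#'   `attr(, "classes")`.
#' @export
functional_group_alphabet <- function() {
  g <- split_groups(c(
    sulfhydryl    = "M",
    thiol         = "C",
    phenyl        = "FWY",
    carboxyl      = "DE",
    guanidyl      = "R",
    imidazole     = "H",
    primary_amino = "K",
    amido         = "NQ",
    hydroxyl      = "ST",
    non_polar     = "GAVLIP"
  ))
  attr(g, "classes") <- c("sulfhydryl", "thiol", "phenyl", "carboxyl",
                          "guanidyl", "imidazole", "primary_amino", "amido",
                          "hydroxyl", "non_polar")
  g
}

#' Seven-property CTD partitions
#'
#' The standard three-class partitions of the amino-acid alphabet for the
#' seven physicochemical properties of the composition/transition/
#' distribution descriptors: hydrophobicity, normalized van der Waals
#' volume, polarity, polarizability, charge, secondary-structure preference
#' and solvent accessibility.
#'
#' @return Named list of seven named integer vectors (classes 1..3).
#' @export
ctd_partitions <- function() {
  defs <- list(
    hydrophobicity = c("RKEDQN", "GASTPHY", "CLVIMFW"),
    vdw_volume     = c("GASTPDC", "NVEQIL", "MHKFRYW"),
    polarity       = c("LIFWCMVY", "PATGS", "HQRKNED"),
    polarizability = c("GASDT", "CPNVEQIL", "KMHFRYW"),
    charge         = c("KR", "ANCQGHILMFPSTWYV", "DE"),
    secondary_structure   = c("EALMQKRH", "VIYCWFT", "GNPSD"),
    solvent_accessibility = c("ALFCGIVW", "RKQEND", "MSPTHY")
  )
  lapply(defs, split_groups)
}

# AA-class memberships for the per-secondary-structure-state frequency
# features ("small" follows the Taylor classification).
SS_AA_CLASSES <- list(
  sulfur   = c("C", "M"),
  aromatic = c("F", "W", "Y"),
  charged  = c("D", "E", "K", "R"),
  polar    = c("N", "Q", "S", "T", "Y", "H"),
  small    = c("A", "C", "D", "G", "N", "P", "S", "T", "V")
)

# Default AAindex identifiers for the autocorrelation / total-property
# descriptors: one hydrophobicity, one flexibility, one polarizability scale.
DEFAULT_AUTOCORR_PROPERTIES <- c(
  hydrophobicity = "KYTJ820101",
  flexibility    = "BHAR880101",
  polarizability = "CHAM820101"
)

seq_to_chars <- function(sequence) strsplit(sequence, "")[[1]]

aa_counts <- function(chars) {
  tab <- table(factor(chars, levels = AA_ALPHABET))
  stats::setNames(as.numeric(tab), AA_ALPHABET)
}
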