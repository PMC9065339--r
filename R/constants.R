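#' @importFrom rlang .data abort warn inform %||%
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join inner_join bind_rows bind_cols n distinct across all_of rename
#' @importFrom tibble tibble as_tibble
#' @importFrom stats predict setNames
#' @importFrom utils head
NULL

# 20 standard amino acids: 3-letter and 1-letter codes
.AA3 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)

# PSI-BLAST ASCII PSSM column order
.PSSM_ALPHABET <- c(
  "A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"
)

# Feature-table column order: 20 PSSM columns (alphabetical residue letter)
# then the 7 network-topology columns.
.PSSM_COLS <- paste0("pssm_", sort(.PSSM_ALPHABET))
.RIN_COLS <- c(
  "betweenness", "closeness", "eigenvector", "eccentricity",
  "degree", "clustering", "avg_neighbor_degree"
)
.FEATURE_COLS <- c(.PSSM_COLS, .RIN_COLS)
.RESIDUE_KEYS <- c("structure_id", "chain", "resnum", "icode", "resname")

.WATER_NAMES <- c("HOH", "WAT", "DOD")

#' Feature column names
#'
#' The fixed column order of the 27-dimensional per-residue feature vector:
#' the 20 position-specific scoring matrix (PSSM) columns
#' (`pssm_A` ... `pssm_Y`, alphabetical by one-letter residue code) followed
#' by the 7 residue-interaction-network topology columns (`betweenness`,
#' `closeness`, `eigenvector`, `eccentricity`, `degree`, `clustering`,
#' `avg_neighbor_degree`).
#'
#' @param group `"all"`, `"pssm"` or `"rin"`.
#' @return Character vector of column names.
#' @export
#' @examples
#' feature_columns("rin")
feature_columns <- function(group = c("all", "pssm", "rin")) {
  group <- match.arg(group)
  switch(group, all = .FEATURE_COLS, pssm = .PSSM_COLS, rin = .RIN_COLS)
}

#' Convert 3-letter amino-acid codes to 1-letter codes
#'
#' @param x Character vector of 3-letter codes (case-insensitive).
#' @return Character vector of 1-letter codes; `NA` for non-standard
#'   residues.
#' @export
#' @examples
#' aa3_to_1(c("ALA", "TRP"))
aa3_to_1 <- function(x) unname(.AA3[toupper(x)])

`%|NA|%` <- function(x, y) ifelse(is.na(x), y, x)
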