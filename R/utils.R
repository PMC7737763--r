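# Internal geometry and angle helpers shared across modules.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Wrap angles into [-180, 180)
#' @param x angles in degrees
#' @return wrapped angles
#' @keywords internal
wrap180 <- function(x) ((x + 180) %% 360) - 180

# Wrap an angular difference into (-period/2, period/2]; default full circle.
# `period` may be a vector (per-dimension periods), recycled to length(x).
wrap_diff <- function(x, period = 360) {
  period <- rep_len(period, length(x))
  y <- x %% period
  adj <- !is.na(y) & y > period / 2
  y[adj] <- y[adj] - period[adj]
  y
}

# Nearest integer, rounding halves away from zero (base round() is banker's).
nint <- function(x) trunc(x + sign(x) * 0.5)

#' Dihedral angle of four points
#'
#' Signed torsion angle about the b-c axis following the IUPAC convention
#' (clockwise positive when viewed from b towards c), in degrees wrapped to
#' `[-180, 180)`. Returns `NA` for degenerate (collinear) geometry.
#'
#' @param a,b,c,d numeric 3-vectors, Angstrom.
#' @return angle in degrees, or `NA_real_`.
#' @export
dihedral <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  if (sum(n1^2) < 1e-12 || sum(n2^2) < 1e-12) return(NA_real_)
  cr <- c(n1[2] * n2[3] - n1[3] * n2[2],
          n1[3] * n2[1] - n1[1] * n2[3],
          n1[1] * n2[2] - n1[2] * n2[1])
  x <- sum(n1 * n2)
  y <- sum(cr * b2) / sqrt(sum(b2^2))
  wrap180(rad2deg(atan2(y, x)))
}

# Proton numbers for elements seen in macromolecular models (no exotic metals).
.element_z <- c(
  H = 1, D = 1, C = 6, N = 7, O = 8, F = 9, NA. = 11, MG = 12, P = 15, S = 16,
  CL = 17, K = 19, CA = 20, MN = 25, FE = 26, CO = 27, NI = 28, CU = 29,
  ZN = 30, SE = 34, BR = 35, I = 53
)

proton_number <- function(element) {
  el <- toupper(trimws(element))
  el[el == "NA"] <- "NA."
  z <- unname(.element_z[el])
  z[is.na(z)] <- 6  # unknown elements scored like carbon rather than dropped
  z
}

# Derive an element symbol from a PDB atom name when the element column is
# blank. Two-letter elements in protein work are rare; strip digits/primes and
# take the first character unless the full name is a known two-letter symbol.
element_from_name <- function(name) {
  vapply(name, function(nm) {
    nm <- gsub("[0-9']", "", toupper(trimws(nm)))
    if (nm %in% c("SE", "FE", "ZN", "MG", "MN", "CL", "BR", "NA", "CU", "NI", "CO"))
      return(nm)
    substr(nm, 1, 1)
  }, character(1), USE.NAMES = FALSE)
}

# The 20 canonical amino acid three-letter codes.
.standard_aa <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                  "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                  "THR", "TRP", "TYR", "VAL")

.aa_one_letter <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)

one_letter_code <- function(resname) {
  out <- unname(.aa_one_letter[toupper(resname)])
  out[is.na(out)] <- "X"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
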