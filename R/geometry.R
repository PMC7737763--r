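# Per-residue B-factor statistics, backbone torsions, and Ramachandran
# probability / classification.

#' Per-residue B-factor statistics
#'
#' Minimum, maximum, mean, and population standard deviation of the B-factors
#' of a residue's included atoms (hydrogens excluded by default).
#'
#' @param residue a `Residue`.
#' @param include_hydrogens include hydrogen B-factors in the aggregation.
#' @return list of class `BFactorStats` with `minimum`, `maximum`, `mean`,
#'   `sd` (all Angstrom^2) and `n_atoms`; all-`NA` with `n_atoms = 0` when the
#'   residue has no included atoms.
#' @export
bfactor_summary <- function(residue, include_hydrogens = FALSE) {
  b <- included_atoms(residue, include_hydrogens)$b
  b <- b[!is.na(b)]
  out <- if (length(b) == 0L) {
    list(minimum = NA_real_, maximum = NA_real_, mean = NA_real_,
         sd = NA_real_, n_atoms = 0L)
  } else {
    m <- mean(b)
    list(minimum = min(b), maximum = max(b), mean = m,
         sd = sqrt(mean((b - m)^2)), n_atoms = length(b))
  }
  class(out) <- "BFactorStats"
  out
}

#' Backbone phi/psi torsions of one residue
#'
#' phi(i) is the C(i-1)-N(i)-CA(i)-C(i) torsion, psi(i) the
#' N(i)-CA(i)-C(i)-N(i+1) torsion (IUPAC sign, degrees in `[-180, 180)`).
#' An angle is `NA` at chain termini, when a required atom is missing, when a
#' neighbour is not an amino acid, or across a chain break (peptide C-N
#' distance above `break_distance`).
#'
#' @param chain a `Chain`.
#' @param index 1-based residue index within the chain.
#' @param break_distance maximum C(i-1)-N(i) bond length in Angstrom still
#'   treated as a peptide bond (default 2.5).
#' @return named numeric vector `c(phi = , psi = )`.
#' @export
backbone_torsions <- function(chain, index, break_distance = 2.5) {
  res <- chain$residues[[index]]
  out <- c(phi = NA_real_, psi = NA_real_)
  if (!isTRUE(res$is_amino_acid)) return(out)
  n <- atom_xyz(res, "N"); ca <- atom_xyz(res, "CA"); cc <- atom_xyz(res, "C")
  if (is.null(n) || is.null(ca) || is.null(cc)) return(out)

  if (index > 1L) {
    prev <- chain$residues[[index - 1L]]
    if (isTRUE(prev$is_amino_acid)) {
      cp <- atom_xyz(prev, "C")
      if (!is.null(cp) && sqrt(sum((cp - n)^2)) <= break_distance)
        out["phi"] <- dihedral(cp, n, ca, cc)
    }
  }
  if (index < length(chain$residues)) {
    nxt <- chain$residues[[index + 1L]]
    if (isTRUE(nxt$is_amino_acid)) {
      nn <- atom_xyz(nxt, "N")
      if (!is.null(nn) && sqrt(sum((cc - nn)^2)) <= break_distance)
        out["psi"] <- dihedral(n, ca, cc, nn)
    }
  }
  out
}

#' Construct a Ramachandran probability table
#'
#' A regular periodic grid of backbone-conformation probabilities over
#' (phi, psi). Both axes must tile `[-180, 180)` exactly.
#'
#' @param category one of `"general"`, `"GLY"`, `"PRO"`, `"pre-PRO"`,
#'   `"ILE/VAL"`.
#' @param grid numeric matrix of probabilities in `[0, 1]`; rows index phi,
#'   columns psi.
#' @param phi_origin,psi_origin angle of the first grid node, degrees.
#' @param phi_spacing,psi_spacing node spacing, degrees.
#' @return object of class `RamaTable`.
#' @export
rama_table <- function(category, grid, phi_origin = -180, psi_origin = -180,
                       phi_spacing = 360 / nrow(grid),
                       psi_spacing = 360 / ncol(grid)) {
  stopifnot(is.matrix(grid), all(grid >= 0 & grid <= 1, na.rm = TRUE))
  if (abs(nrow(grid) * phi_spacing - 360) > 1e-6 ||
      abs(ncol(grid) * psi_spacing - 360) > 1e-6)
    stop("RamaTable axes must cover 360 degrees periodically")
  structure(list(category = category, grid = grid,
                 phi_origin = phi_origin, psi_origin = psi_origin,
                 phi_spacing = phi_spacing, psi_spacing = psi_spacing),
            class = "RamaTable")
}

#' Ramachandran probability at (phi, psi)
#'
#' Bilinear interpolation on the periodic probability grid.
#'
#' @param phi,psi backbone torsions in degrees.
#' @param table a `RamaTable`.
#' @return probability in `[0, 1]`; `NA` if either angle is `NA`.
#' @export
rama_probability <- function(phi, psi, table) {
  if (is.na(phi) || is.na(psi)) return(NA_real_)
  g <- table$grid
  np <- nrow(g); ns <- ncol(g)
  u <- (phi - table$phi_origin) / table$phi_spacing
  v <- (psi - table$psi_origin) / table$psi_spacing
  i0 <- floor(u); j0 <- floor(v)
  fu <- u - i0; fv <- v - j0
  i0 <- ((i0 %% np) + np) %% np
  j0 <- ((j0 %% ns) + ns) %% ns
  i1 <- (i0 + 1) %% np
  j1 <- (j0 + 1) %% ns
  val <- g[i0 + 1, j0 + 1] * (1 - fu) * (1 - fv) +
    g[i1 + 1, j0 + 1] * fu * (1 - fv) +
    g[i0 + 1, j1 + 1] * (1 - fu) * fv +
    g[i1 + 1, j1 + 1] * fu * fv
  min(max(val, 0), 1)
}

#' Classify a Ramachandran probability
#'
#' Thresholds follow the convention used by interactive model-building tools:
#' favored at or above `favored_min`, outlier below `allowed_min`, allowed in
#' between. Defaults are configurable because published threshold choices
#' vary.
#'
#' @param p probability in `[0, 1]` (or `NA`).
#' @param thresholds named numeric vector with `favored_min > allowed_min`.
#' @return one of `"favored"`, `"allowed"`, `"outlier"`, `"unknown"`.
#' @export
rama_classify <- function(p, thresholds = c(favored_min = 0.02, allowed_min = 0.002)) {
  stopifnot(thresholds[["favored_min"]] > thresholds[["allowed_min"]])
  if (is.na(p)) return("unknown")
  if (p >= thresholds[["favored_min"]]) return("favored")
  if (p >= thresholds[["allowed_min"]]) return("allowed")
  "outlier"
}

#' Ramachandran category of a residue
#'
#' `GLY` and `PRO` by name, `pre-PRO` when the successor is proline,
#' `ILE/VAL` by name, otherwise `general`.
#'
#' @param resname residue three-letter code.
#' @param next_resname successor residue name or `NA`.
#' @return category string.
#' @export
rama_category <- function(resname, next_resname = NA_character_) {
  resname <- toupper(resname)
  if (resname == "GLY") return("GLY")
  if (resname == "PRO") return("PRO")
  if (!is.na(next_resname) && toupper(next_resname) == "PRO") return("pre-PRO")
  if (resname %in% c("ILE", "VAL")) return("ILE/VAL")
  "general"
}

#' Write / read a Ramachandran table in the plain-text grid format
#'
#' The format is a commented header (`# category:`, `# phi_origin:` etc.)
#' followed by whitespace-separated `phi psi probability` rows.
#'
#' @param table a `RamaTable`.
#' @param path output file.
#' @return `read_rama_table` returns a `RamaTable`; the writer returns the
#'   path invisibly.
#' @export
write_rama_table <- function(table, path) {
  np <- nrow(table$grid); ns <- ncol(table$grid)
  hdr <- c(sprintf("# category: %s", table$category),
           sprintf("# phi_origin: %.6g", table$phi_origin),
           sprintf("# psi_origin: %.6g", table$psi_origin),
           sprintf("# phi_spacing: %.6g", table$phi_spacing),
           sprintf("# psi_spacing: %.6g", table$psi_spacing))
  idx <- expand.grid(i = seq_len(np), j = seq_len(ns))
  rows <- sprintf("%.6g %.6g %.10g",
                  table$phi_origin + (idx$i - 1) * table$phi_spacing,
                  table$psi_origin + (idx$j - 1) * table$psi_spacing,
                  table$grid[cbind(idx$i, idx$j)])
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_rama_table
#' @export
read_rama_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  getv <- function(key) {
    ln <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    if (!length(ln)) stop("RamaTable header missing '", key, "'")
    trimws(sub(paste0("^# ", key, ":"), "", ln[1]))
  }
  dat <- utils::read.table(text = lines[!grepl("^#", lines)],
                           col.names = c("phi", "psi", "p"))
  phi0 <- as.numeric(getv("phi_origin")); psi0 <- as.numeric(getv("psi_origin"))
  dphi <- as.numeric(getv("phi_spacing")); dpsi <- as.numeric(getv("psi_spacing"))
  i <- nint((dat$phi - phi0) / dphi) + 1
  j <- nint((dat$psi - psi0) / dpsi) + 1
  g <- matrix(NA_real_, max(i), max(j))
  g[cbind(i, j)] <- dat$p
  rama_table(getv("category"), g, phi0, psi0, dphi, dpsi)
}
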