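# Electron-density map synthesis from structure factors and real-space
# per-atom / per-residue fit scoring.
#
# The map is synthesized on a periodic grid by inverse Fourier transform of
# the (amplitude, phase) reflection set with Friedel completion. Atom fit
# scores compare the proton-number-normalized density at the atom position
# with the map's global distribution through the standard normal CDF.

# Orthogonalization matrix (fractional -> Cartesian), PDB convention:
# a along x, b in the xy plane.
orth_matrix <- function(cell) {
  a <- cell[1]; b <- cell[2]; c_ <- cell[3]
  al <- deg2rad(cell[4]); be <- deg2rad(cell[5]); ga <- deg2rad(cell[6])
  v <- sqrt(1 - cos(al)^2 - cos(be)^2 - cos(ga)^2 +
              2 * cos(al) * cos(be) * cos(ga))
  matrix(c(a, b * cos(ga), c_ * cos(be),
           0, b * sin(ga), c_ * (cos(al) - cos(be) * cos(ga)) / sin(ga),
           0, 0, c_ * v / sin(ga)),
         nrow = 3, byrow = TRUE)
}

cell_volume <- function(cell) {
  al <- deg2rad(cell[4]); be <- deg2rad(cell[5]); ga <- deg2rad(cell[6])
  v <- sqrt(1 - cos(al)^2 - cos(be)^2 - cos(ga)^2 +
              2 * cos(al) * cos(be) * cos(ga))
  cell[1] * cell[2] * cell[3] * v
}

# Resolution d = 1/|h . A*| for Miller indices; general triclinic via the
# reciprocal of the orthogonalization matrix.
d_spacing <- function(h, k, l, cell) {
  Ainv <- solve(orth_matrix(cell))       # rows are reciprocal axes
  s <- cbind(h, k, l) %*% Ainv
  1 / sqrt(rowSums(s^2))
}

#' Construct a reflection set
#'
#' Structure factors as (amplitude, phase) pairs on Miller indices, with the
#' unit cell they refer to.
#'
#' @param hkl integer matrix (n x 3) of Miller indices; no duplicates.
#' @param f amplitudes, `>= 0`.
#' @param phi phases in degrees.
#' @param cell unit cell `c(a, b, c, alpha, beta, gamma)` (Angstrom, degrees).
#' @param dmin resolution limit in Angstrom; computed from the indices when
#'   omitted.
#' @return object of class `ReflectionSet`.
#' @export
reflection_set <- function(hkl, f, phi, cell, dmin = NULL) {
  hkl <- matrix(as.integer(hkl), ncol = 3)
  stopifnot(nrow(hkl) == length(f), length(f) == length(phi), all(f >= 0))
  key <- paste(hkl[, 1], hkl[, 2], hkl[, 3])
  if (anyDuplicated(key)) stop("duplicate Miller indices in reflection set")
  if (is.null(dmin)) {
    nonzero <- rowSums(abs(hkl)) > 0
    dmin <- if (any(nonzero))
      min(d_spacing(hkl[nonzero, 1], hkl[nonzero, 2], hkl[nonzero, 3], cell))
    else Inf
  }
  structure(list(hkl = hkl, f = as.numeric(f), phi = as.numeric(phi),
                 cell = as.numeric(cell), dmin = dmin),
            class = "ReflectionSet")
}

#' Synthesize a density map from reflections
#'
#' Inverse Fourier synthesis
#' `rho(x) = (1/V) * sum_h F_h exp(-2*pi*i h.x)` on a periodic grid whose
#' spacing is at most `dmin / (2 * sampling)` on every axis. Friedel mates
#' are completed automatically (the input lists each reflection once).
#'
#' @param refl a `ReflectionSet`.
#' @param sampling oversampling factor; the default 1.5 gives grid spacing
#'   `dmin / 3`.
#' @return object of class `DensityMap`: `grid` (3-D array), `cell`, `mean`,
#'   `sd` (population, over all grid samples), and `degenerate` (logical;
#'   constant map).
#' @export
map_from_reflections <- function(refl, sampling = 1.5) {
  stopifnot(inherits(refl, "ReflectionSet"))
  if (nrow(refl$hkl) == 0L) stop("empty reflection set")
  cell <- refl$cell
  dmin <- refl$dmin
  if (!is.finite(dmin)) dmin <- max(cell[1:3]) / 4  # DC-only set: any grid works
  spacing <- dmin / (2 * sampling)
  n <- vapply(cell[1:3], function(len) {
    m <- max(4L, as.integer(ceiling(len / spacing)))
    stats::nextn(m, c(2, 3, 5))
  }, integer(1))
  hmax <- floor((n - 1) / 2)
  if (any(abs(refl$hkl) > matrix(hmax, nrow(refl$hkl), 3, byrow = TRUE)))
    stop("grid too coarse for reflection indices; increase sampling")

  F <- array(complex(real = 0, imaginary = 0), dim = n)
  put <- function(h, val) {
    i <- ((h %% n) + n) %% n + 1L
    F[i[1], i[2], i[3]] <<- val
  }
  for (r in seq_len(nrow(refl$hkl))) {
    h <- refl$hkl[r, ]
    val <- refl$f[r] * exp(1i * deg2rad(refl$phi[r]))
    put(h, val)
    if (any(h != 0)) put(-h, Conj(val))
  }
  # fft(..., inverse = TRUE) sums F[h] exp(+2*pi*i h.k/n); with Friedel pairs
  # present the result is real and equals the cosine synthesis.
  rho <- Re(stats::fft(F, inverse = TRUE)) / cell_volume(cell)
  m <- mean(rho)
  s <- sqrt(mean((rho - m)^2))
  structure(list(grid = rho, cell = as.numeric(cell), mean = m, sd = s,
                 degenerate = s < 1e-12 * max(abs(m), 1)),
            class = "DensityMap")
}

#' Extract structure factors from a map (forward analysis)
#'
#' Inverse of [map_from_reflections()]: returns the (amplitude, phase) of the
#' requested Miller indices from the discrete Fourier transform of the grid.
#'
#' @param map a `DensityMap`.
#' @param hkl integer matrix (n x 3) of Miller indices to extract.
#' @return a `ReflectionSet`.
#' @export
reflections_from_map <- function(map, hkl) {
  hkl <- matrix(as.integer(hkl), ncol = 3)
  n <- dim(map$grid)
  Fg <- stats::fft(map$grid) * cell_volume(map$cell) / prod(n)
  f <- numeric(nrow(hkl)); ph <- numeric(nrow(hkl))
  for (r in seq_len(nrow(hkl))) {
    i <- ((hkl[r, ] %% n) + n) %% n + 1L
    v <- Fg[i[1], i[2], i[3]]
    f[r] <- Mod(v)
    ph[r] <- if (f[r] > 0) wrap180(rad2deg(Arg(v))) else 0
  }
  reflection_set(hkl, f, ph, map$cell)
}

#' Density at a Cartesian position
#'
#' Trilinear interpolation of the 8 enclosing grid nodes after
#' fractionalization, with periodic wrapping.
#'
#' @param map a `DensityMap`.
#' @param position Cartesian 3-vector, Angstrom.
#' @return interpolated density value.
#' @export
density_at <- function(map, position) {
  origin <- map$origin %||% c(0, 0, 0)
  frac <- solve(orth_matrix(map$cell), as.numeric(position) - origin)
  n <- dim(map$grid)
  u <- frac * n
  i0 <- floor(u)
  fu <- u - i0
  i0 <- ((i0 %% n) + n) %% n
  i1 <- (i0 + 1) %% n
  g <- map$grid
  c000 <- g[i0[1] + 1, i0[2] + 1, i0[3] + 1]
  c100 <- g[i1[1] + 1, i0[2] + 1, i0[3] + 1]
  c010 <- g[i0[1] + 1, i1[2] + 1, i0[3] + 1]
  c110 <- g[i1[1] + 1, i1[2] + 1, i0[3] + 1]
  c001 <- g[i0[1] + 1, i0[2] + 1, i1[3] + 1]
  c101 <- g[i1[1] + 1, i0[2] + 1, i1[3] + 1]
  c011 <- g[i0[1] + 1, i1[2] + 1, i1[3] + 1]
  c111 <- g[i1[1] + 1, i1[2] + 1, i1[3] + 1]
  (c000 * (1 - fu[1]) + c100 * fu[1]) * (1 - fu[2]) * (1 - fu[3]) +
    (c010 * (1 - fu[1]) + c110 * fu[1]) * fu[2] * (1 - fu[3]) +
    (c001 * (1 - fu[1]) + c101 * fu[1]) * (1 - fu[2]) * fu[3] +
    (c011 * (1 - fu[1]) + c111 * fu[1]) * fu[2] * fu[3]
}

#' Per-atom density fit score
#'
#' `score = -ln(Phi(z))` with `z = (rho/Z - mu_map)/sigma_map`, `Phi` the
#' standard normal CDF, the probability clamped above machine-tiny before the
#' log. Zero is a perfect fit in the limit; larger is poorer. The map mean
#' and SD refer to the unnormalized density distribution.
#'
#' @param rho density at the atom position.
#' @param proton_number atomic number Z (`>= 1`).
#' @param map_mean,map_sd global map statistics; `map_sd` must be positive.
#' @return non-negative score.
#' @export
atom_fit_score <- function(rho, proton_number, map_mean, map_sd) {
  if (!isTRUE(map_sd > 0)) stop("degenerate map: sd must be positive")
  stopifnot(proton_number >= 1)
  z <- (rho / proton_number - map_mean) / map_sd
  p <- pmax(stats::pnorm(z), .Machine$double.xmin)
  -log(p)
}

# Backbone atom names for the fit-score split; OXT counts as backbone.
.backbone_atoms <- c("N", "CA", "C", "O", "OXT")

#' Per-residue density fit scores
#'
#' Arithmetic mean of atom fit scores over all included atoms, over the
#' backbone subset (N, CA, C, O, OXT), and over the remaining (side-chain)
#' atoms. A subset with no atoms yields `NA`.
#'
#' @param residue a `Residue`.
#' @param map a `DensityMap`.
#' @param include_hydrogens include hydrogens in the aggregation.
#' @return list of class `ResidueFitScores` with `all_atoms`, `backbone`,
#'   `side_chain`.
#' @export
residue_fit_scores <- function(residue, map, include_hydrogens = FALSE) {
  a <- included_atoms(residue, include_hydrogens)
  if (nrow(a) == 0L)
    return(structure(list(all_atoms = NA_real_, backbone = NA_real_,
                          side_chain = NA_real_), class = "ResidueFitScores"))
  scores <- vapply(seq_len(nrow(a)), function(i) {
    atom_fit_score(density_at(map, as.numeric(a[i, c("x", "y", "z")])),
                   a$proton[i], map$mean, map$sd)
  }, numeric(1))
  bb <- a$name %in% .backbone_atoms
  structure(list(
    all_atoms = mean(scores),
    backbone = if (any(bb)) mean(scores[bb]) else NA_real_,
    side_chain = if (any(!bb)) mean(scores[!bb]) else NA_real_
  ), class = "ResidueFitScores")
}

# --- file formats -----------------------------------------------------------

#' Read / write the plain-text reflection dialect
#'
#' Comment header carrying the cell (`# cell: a b c alpha beta gamma`) and
#' optionally `# resolution: d`, then whitespace-separated rows
#' `h k l F phi`.
#'
#' @param path file path.
#' @return a `ReflectionSet` (reader); the path, invisibly (writer).
#' @export
read_reflections_txt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  cl <- grep("^# cell:", lines, value = TRUE)
  if (!length(cl)) stop("reflection file missing '# cell:' header: ", path)
  cell <- as.numeric(strsplit(trimws(sub("^# cell:", "", cl[1])), "\\s+")[[1]])
  rl <- grep("^# resolution:", lines, value = TRUE)
  dmin <- if (length(rl)) as.numeric(trimws(sub("^# resolution:", "", rl[1]))) else NULL
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (!length(body)) stop("reflection file has no data rows: ", path)
  dat <- utils::read.table(text = body, col.names = c("h", "k", "l", "f", "phi"))
  reflection_set(as.matrix(dat[, 1:3]), dat$f, dat$phi, cell, dmin)
}

#' @rdname read_reflections_txt
#' @param refl a `ReflectionSet`.
#' @export
write_reflections_txt <- function(refl, path) {
  hdr <- c(sprintf("# cell: %s", paste(sprintf("%.6g", refl$cell), collapse = " ")),
           sprintf("# resolution: %.6g", refl$dmin))
  rows <- sprintf("%d %d %d %.10g %.10g", refl$hkl[, 1], refl$hkl[, 2],
                  refl$hkl[, 3], refl$f, refl$phi)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read / write CCP4-format map files (minimal subset)
#'
#' Mode-2 (32-bit float) maps with axis order X,Y,Z covering exactly one unit
#' cell, which is what [synthetic_map()] and [map_from_reflections()]
#' produce. Sufficient for exchanging precomputed maps with other tools.
#'
#' @param map a `DensityMap`.
#' @param path file path.
#' @return the path (writer, invisibly) or a `DensityMap` (reader).
#' @export
write_ccp4_map <- function(map, path) {
  n <- dim(map$grid)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(n)                      # NC, NR, NS
  wi(2)                      # MODE 2: float
  wi(c(0, 0, 0))             # start
  wi(n)                      # sampling intervals along cell
  wf(map$cell)               # cell
  wi(c(1, 2, 3))             # MAPC/MAPR/MAPS
  wf(c(min(map$grid), max(map$grid), map$mean))
  wi(1)                      # ISPG (P1)
  wi(0)                      # NSYMBT
  wi(rep(0, 25))             # extra
  wf(map$origin %||% c(0, 0, 0))  # Cartesian origin (words 50-52)
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x41, 0x00, 0x00)), con)  # little-endian stamp
  wf(map$sd)                 # RMS
  wi(0)                      # NLABL
  writeBin(raw(800), con)    # labels
  wf(as.numeric(aperm(map$grid, c(1, 2, 3))))  # column-major = x fastest
  invisible(path)
}

#' @rdname write_ccp4_map
#' @export
read_ccp4_map <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(k) readBin(con, "integer", n = k, size = 4, endian = "little")
  rf <- function(k) readBin(con, "numeric", n = k, size = 4, endian = "little")
  n <- ri(3)
  mode <- ri(1)
  if (mode != 2) stop("unsupported CCP4 map mode: ", mode)
  ri(3); ni <- ri(3)
  cell <- rf(6)
  axes <- ri(3)
  if (!identical(axes, c(1L, 2L, 3L))) stop("unsupported CCP4 axis order")
  rf(3); ispg <- ri(1); nsymbt <- ri(1)
  ri(25); origin <- rf(3)
  magic <- rawToChar(readBin(con, "raw", 4))
  if (magic != "MAP ") stop("not a CCP4 map file: ", path)
  readBin(con, "raw", 4)
  rf(1); ri(1)
  readBin(con, "raw", 800)
  if (nsymbt > 0) readBin(con, "raw", nsymbt)
  vals <- rf(prod(n))
  grid <- array(vals, dim = n)
  m <- mean(grid)
  s <- sqrt(mean((grid - m)^2))
  structure(list(grid = grid, cell = cell, mean = m, sd = s,
                 degenerate = s < 1e-12 * max(abs(m), 1),
                 origin = origin),
            class = "DensityMap")
}
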