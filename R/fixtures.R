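# Seeded generators for every synthetic input the pipeline consumes: models
# built from specified torsions, Gaussian-atom density maps with matching
# reflection sets, and small rotamer/Ramachandran reference libraries with
# known ground truth. All generators are pure functions of their spec.

# Run a block under a private RNG stream without disturbing the caller's.
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(code)
}

#' Fixture specification
#'
#' Bundles every knob of the synthetic-model generator. Identical specs give
#' byte-identical outputs.
#'
#' @param seed integer RNG seed.
#' @param n_chains number of chains (ids A, B, ...).
#' @param n_residues residues per chain.
#' @param torsions `"helix"` (phi -57, psi -47), `"sheet"` (-120, 130),
#'   `"random"`, or a two-column matrix of (phi, psi) rows.
#' @param sequence character vector of three-letter codes (recycled), or
#'   `NULL` for a seeded mix of the supported types.
#' @param chis named list: `chis[[as.character(i)]]` fixes residue i's chi
#'   angles; unlisted residues get seeded staggered/trans values.
#' @param b_base,b_gradient B-factor baseline and per-residue increment.
#' @param b_hotspots list of `list(pos =, delta =)` B-factor bumps.
#' @param displace `list(chain =, pos =, dist =)`: translate one residue by
#'   `dist` Angstrom along x after building.
#' @param resolution nominal resolution written to the REMARK 2 header and
#'   used by the map generator, Angstrom.
#' @param noise_sd white-noise SD added to synthetic maps.
#' @return object of class `FixtureSpec`.
#' @export
fixture_spec <- function(seed = 1, n_chains = 1, n_residues = 10,
                         torsions = "helix", sequence = NULL, chis = list(),
                         b_base = 20, b_gradient = 0, b_hotspots = list(),
                         displace = NULL, resolution = 2.0, noise_sd = 0) {
  structure(list(seed = seed, n_chains = n_chains, n_residues = n_residues,
                 torsions = torsions, sequence = sequence, chis = chis,
                 b_base = b_base, b_gradient = b_gradient,
                 b_hotspots = b_hotspots, displace = displace,
                 resolution = resolution, noise_sd = noise_sd),
            class = "FixtureSpec")
}

# --- internal-coordinate atom placement (NeRF) --------------------------------

# Place atom d bonded to c with |cd| = bond, angle(b,c,d) = angle and
# dihedral(a,b,c,d) = torsion (degrees).
place_atom <- function(a, b, c, bond, angle, torsion) {
  th <- deg2rad(angle); ph <- deg2rad(torsion)
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  nv <- c(ab[2] * bc[3] - ab[3] * bc[2],
          ab[3] * bc[1] - ab[1] * bc[3],
          ab[1] * bc[2] - ab[2] * bc[1])
  nv <- nv / sqrt(sum(nv^2))
  mv <- c(nv[2] * bc[3] - nv[3] * bc[2],
          nv[3] * bc[1] - nv[1] * bc[3],
          nv[1] * bc[2] - nv[2] * bc[1])
  d2 <- c(-bond * cos(th), bond * cos(ph) * sin(th), bond * sin(ph) * sin(th))
  c + cbind(bc, mv, nv) %*% d2
}

# Ideal backbone internal coordinates (Engh & Huber-like values).
.bb <- list(n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
            ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
            ang_ca_c_o = 120.8, omega = 180)

# Side-chain topology: atoms placed in order; refs name backbone/side atoms of
# the same residue; tor is either list(chi = k, offset = o) or a fixed angle.
.sidechain_topo <- list(
  GLY = list(),
  ALA = list(
    list(name = "CB", refs = c("N", "C", "CA"), bond = 1.521, angle = 110.4, tor = 122.6)),
  SER = list(
    list(name = "CB", refs = c("N", "C", "CA"), bond = 1.530, angle = 110.5, tor = 122.6),
    list(name = "OG", refs = c("N", "CA", "CB"), bond = 1.417, angle = 111.1,
         tor = list(chi = 1, offset = 0))),
  VAL = list(
    list(name = "CB", refs = c("N", "C", "CA"), bond = 1.540, angle = 111.5, tor = 123.2),
    list(name = "CG1", refs = c("N", "CA", "CB"), bond = 1.521, angle = 110.5,
         tor = list(chi = 1, offset = 0)),
    list(name = "CG2", refs = c("N", "CA", "CB"), bond = 1.521, angle = 110.5,
         tor = list(chi = 1, offset = 122))),
  LEU = list(
    list(name = "CB", refs = c("N", "C", "CA"), bond = 1.530, angle = 110.4, tor = 122.6),
    list(name = "CG", refs = c("N", "CA", "CB"), bond = 1.530, angle = 116.3,
         tor = list(chi = 1, offset = 0)),
    list(name = "CD1", refs = c("CA", "CB", "CG"), bond = 1.521, angle = 110.7,
         tor = list(chi = 2, offset = 0)),
    list(name = "CD2", refs = c("CA", "CB", "CG"), bond = 1.521, angle = 110.7,
         tor = list(chi = 2, offset = 122))),
  ASP = list(
    list(name = "CB", refs = c("N", "C", "CA"), bond = 1.530, angle = 110.4, tor = 122.6),
    list(name = "CG", refs = c("N", "CA", "CB"), bond = 1.516, angle = 112.6,
         tor = list(chi = 1, offset = 0)),
    list(name = "OD1", refs = c("CA", "CB", "CG"), bond = 1.249, angle = 118.4,
         tor = list(chi = 2, offset = 0)),
    list(name = "OD2", refs = c("CA", "CB", "CG"), bond = 1.249, angle = 118.4,
         tor = list(chi = 2, offset = 180))),
  MET = list(
    list(name = "CB", refs = c("N", "C", "CA"), bond = 1.530, angle = 110.4, tor = 122.6),
    list(name = "CG", refs = c("N", "CA", "CB"), bond = 1.520, angle = 114.1,
         tor = list(chi = 1, offset = 0)),
    list(name = "SD", refs = c("CA", "CB", "CG"), bond = 1.803, angle = 112.7,
         tor = list(chi = 2, offset = 0)),
    list(name = "CE", refs = c("CB", "CG", "SD"), bond = 1.791, angle = 100.2,
         tor = list(chi = 3, offset = 0))),
  LYS = list(
    list(name = "CB", refs = c("N", "C", "CA"), bond = 1.530, angle = 110.4, tor = 122.6),
    list(name = "CG", refs = c("N", "CA", "CB"), bond = 1.520, angle = 114.1,
         tor = list(chi = 1, offset = 0)),
    list(name = "CD", refs = c("CA", "CB", "CG"), bond = 1.520, angle = 111.3,
         tor = list(chi = 2, offset = 0)),
    list(name = "CE", refs = c("CB", "CG", "CD"), bond = 1.520, angle = 111.3,
         tor = list(chi = 3, offset = 0)),
    list(name = "NZ", refs = c("CG", "CD", "CE"), bond = 1.489, angle = 111.9,
         tor = list(chi = 4, offset = 0))),
  PHE = list(
    list(name = "CB", refs = c("N", "C", "CA"), bond = 1.530, angle = 110.4, tor = 122.6),
    list(name = "CG", refs = c("N", "CA", "CB"), bond = 1.502, angle = 113.8,
         tor = list(chi = 1, offset = 0)),
    list(name = "CD1", refs = c("CA", "CB", "CG"), bond = 1.384, angle = 120.8,
         tor = list(chi = 2, offset = 0)),
    list(name = "CD2", refs = c("CA", "CB", "CG"), bond = 1.384, angle = 120.8,
         tor = list(chi = 2, offset = 180)),
    list(name = "CE1", refs = c("CB", "CG", "CD1"), bond = 1.382, angle = 121.0, tor = 180),
    list(name = "CE2", refs = c("CB", "CG", "CD2"), bond = 1.382, angle = 121.0, tor = 180),
    list(name = "CZ", refs = c("CG", "CD1", "CE1"), bond = 1.382, angle = 120.0, tor = 0))
)

# Number of chi torsions the generator can set per supported type.
.fixture_n_chi <- c(GLY = 0, ALA = 0, SER = 1, VAL = 1, LEU = 2, ASP = 2,
                    PHE = 2, MET = 3, LYS = 4)

fixture_torsion_table <- function(spec) {
  n <- spec$n_residues
  if (is.matrix(spec$torsions)) {
    stopifnot(nrow(spec$torsions) == n)
    return(spec$torsions)
  }
  switch(as.character(spec$torsions),
    helix = cbind(phi = rep(-57, n), psi = rep(-47, n)),
    sheet = cbind(phi = rep(-120, n), psi = rep(130, n)),
    random = cbind(phi = stats::runif(n, -175, -45),
                   psi = stats::runif(n, -60, 170)),
    stop("unknown torsion regime: ", spec$torsions))
}

#' Build a synthetic protein model
#'
#' Constructs backbone coordinates from the spec's (phi, psi) torsions with
#' ideal bond lengths and angles (omega fixed trans), places side chains at
#' the specified chi angles for the supported residue types, assigns the
#' B-factor profile, writes a standard PDB file with a REMARK 2 resolution
#' record, and re-reads it so the returned hierarchy is exactly what any
#' consumer of the file sees.
#'
#' @param spec a `FixtureSpec`.
#' @param path output PDB path; a tempfile by default.
#' @return list with `model` (a `StructureModel` re-read from the file, i.e.
#'   at PDB format precision), `model_exact` (the same hierarchy with
#'   full-precision coordinates, for sub-millidegree torsion round-trips),
#'   `path`, `torsions` (list per chain of the (phi, psi) matrix used),
#'   `chis` (list per chain, per residue), and `sequence` (list per chain).
#' @export
synthetic_model <- function(spec, path = tempfile(fileext = ".pdb")) {
  stopifnot(inherits(spec, "FixtureSpec"))
  with_seed(spec$seed, {
    supported <- names(.sidechain_topo)
    n <- spec$n_residues
    chains <- LETTERS[seq_len(spec$n_chains)]
    lines <- c(sprintf("REMARK   2 RESOLUTION.    %.2f ANGSTROMS.", spec$resolution))
    serial <- 0L
    tors_out <- list(); chis_out <- list(); seq_out <- list()
    exact_chains <- list()

    for (ci in seq_along(chains)) {
      seqv <- if (is.null(spec$sequence)) {
        sample(c("ALA", "SER", "LEU", "LYS", "MET", "VAL", "ASP", "PHE", "GLY"),
               n, replace = TRUE)
      } else rep(toupper(spec$sequence), length.out = n)
      if (!all(seqv %in% supported))
        stop("unsupported residue type(s) for the fixture builder: ",
             paste(setdiff(seqv, supported), collapse = ", "))
      tors <- fixture_torsion_table(spec)
      offset <- c(0, 30 * (ci - 1), 0)

      # backbone
      N <- matrix(NA_real_, n, 3); CA <- N; CC <- N; OO <- N
      N[1, ] <- c(0, 0, 0)
      CA[1, ] <- c(.bb$n_ca, 0, 0)
      th <- deg2rad(.bb$ang_n_ca_c)
      CC[1, ] <- CA[1, ] + .bb$ca_c * c(-cos(th), sin(th), 0)
      for (i in seq_len(n - 1)) {
        N[i + 1, ] <- place_atom(N[i, ], CA[i, ], CC[i, ], .bb$c_n,
                                 .bb$ang_ca_c_n, tors[i, 2])
        CA[i + 1, ] <- place_atom(CA[i, ], CC[i, ], N[i + 1, ], .bb$n_ca,
                                  .bb$ang_c_n_ca, .bb$omega)
        CC[i + 1, ] <- place_atom(CC[i, ], N[i + 1, ], CA[i + 1, ], .bb$ca_c,
                                  .bb$ang_n_ca_c, tors[i + 1, 1])
      }
      for (i in seq_len(n))
        OO[i, ] <- place_atom(N[i, ], CA[i, ], CC[i, ], .bb$c_o,
                              .bb$ang_ca_c_o, wrap180(tors[i, 2] + 180))

      # side chains + B factors + PDB records
      chi_list <- vector("list", n)
      exact_res <- vector("list", n)
      for (i in seq_len(n)) {
        rt <- seqv[i]
        nchi <- .fixture_n_chi[[rt]]
        chi <- spec$chis[[as.character(i)]]
        if (is.null(chi) && nchi > 0)
          chi <- sample(c(-60, 60, 180), nchi, replace = TRUE)
        if (nchi > 0) stopifnot(length(chi) == nchi)
        chi_list[[i]] <- if (nchi > 0) wrap180(chi) else numeric(0)

        b <- spec$b_base + spec$b_gradient * (i - 1)
        for (hs in spec$b_hotspots) if (hs$pos == i) b <- b + hs$delta

        pos <- list(N = N[i, ], CA = CA[i, ], C = CC[i, ], O = OO[i, ])
        for (row in .sidechain_topo[[rt]]) {
          tor <- if (is.list(row$tor)) {
            wrap180(chi_list[[i]][row$tor$chi] + row$tor$offset)
          } else row$tor
          pos[[row$name]] <- as.numeric(place_atom(
            pos[[row$refs[1]]], pos[[row$refs[2]]], pos[[row$refs[3]]],
            row$bond, row$angle, tor))
        }

        move <- c(0, 0, 0)
        if (!is.null(spec$displace) &&
            (spec$displace$chain %||% 1) == ci && spec$displace$pos == i)
          move <- c(spec$displace$dist, 0, 0)

        coords <- t(vapply(names(pos), function(an) pos[[an]] + offset + move,
                           numeric(3)))
        for (k in seq_along(pos)) {
          serial <- serial + 1L
          lines <- c(lines, pdb_atom_line(serial, names(pos)[k], rt,
                                          chains[ci], i, coords[k, ], 1.00, b))
        }
        el <- element_from_name(names(pos))
        res <- list(seq_num = i, insertion_code = "", name = rt,
                    atoms = data.frame(
                      name = names(pos), element = el,
                      proton = proton_number(el),
                      x = coords[, 1], y = coords[, 2], z = coords[, 3],
                      b = b, occupancy = 1, altloc = "",
                      stringsAsFactors = FALSE))
        res$is_amino_acid <- is_amino_acid(res)
        class(res) <- "Residue"
        exact_res[[i]] <- res
      }
      lines <- c(lines, sprintf("TER   %5d      %3s %1s%4d", serial + 1L,
                                seqv[n], chains[ci], n))
      serial <- serial + 1L
      tors_out[[chains[ci]]] <- tors
      chis_out[[chains[ci]]] <- chi_list
      seq_out[[chains[ci]]] <- seqv
      exact_chains[[ci]] <- structure(list(chain_id = chains[ci],
                                           residues = exact_res),
                                      class = "Chain")
    }
    lines <- c(lines, "END")
    writeLines(lines, path)
    model_exact <- structure(list(chains = exact_chains,
                                  resolution = spec$resolution,
                                  source_path = "<synthetic>",
                                  include_hydrogens = FALSE,
                                  aa_allow = character()),
                             class = "StructureModel")
    list(model = read_model(path), model_exact = model_exact, path = path,
         torsions = tors_out, chis = chis_out, sequence = seq_out)
  })
}

# Fixed-width PDB ATOM record. Names shorter than 4 characters are indented
# one column per convention.
pdb_atom_line <- function(serial, name, resname, chain, resno, xyz, occ, b) {
  name4 <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
  el <- element_from_name(name)
  sprintf("ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name4, resname, chain, resno, xyz[1], xyz[2], xyz[3], occ, b,
          el)
}

#' Synthesize a density map for a model
#'
#' Sum of per-atom isotropic Gaussians (amplitude proportional to the proton
#' number, width tied to the resolution) sampled on a periodic grid over an
#' orthogonal cell that encloses the model with a margin, plus optional white
#' noise.
#'
#' @param model a `StructureModel`.
#' @param resolution Angstrom; sets grid spacing (`resolution / 3`) and the
#'   Gaussian width (`resolution / 3`).
#' @param noise_sd white-noise standard deviation (density units).
#' @param margin cell padding around the model, Angstrom.
#' @param seed RNG seed for the noise.
#' @return a `DensityMap`.
#' @export
synthetic_map <- function(model, resolution = 2.0, noise_sd = 0, margin = 5,
                          seed = 1) {
  atoms <- do.call(rbind, unlist(lapply(model$chains, function(ch) {
    lapply(ch$residues, function(r) r$atoms[, c("x", "y", "z", "proton")])
  }), recursive = FALSE))
  stopifnot(nrow(atoms) > 0)
  lo <- unname(apply(atoms[, 1:3], 2, min)) - margin
  len <- unname(apply(atoms[, 1:3], 2, max)) - lo + margin
  cell <- c(len, 90, 90, 90)
  spacing <- resolution / 3
  n <- vapply(len, function(l) stats::nextn(max(8L, as.integer(ceiling(l / spacing))),
                                            c(2, 3, 5)), integer(1))
  w <- resolution / 3
  grid <- array(0, dim = n)
  rad <- ceiling(3 * w / (len / n))  # node window per axis

  for (ai in seq_len(nrow(atoms))) {
    frac <- ((as.numeric(atoms[ai, 1:3]) - lo) / len) %% 1
    u <- frac * n
    ij <- lapply(1:3, function(d) nint(u[d]) + (-rad[d]:rad[d]))
    dx <- lapply(1:3, function(d) {
      delta <- (ij[[d]] - u[d]) * len[d] / n[d]
      delta
    })
    gsub1 <- exp(-dx[[1]]^2 / (2 * w^2))
    gsub2 <- exp(-dx[[2]]^2 / (2 * w^2))
    gsub3 <- exp(-dx[[3]]^2 / (2 * w^2))
    blob <- atoms$proton[ai] * (gsub1 %o% gsub2 %o% gsub3)
    idx <- lapply(1:3, function(d) ((ij[[d]] %% n[d]) + n[d]) %% n[d] + 1L)
    grid[idx[[1]], idx[[2]], idx[[3]]] <-
      grid[idx[[1]], idx[[2]], idx[[3]]] + blob
  }
  if (noise_sd > 0)
    grid <- grid + with_seed(seed, array(stats::rnorm(prod(n), 0, noise_sd),
                                         dim = n))
  m <- mean(grid)
  s <- sqrt(mean((grid - m)^2))
  # Cell frame: the map's fractional origin coincides with `lo`, so shift the
  # cell by storing the offset; consumers fractionalize (pos - origin).
  structure(list(grid = grid, cell = cell, mean = m, sd = s,
                 degenerate = s < 1e-12 * max(abs(m), 1), origin = lo),
            class = "DensityMap")
}

#' Enumerate a reflection set from a map
#'
#' Forward-transforms the map and keeps one reflection per Friedel pair down
#' to the requested resolution limit.
#'
#' @param map a `DensityMap`.
#' @param dmin resolution limit, Angstrom.
#' @return a `ReflectionSet`.
#' @export
synthetic_reflections <- function(map, dmin = 2.0) {
  cell <- map$cell
  hmax <- pmin(floor(cell[1:3] / dmin), floor((dim(map$grid) - 1) / 2))
  hkl <- as.matrix(expand.grid(h = -hmax[1]:hmax[1], k = -hmax[2]:hmax[2],
                               l = 0:hmax[3]))
  keep <- hkl[, 3] > 0 | (hkl[, 3] == 0 & (hkl[, 2] > 0 |
                          (hkl[, 2] == 0 & hkl[, 1] >= 0)))
  hkl <- hkl[keep, , drop = FALSE]
  nonzero <- rowSums(abs(hkl)) > 0
  d <- rep(Inf, nrow(hkl))
  d[nonzero] <- d_spacing(hkl[nonzero, 1], hkl[nonzero, 2], hkl[nonzero, 3], cell)
  hkl <- hkl[d >= dmin, , drop = FALSE]
  reflections_from_map(map, hkl)
}

#' Generate synthetic rotamer and Ramachandran reference data
#'
#' Small libraries with planted ground truth: three residue types (SER, LEU,
#' MET; 1, 2, and 3 chi dimensions), each with central-values rotamers and a
#' contour grid whose rotamericity is 5% within 25 degrees of a rotamer
#' center, 1% within 50 degrees, 0.1% inside a planted outlier blob, and
#' unlisted (unknown) elsewhere; plus Ramachandran tables for all five
#' categories with favored basins at the helix (-57, -47) and sheet
#' (-120, 130) positions.
#'
#' @param seed RNG seed (reserved; the reference is deterministic).
#' @param spacing contour-grid node spacing, degrees.
#' @return list with `central_values`, `raw_grids`, `grids` (decompressed
#'   `ContourGrid`s), `library` (the `CompressedLibrary`), and `rama_tables`.
#' @export
synthetic_rotamer_reference <- function(seed = 1, spacing = 10) {
  central_values <- list(
    SER = list(central_values_entry("SER", "p", 62, 10),
               central_values_entry("SER", "m", -65, 10),
               central_values_entry("SER", "t", 180, 12)),
    LEU = list(central_values_entry("LEU", "mt", c(-65, 175), c(10, 10)),
               central_values_entry("LEU", "tp", c(177, 65), c(10, 10))),
    MET = list(central_values_entry("MET", "mmm", c(-65, -65, -70), c(10, 10, 10)),
               central_values_entry("MET", "ttt", c(180, 180, 180), c(12, 12, 12)))
  )
  outlier_blob <- list(SER = matrix(120, 1), LEU = matrix(c(100, -100), 1),
                       MET = matrix(c(100, -100, 100), 1))
  size <- as.integer(360 / spacing)
  axes <- seq(-180, 180 - spacing, by = spacing)

  raw_grids <- list()
  for (rt in names(central_values)) {
    nd <- length(central_values[[rt]][[1]]$chi_means)
    nodes <- as.matrix(do.call(expand.grid, replicate(nd, axes, simplify = FALSE)))
    colnames(nodes) <- NULL
    centers <- do.call(rbind, lapply(central_values[[rt]], `[[`, "chi_means"))
    # per-node min angular distance to any rotamer center / outlier blob
    node_min <- function(centers) {
      d <- matrix(Inf, nrow(nodes), nrow(centers))
      for (k in seq_len(nrow(centers))) {
        dd <- 0
        for (cdim in seq_len(ncol(nodes)))
          dd <- dd + wrap_diff(nodes[, cdim] - centers[k, cdim])^2
        d[, k] <- sqrt(dd)
      }
      do.call(pmin, asplit(d, 2))
    }
    dc <- node_min(centers)
    db <- node_min(outlier_blob[[rt]])
    val <- rep(NA_real_, nrow(nodes))
    val[dc <= 50] <- 1.0
    val[dc <= 25] <- 5.0
    val[db <= 25 & is.na(val)] <- 0.1
    listed <- !is.na(val)
    raw_grids[[rt]] <- list(coords = nodes[listed, , drop = FALSE],
                            values = val[listed],
                            axis_origins = rep(-180, nd),
                            axis_spacings = rep(spacing, nd),
                            axis_sizes = rep(size, nd))
  }
  lib <- compress_library(raw_grids)
  grids <- decompress_library(lib)

  mk_rama <- function(category) {
    sp <- 5
    ax <- seq(-180, 180 - sp, by = sp)
    g <- outer(ax, ax, function(phi, psi) {
      b1 <- exp(-(wrap_diff(phi + 57)^2 + wrap_diff(psi + 47)^2) / (2 * 25^2))
      b2 <- exp(-(wrap_diff(phi + 120)^2 + wrap_diff(psi - 130)^2) / (2 * 25^2))
      pmin(0.6 * (b1 + b2), 1)
    })
    rama_table(category, g, -180, -180, sp, sp)
  }
  rama_tables <- lapply(stats::setNames(nm = c("general", "GLY", "PRO",
                                               "pre-PRO", "ILE/VAL")), mk_rama)

  list(central_values = central_values, raw_grids = raw_grids, grids = grids,
       library = lib, rama_tables = rama_tables)
}

#' Synthetic percentile-library training records
#'
#' Draws plausible per-residue metric values (log-normal B-factors and fit
#' scores, beta-distributed backbone probabilities) at resolutions spread
#' over 0.8-5.0 Angstrom, for exercising the percentile library away from any
#' real corpus.
#'
#' @param seed RNG seed.
#' @param n records per metric.
#' @return data frame with columns `metric`, `value`, `resolution`.
#' @export
synthetic_percentile_records <- function(seed = 1, n = 2000) {
  with_seed(seed, {
    res <- stats::runif(n, 0.8, 5.0)
    mk <- function(metric, value) data.frame(metric = metric, value = value,
                                             resolution = res)
    rbind(
      mk("b_mean", stats::rlnorm(n, log(25 + 8 * res), 0.4)),
      mk("b_max", stats::rlnorm(n, log(35 + 10 * res), 0.4)),
      mk("fit_all", stats::rlnorm(n, log(0.5 + 0.15 * res), 0.5)),
      mk("fit_side", stats::rlnorm(n, log(0.6 + 0.18 * res), 0.55)),
      mk("rama_prob", stats::rbeta(n, 2, 1.2)),
      mk("rot_score", stats::rlnorm(n, log(1.2), 0.6))
    )
  })
}
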