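# Side-chain conformation scoring and classification.
#
# Two complementary routes, mirroring how rotamer reference data is published:
# a continuous score computed from per-rotamer "central values" (chi means and
# SDs), and a discrete favored/allowed/outlier/unknown classification looked
# up in a flattened contour grid over chi space. The contour grids are stored
# bit-packed (2 bits per lattice point, four points per byte) and
# gzip-compressed; this module also implements the compressor.

# Classification states stored on the lattice.
.rot_states <- c("unknown", "outlier", "allowed", "favored")

# Rotamericity (%) thresholds shared with the discrete classification:
# at or below `outlier_max` -> outlier, at or above `favored_min` -> favored.
.rot_thresholds <- c(outlier_max = 0.3, favored_min = 2.0)

rotamer_state_of <- function(value,
                             outlier_max = .rot_thresholds[["outlier_max"]],
                             favored_min = .rot_thresholds[["favored_min"]]) {
  ifelse(value <= outlier_max, 1L, ifelse(value >= favored_min, 3L, 2L))
}

#' Central-values entry for one rotamer
#'
#' @param residue_type three-letter code.
#' @param rotamer_name label, e.g. `"mt"`.
#' @param chi_means,chi_sds equal-length numeric vectors, degrees; all SDs
#'   must be positive.
#' @return object of class `CentralValuesEntry`.
#' @export
central_values_entry <- function(residue_type, rotamer_name, chi_means, chi_sds) {
  stopifnot(length(chi_means) == length(chi_sds), length(chi_means) >= 1,
            all(chi_sds > 0))
  structure(list(residue_type = toupper(residue_type),
                 rotamer_name = rotamer_name,
                 chi_means = as.numeric(chi_means),
                 chi_sds = as.numeric(chi_sds)),
            class = "CentralValuesEntry")
}

# Terminal-chi periods for side chains with two-fold symmetric end groups.
.chi_periods_special <- list(
  ASP = c(360, 180), GLU = c(360, 360, 180),
  PHE = c(360, 180), TYR = c(360, 180)
)

chi_periods <- function(residue_type, n_chi) {
  p <- .chi_periods_special[[toupper(residue_type)]]
  if (is.null(p) || length(p) != n_chi) rep(360, n_chi) else p
}

#' Continuous rotamer score
#'
#' Models each chi dimension of each recognized rotamer as a Gaussian,
#' computes the z-score in every dimension, takes the quadratic mean
#' (root-mean-square) across dimensions, and returns the minimum over
#' rotamers. Zero means the side chain sits exactly on a rotamer's central
#' values; larger is worse. Angle differences are wrapped to the shortest
#' arc (period 360, or 180 for the terminal chi of two-fold symmetric side
#' chains).
#'
#' @param chis measured chi angles, degrees.
#' @param entries list of `CentralValuesEntry` for the residue type.
#' @return non-negative score, or an object of class `chi_mismatch` (flagged
#'   error record) when the chi count does not match the entries.
#' @export
rotamer_score <- function(chis, entries) {
  stopifnot(length(entries) >= 1)
  n <- length(chis)
  bad <- vapply(entries, function(e) length(e$chi_means) != n, logical(1))
  if (any(bad)) {
    return(structure(list(n_given = n,
                          n_expected = length(entries[[1]]$chi_means),
                          residue_type = entries[[1]]$residue_type),
                     class = "chi_mismatch"))
  }
  per <- chi_periods(entries[[1]]$residue_type, n)
  scores <- vapply(entries, function(e) {
    z <- wrap_diff(chis - e$chi_means, period = per) / e$chi_sds
    sqrt(mean(z^2))
  }, numeric(1))
  min(scores)
}

#' Contour grid over chi space
#'
#' A flattened regular lattice of classification states. The flat layout is
#' row-major in the chi dimensions: the last chi varies fastest, so the index
#' of a lattice coordinate `(i_1, ..., i_N)` (0-based) is
#' `sum_n i_n * prod_{m>n} size_m`.
#'
#' @param residue_type three-letter code.
#' @param axis_origins first node angle per chi dimension, degrees.
#' @param axis_spacings node spacing per dimension, degrees (uniform).
#' @param axis_sizes number of nodes per dimension.
#' @param values integer vector of states 0..3 (`unknown`, `outlier`,
#'   `allowed`, `favored`), length `prod(axis_sizes)`.
#' @return object of class `ContourGrid`.
#' @export
contour_grid <- function(residue_type, axis_origins, axis_spacings, axis_sizes,
                         values) {
  n <- length(axis_sizes)
  stopifnot(length(axis_origins) == n, length(axis_spacings) == n,
            length(values) == prod(axis_sizes),
            all(values >= 0 & values <= 3))
  structure(list(residue_type = toupper(residue_type), n_dims = n,
                 axis_origins = as.numeric(axis_origins),
                 axis_spacings = as.numeric(axis_spacings),
                 axis_sizes = as.integer(axis_sizes),
                 values = as.integer(values)),
            class = "ContourGrid")
}

#' Flat index of a chi-space coordinate
#'
#' Maps chi angles to the nearest lattice node per dimension (nearest-integer
#' rounding, halves away from zero), wraps periodically into the axis range,
#' and flattens row-major (last dimension fastest). The returned index is
#' 0-based, matching the flat layout of `ContourGrid$values` offset by one.
#'
#' @param chis chi angles, degrees; length `grid$n_dims`.
#' @param grid a `ContourGrid`.
#' @return integer in `[0, prod(axis_sizes))`.
#' @export
grid_index <- function(chis, grid) {
  stopifnot(length(chis) == grid$n_dims)
  i <- nint((chis - grid$axis_origins) / grid$axis_spacings)
  i <- ((i %% grid$axis_sizes) + grid$axis_sizes) %% grid$axis_sizes
  sizes <- grid$axis_sizes
  mult <- rev(cumprod(rev(c(sizes[-1], 1))))
  as.integer(sum(i * mult))
}

#' Discrete rotamer classification
#'
#' Looks up the state stored at the nearest lattice node.
#'
#' @inheritParams grid_index
#' @return one of `"favored"`, `"allowed"`, `"outlier"`, `"unknown"`.
#' @export
classify_rotamer <- function(chis, grid) {
  .rot_states[grid$values[grid_index(chis, grid) + 1L] + 1L]
}

# --- bit packing ------------------------------------------------------------

# Point j (0-based) occupies bits 2*(j mod 4) .. 2*(j mod 4)+1 of byte
# floor(j/4), little-end-first within the byte.
pack_states <- function(states) {
  n <- length(states)
  pad <- (4 - n %% 4) %% 4
  s <- c(as.integer(states), rep(0L, pad))
  m <- matrix(s, nrow = 4)
  as.raw(m[1, ] + m[2, ] * 4L + m[3, ] * 16L + m[4, ] * 64L)
}

unpack_states <- function(bytes, n_points) {
  v <- as.integer(bytes)
  s <- rbind(v %% 4L, (v %/% 4L) %% 4L, (v %/% 16L) %% 4L, (v %/% 64L) %% 4L)
  out <- as.integer(s)[seq_len(n_points)]
  out
}

# --- library compression ----------------------------------------------------

#' Build a compressed rotamer classification library
#'
#' Takes, per residue type, a sparse set of lattice coordinates with raw
#' rotamericity values (%), thresholds each value into a 2-bit state
#' (`<= 0.3` outlier, `>= 2.0` favored, between allowed), fills unlisted
#' lattice points with the `unknown` state, flattens row-major, packs four
#' states per byte, and gzips the concatenated payload.
#'
#' @param raw_grids named list (by residue type); each element a list with
#'   `coords` (numeric matrix, one row per listed point, degrees), `values`
#'   (rotamericity %, same row count), `axis_origins`, `axis_spacings`,
#'   `axis_sizes`.
#' @param outlier_max,favored_min classification thresholds in rotamericity %.
#' @return object of class `CompressedLibrary`: header (per-type axis
#'   metadata with byte offsets) plus a single gzip payload.
#' @export
compress_library <- function(raw_grids,
                             outlier_max = .rot_thresholds[["outlier_max"]],
                             favored_min = .rot_thresholds[["favored_min"]]) {
  stopifnot(length(raw_grids) >= 1, !is.null(names(raw_grids)))
  header <- list()
  packed <- list()
  offset <- 0L
  for (rt in names(raw_grids)) {
    rg <- raw_grids[[rt]]
    sizes <- as.integer(rg$axis_sizes)
    ndim <- length(sizes)
    coords <- rg$coords
    if (is.null(dim(coords))) coords <- matrix(coords, ncol = ndim)
    states <- rep(0L, prod(sizes))
    if (nrow(coords) > 0) {
      idx <- numeric(nrow(coords))
      mult <- rev(cumprod(rev(c(sizes[-1], 1))))
      for (r in seq_len(nrow(coords))) {
        u <- (coords[r, ] - rg$axis_origins) / rg$axis_spacings
        if (any(abs(u - nint(u)) > 1e-6))
          stop("off-lattice coordinate for ", rt, ": (",
               paste(coords[r, ], collapse = ", "), ")")
        i <- nint(u)
        if (any(i < 0 | i >= sizes))
          stop("off-lattice coordinate for ", rt, ": (",
               paste(coords[r, ], collapse = ", "), ") outside declared axes")
        idx[r] <- sum(i * mult)
      }
      states[idx + 1L] <- rotamer_state_of(rg$values, outlier_max, favored_min)
    }
    bytes <- pack_states(states)
    header[[rt]] <- list(residue_type = rt, n_dims = ndim,
                         axis_origins = as.numeric(rg$axis_origins),
                         axis_spacings = as.numeric(rg$axis_spacings),
                         axis_sizes = sizes,
                         n_points = prod(sizes),
                         byte_offset = offset, n_bytes = length(bytes))
    packed[[rt]] <- bytes
    offset <- offset + length(bytes)
  }
  structure(list(format = "RTLB1",
                 bit_order = "little-end-first",
                 thresholds = c(outlier_max = outlier_max,
                                favored_min = favored_min),
                 header = header,
                 payload = memCompress(do.call(c, packed), type = "gzip")),
            class = "CompressedLibrary")
}

#' Decompress a rotamer classification library
#'
#' Exact inverse of [compress_library()]'s packing: gunzips the payload and
#' unpacks each residue type's 2-bit states into a `ContourGrid`.
#'
#' @param lib a `CompressedLibrary`.
#' @return named list of `ContourGrid`, one per residue type.
#' @export
decompress_library <- function(lib) {
  stopifnot(inherits(lib, "CompressedLibrary"))
  bytes <- tryCatch(memDecompress(lib$payload, type = "gzip"),
                    error = function(e) stop("corrupt rotamer library payload: ",
                                             conditionMessage(e)))
  out <- list()
  for (rt in names(lib$header)) {
    h <- lib$header[[rt]]
    span <- h$byte_offset + seq_len(h$n_bytes)
    if (max(span) > length(bytes))
      stop("truncated rotamer library payload for residue type ", rt)
    out[[rt]] <- contour_grid(rt, h$axis_origins, h$axis_spacings,
                              h$axis_sizes,
                              unpack_states(bytes[span], h$n_points))
  }
  out
}

# --- on-disk formats --------------------------------------------------------

#' Write / read the compressed library file
#'
#' Layout: 5 magic bytes `"RTLB\\x01"`, a 4-byte little-endian header length,
#' the JSON header (types, axis metadata, byte offsets, bit order,
#' thresholds), then the gzip payload.
#'
#' @param lib a `CompressedLibrary`.
#' @param path file path.
#' @return the path (writer, invisibly) or a `CompressedLibrary` (reader).
#' @export
write_rotamer_library <- function(lib, path) {
  hdr <- charToRaw(jsonlite::toJSON(
    list(bit_order = lib$bit_order, thresholds = as.list(lib$thresholds),
         header = lib$header),
    auto_unbox = TRUE, digits = NA))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("RTLB"), as.raw(1L)), con)
  writeBin(length(hdr), con, size = 4, endian = "little")
  writeBin(hdr, con)
  writeBin(lib$payload, con)
  invisible(path)
}

#' @rdname write_rotamer_library
#' @export
read_rotamer_library <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 9 || rawToChar(raw[1:4]) != "RTLB")
    stop("not a rotamer library file: ", path)
  hlen <- readBin(raw[6:9], "integer", size = 4, endian = "little")
  hdr <- jsonlite::fromJSON(rawToChar(raw[9 + seq_len(hlen)]),
                            simplifyDataFrame = FALSE)
  header <- lapply(hdr$header, function(h) {
    h$axis_sizes <- as.integer(unlist(h$axis_sizes))
    h$axis_origins <- as.numeric(unlist(h$axis_origins))
    h$axis_spacings <- as.numeric(unlist(h$axis_spacings))
    h
  })
  structure(list(format = "RTLB1", bit_order = hdr$bit_order,
                 thresholds = unlist(hdr$thresholds),
                 header = header,
                 payload = raw[(9 + hlen + 1):length(raw)]),
            class = "CompressedLibrary")
}

#' Read / write raw contour grids in the text column format
#'
#' One file per residue type: comment header (`# residue_type:`,
#' `# axis_origins:`, `# axis_spacings:`, `# axis_sizes:`) then rows of
#' `chi_1 ... chi_N rotamericity`.
#'
#' @param path file path.
#' @return a list suitable as one element of `compress_library()`'s
#'   `raw_grids` argument, named with its residue type.
#' @export
read_raw_contour_grid <- function(path) {
  lines <- readLines(path, warn = FALSE)
  getv <- function(key) {
    ln <- grep(paste0("^# ", key, ":"), lines, value = TRUE)
    if (!length(ln)) stop("contour grid header missing '", key, "'")
    trimws(sub(paste0("^# ", key, ":"), "", ln[1]))
  }
  rt <- getv("residue_type")
  origins <- as.numeric(strsplit(getv("axis_origins"), "\\s+")[[1]])
  spacings <- as.numeric(strsplit(getv("axis_spacings"), "\\s+")[[1]])
  sizes <- as.integer(strsplit(getv("axis_sizes"), "\\s+")[[1]])
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  dat <- if (length(body)) {
    as.matrix(utils::read.table(text = body))
  } else matrix(numeric(), 0, length(sizes) + 1)
  out <- list(list(coords = dat[, seq_along(sizes), drop = FALSE],
                   values = dat[, length(sizes) + 1],
                   axis_origins = origins, axis_spacings = spacings,
                   axis_sizes = sizes))
  names(out) <- rt
  out
}

#' @rdname read_raw_contour_grid
#' @param raw one element of a `raw_grids` list (with `coords`, `values`,
#'   axis metadata).
#' @param residue_type three-letter code written into the header.
#' @export
write_raw_contour_grid <- function(raw, residue_type, path) {
  hdr <- c(sprintf("# residue_type: %s", residue_type),
           sprintf("# axis_origins: %s", paste(raw$axis_origins, collapse = " ")),
           sprintf("# axis_spacings: %s", paste(raw$axis_spacings, collapse = " ")),
           sprintf("# axis_sizes: %s", paste(raw$axis_sizes, collapse = " ")))
  coords <- raw$coords
  if (is.null(dim(coords))) coords <- matrix(coords, ncol = length(raw$axis_sizes))
  rows <- vapply(seq_len(nrow(coords)), function(r) {
    paste(c(sprintf("%.6g", coords[r, ]), sprintf("%.10g", raw$values[r])),
          collapse = " ")
  }, character(1))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read / write central-values tables
#'
#' Text format: comment lines allowed; data rows are
#' `residue_type rotamer_name N mean_1 sd_1 ... mean_N sd_N`.
#'
#' @param path file path.
#' @return named list (by residue type) of lists of `CentralValuesEntry`.
#' @export
read_central_values <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  out <- list()
  for (ln in lines) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    n <- as.integer(f[3])
    mu <- as.numeric(f[3 + 2 * seq_len(n) - 1])
    sd <- as.numeric(f[3 + 2 * seq_len(n)])
    e <- central_values_entry(f[1], f[2], mu, sd)
    out[[e$residue_type]] <- c(out[[e$residue_type]], list(e))
  }
  out
}

#' @rdname read_central_values
#' @param central_values named list of lists of `CentralValuesEntry`.
#' @export
write_central_values <- function(central_values, path) {
  rows <- unlist(lapply(central_values, function(entries) {
    vapply(entries, function(e) {
      paste(c(e$residue_type, e$rotamer_name, length(e$chi_means),
              sprintf("%.6g", as.vector(rbind(e$chi_means, e$chi_sds)))),
            collapse = " ")
    }, character(1))
  }), use.names = FALSE)
  writeLines(rows, path)
  invisible(path)
}
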