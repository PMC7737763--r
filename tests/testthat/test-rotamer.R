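# Continuous rotamer scoring, the flattened contour-grid index, and the
# 2-bit packed compressed library.

test_that("rotamer score is zero at a rotamer's central values", {
  e <- central_values_entry("SER", "m", -65, 10)
  expect_equal(rotamer_score(-65, list(e)), 0)
  e2 <- central_values_entry("LEU", "mt", c(-65, 175), c(8, 11))
  expect_equal(rotamer_score(c(-65, 175), list(e2)), 0)
})

test_that("a one-sigma single-chi displacement scores exactly 1", {
  e <- central_values_entry("SER", "m", -65, 10)
  expect_equal(rotamer_score(-55, list(e)), 1.0)
  expect_equal(rotamer_score(-75, list(e)), 1.0)
})

test_that("score is the minimum quadratic mean over rotamers", {
  # brute-force oracle: per-rotamer RMS z-scores computed directly
  entries <- list(central_values_entry("LEU", "r1", c(-60, 170), c(10, 10)),
                  central_values_entry("LEU", "r2", c(65, 85), c(12, 9)))
  chis <- c(-45, 150)
  oracle <- min(vapply(entries, function(e) {
    z <- chainview:::wrap_diff(chis - e$chi_means) / e$chi_sds
    sqrt(mean(z^2))
  }, numeric(1)))
  expect_equal(rotamer_score(chis, entries), oracle)
  # permutation invariance
  expect_equal(rotamer_score(chis, rev(entries)), oracle)
})

test_that("angle differences wrap across the -180/180 seam", {
  e <- central_values_entry("SER", "t", 175, 10)
  expect_equal(rotamer_score(-175, list(e)), 1.0)  # wrapped difference is 10
})

test_that("score is non-negative and zero only on an exact match", {
  set.seed(31)
  for (k in 1:20) {
    n <- sample(1:4, 1)
    entries <- lapply(1:2, function(i)
      central_values_entry("LYS", paste0("r", i), runif(n, -180, 180),
                           runif(n, 5, 20)))
    chis <- runif(n, -180, 180)
    s <- rotamer_score(chis, entries)
    expect_gte(s, 0)
    expect_equal(rotamer_score(entries[[1]]$chi_means, entries), 0)
  }
})

test_that("chi count mismatches come back as flagged records, not errors", {
  e <- central_values_entry("LEU", "mt", c(-65, 175), c(10, 10))
  out <- rotamer_score(-65, list(e))
  expect_s3_class(out, "chi_mismatch")
})

test_that("grid_index maps the origin to zero and matches brute-force enumeration", {
  g <- contour_grid("LEU", c(-180, -180), c(90, 72), c(4, 5), rep(1, 20))
  expect_equal(grid_index(c(-180, -180), g), 0L)
  # node coordinates (2, 3) (0-based) in a 4x5 grid -> flat index 13
  expect_equal(brute_grid_index(c(2, 3), c(4, 5)), 13L)
  expect_equal(grid_index(c(-180 + 2 * 90, -180 + 3 * 72), g), 13L)
})

test_that("chi angles one full period above the origin reuse the origin node", {
  g <- contour_grid("SER", -180, 10, 36, rep(2, 36))
  expect_equal(grid_index(-180 + 36 * 10, g), grid_index(-180, g))
  g2 <- contour_grid("LEU", c(-180, -180), c(10, 10), c(36, 36), rep(2, 36^2))
  expect_equal(grid_index(c(-180 + 360, 40), g2), grid_index(c(-180, 40), g2))
})

test_that("grid_index is a bijection onto the flat range (random small grids)", {
  set.seed(100)
  for (trial in 1:40) {
    nd <- sample(1:4, 1)
    sizes <- sample(2:6, nd, replace = TRUE)
    spacing <- 360 / sizes
    g <- contour_grid("XXX", rep(-180, nd), spacing, sizes,
                      rep(0, prod(sizes)))
    lattice <- as.matrix(expand.grid(rev(lapply(sizes, function(s) 0:(s - 1)))))
    lattice <- lattice[, rev(seq_len(nd)), drop = FALSE]
    idx <- apply(lattice, 1, function(ids) {
      grid_index(-180 + ids * spacing, g)
    })
    expect_equal(idx, seq_len(prod(sizes)) - 1L)  # row-major bijection
  }
})

test_that("classification states map onto the named classes", {
  g <- contour_grid("SER", -180, 90, 4, c(3L, 0L, 1L, 2L))
  expect_equal(classify_rotamer(-180, g), "favored")
  expect_equal(classify_rotamer(-90, g), "unknown")
  expect_equal(classify_rotamer(0, g), "outlier")
  expect_equal(classify_rotamer(90, g), "allowed")
})

test_that("bit packing stores four states per byte, little-end-first", {
  expect_equal(chainview:::pack_states(c(3, 3, 3, 3)), as.raw(0xFF))
  # fully favored 2x2 grid -> one byte 0b11111111
  raw <- list(G = list(coords = as.matrix(expand.grid(c(-180, 0), c(-180, 0))),
                       values = rep(5, 4), axis_origins = c(-180, -180),
                       axis_spacings = c(180, 180), axis_sizes = c(2, 2)))
  lib <- compress_library(raw)
  expect_equal(memDecompress(lib$payload, type = "gzip"), as.raw(0xFF))
  # byte 0b00011011 decodes, little-end-first, to states [3, 2, 1, 0]
  expect_equal(chainview:::unpack_states(as.raw(0x1B), 4), c(3L, 2L, 1L, 0L))
  # packed footprint is exactly ceil(n/4) bytes
  for (n in c(1, 4, 5, 17, 64)) {
    states <- rep_len(c(0L, 1L, 2L, 3L), n)
    expect_length(chainview:::pack_states(states), ceiling(n / 4))
    expect_equal(chainview:::unpack_states(chainview:::pack_states(states), n),
                 states)
  }
})

test_that("compression thresholds split rotamericity at 0.3 and 2.0 percent", {
  vals <- c(0.05, 0.3, 0.31, 1.99, 2.0, 3.5)
  raw <- list(T1 = list(coords = matrix(-180 + (0:5) * 60, ncol = 1),
                        values = vals, axis_origins = -180,
                        axis_spacings = 60, axis_sizes = 6))
  g <- decompress_library(compress_library(raw))$T1
  got <- vapply(0:5, function(i) classify_rotamer(-180 + i * 60, g), "")
  expect_equal(got, c("outlier", "outlier", "allowed", "allowed",
                      "favored", "favored"))
})

test_that("unlisted lattice points decode to the unknown state", {
  raw <- list(T1 = list(coords = matrix(c(-180, 0), ncol = 1),
                        values = c(5, 0.1), axis_origins = -180,
                        axis_spacings = 90, axis_sizes = 4))
  g <- decompress_library(compress_library(raw))$T1
  expect_equal(g$values, c(3L, 0L, 1L, 0L))
})

test_that("compress/decompress is the identity on states", {
  for (seed in 1:10) {
    raw <- random_raw_library(seed)
    lib <- compress_library(raw)
    grids <- decompress_library(lib)
    for (rt in names(raw)) {
      rg <- raw[[rt]]
      expected <- rep(0L, prod(rg$axis_sizes))
      for (r in seq_len(nrow(rg$coords))) {
        idx <- grid_index(rg$coords[r, ], grids[[rt]])
        expected[idx + 1L] <- chainview:::rotamer_state_of(rg$values[r])
      }
      expect_equal(grids[[rt]]$values, expected)
    }
  }
})

test_that("classification of compressed data equals direct thresholding", {
  for (seed in 21:25) {
    raw <- random_raw_library(seed, n_types = 1)
    rt <- names(raw)[1]
    grids <- decompress_library(compress_library(raw))
    rg <- raw[[rt]]
    for (r in seq_len(nrow(rg$coords))) {
      v <- rg$values[r]
      direct <- if (v <= 0.3) "outlier" else if (v >= 2.0) "favored" else "allowed"
      expect_equal(classify_rotamer(rg$coords[r, ], grids[[rt]]), direct)
    }
  }
})

test_that("off-lattice coordinates abort the library build with the offender", {
  raw <- list(T1 = list(coords = matrix(-179, ncol = 1), values = 1,
                        axis_origins = -180, axis_spacings = 90,
                        axis_sizes = 4))
  expect_error(compress_library(raw), "off-lattice.*-179")
})

test_that("truncated payloads fail loudly, naming the residue type", {
  raw <- random_raw_library(3)
  lib <- compress_library(raw)
  bytes <- memDecompress(lib$payload, type = "gzip")
  lib$payload <- memCompress(bytes[-length(bytes)], type = "gzip")
  expect_error(decompress_library(lib), "truncated.*TY")
})

test_that("the compressed library file round-trips", {
  raw <- random_raw_library(8, n_types = 3)
  lib <- compress_library(raw)
  path <- withr::local_tempfile(fileext = ".rtlb")
  write_rotamer_library(lib, path)
  lib2 <- read_rotamer_library(path)
  g1 <- decompress_library(lib)
  g2 <- decompress_library(lib2)
  expect_equal(names(g2), names(g1))
  for (rt in names(g1)) expect_equal(g2[[rt]], g1[[rt]])
  expect_error(read_rotamer_library(fixture_path_bad <- {
    p <- withr::local_tempfile(); writeLines("junk", p); p
  }), "not a rotamer library")
})

test_that("raw contour grids and central values round-trip as text", {
  raw <- random_raw_library(12, n_types = 1)
  rt <- names(raw)[1]
  path <- withr::local_tempfile(fileext = ".txt")
  write_raw_contour_grid(raw[[rt]], rt, path)
  raw2 <- read_raw_contour_grid(path)
  expect_equal(names(raw2), rt)
  expect_equal(decompress_library(compress_library(raw2))[[rt]],
               decompress_library(compress_library(raw))[[rt]])

  cv <- test_refdata$central_values
  path2 <- withr::local_tempfile(fileext = ".txt")
  write_central_values(cv, path2)
  cv2 <- read_central_values(path2)
  expect_equal(names(cv2), names(cv))
  expect_equal(cv2$LEU[[1]]$chi_means, cv$LEU[[1]]$chi_means)
  expect_equal(cv2$MET[[2]]$chi_sds, cv$MET[[2]]$chi_sds)
})
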