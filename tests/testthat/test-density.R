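# Map synthesis, interpolation, and the real-space fit score.

p1_cell <- c(20, 16, 12, 90, 90, 90)

test_that("a DC-only synthesis gives a constant, degenerate map", {
  refl <- reflection_set(matrix(c(0, 0, 0), 1), f = 100, phi = 0,
                         cell = p1_cell)
  map <- map_from_reflections(refl)
  expect_true(map$degenerate)
  expect_lt(diff(range(map$grid)), 1e-9 * max(abs(map$grid)))
})

test_that("a single (1,0,0) cosine wave peaks at x = 0", {
  refl <- reflection_set(matrix(c(1, 0, 0), 1), f = 1, phi = 0,
                         cell = p1_cell, dmin = 2)
  map <- map_from_reflections(refl)
  expect_equal(map$grid[1, 1, 1], max(map$grid))
  # and the mean of a synthesis without the (0,0,0) term is zero
  expect_equal(map$mean, 0, tolerance = 1e-12)
})

test_that("synthesis then analysis recovers amplitudes and phases", {
  set.seed(4)
  hkl <- unique(matrix(sample(-3:3, 60, replace = TRUE), ncol = 3))
  hkl <- hkl[rowSums(abs(hkl)) > 0, , drop = FALSE]
  # keep one reflection per Friedel pair
  key <- apply(hkl, 1, paste, collapse = ",")
  mate <- apply(-hkl, 1, paste, collapse = ",")
  hkl <- hkl[!(mate %in% key) | key < mate, , drop = FALSE]
  f <- runif(nrow(hkl), 0.5, 5)
  phi <- runif(nrow(hkl), -180, 180)
  refl <- reflection_set(hkl, f, phi, p1_cell, dmin = 2)
  map <- map_from_reflections(refl)
  back <- reflections_from_map(map, hkl)
  expect_equal(back$f, refl$f, tolerance = 1e-6)
  expect_equal(chainview:::wrap_diff(back$phi - refl$phi),
               rep(0, nrow(hkl)), tolerance = 1e-6)
})

test_that("density_at interpolates trilinearly with periodic wrap", {
  grid <- array(0, dim = c(4, 4, 4))
  grid[2, 1, 1] <- 1
  map <- structure(list(grid = grid, cell = c(4, 4, 4, 90, 90, 90),
                        mean = mean(grid), sd = sd(grid)), class = "DensityMap")
  expect_equal(density_at(map, c(1, 0, 0)), 1)       # exactly on the node
  expect_equal(density_at(map, c(0.5, 0, 0)), 0.5)   # edge midpoint
  expect_equal(density_at(map, c(1 + 4, 0, 0)), 1)   # one full cell over
  expect_equal(density_at(map, c(1, 0 - 4, 0)), 1)
})

test_that("atom fit score matches its closed forms", {
  # rho_norm at the map mean: -ln Phi(0) = ln 2
  expect_equal(atom_fit_score(6 * 1.5, 6, 1.5, 0.5), log(2))
  # z = -1: -ln Phi(-1)
  expect_equal(atom_fit_score(1.5 - 0.5, 1, 1.5, 0.5), 1.841021645, tolerance = 1e-8)
  # z -> +inf: score -> 0
  expect_lt(atom_fit_score(1e6, 1, 0, 1), 1e-12)
  # extreme negative z stays finite thanks to the clamp
  expect_true(is.finite(atom_fit_score(-1e6, 1, 0, 1)))
})

test_that("atom fit score decreases strictly and continuously in density", {
  rhos <- seq(-4, 4, by = 0.01)
  s <- vapply(rhos, atom_fit_score, numeric(1), proton_number = 1,
              map_mean = 0, map_sd = 1)
  expect_true(all(diff(s) < 0))
  expect_true(all(s >= 0))
  expect_lt(max(abs(diff(s))), 0.05)  # no jumps on a fine grid
  expect_error(atom_fit_score(1, 1, 0, 0), "degenerate")
})

test_that("residue fit scores average atom scores over the three subsets", {
  # constant map regions: place two atoms on nodes with known density
  grid <- array(0, dim = c(8, 8, 8))
  grid[1, 1, 1] <- 2; grid[3, 1, 1] <- 6
  map <- structure(list(grid = grid, cell = c(8, 8, 8, 90, 90, 90),
                        mean = mean(grid),
                        sd = sqrt(mean((grid - mean(grid))^2))),
                   class = "DensityMap")
  res <- make_residue("GLY", c("N", "CA"), xyz = rbind(c(0, 0, 0), c(2, 0, 0)))
  s1 <- atom_fit_score(2, 7, map$mean, map$sd)
  s2 <- atom_fit_score(6, 6, map$mean, map$sd)
  fit <- residue_fit_scores(res, map)
  expect_equal(fit$all_atoms, (s1 + s2) / 2)
  expect_equal(fit$backbone, (s1 + s2) / 2)
  expect_true(is.na(fit$side_chain))        # glycine: no side-chain atoms
  expect_gte(fit$all_atoms, min(s1, s2))
  expect_lte(fit$all_atoms, max(s1, s2))
})

test_that("hand-mean example: atom scores {0.2, 1.0} average to 0.6", {
  # invert the score formula to find the densities producing 0.2 and 1.0
  rho_for <- function(score, z_mean, z_sd) (qnorm(exp(-score)) * z_sd + z_mean)
  grid <- array(0, dim = c(8, 8, 8))
  map0 <- list(mean = 0.4, sd = 1.3)
  r1 <- rho_for(0.2, map0$mean, map0$sd) * 7  # N, Z = 7
  r2 <- rho_for(1.0, map0$mean, map0$sd) * 6  # CA, Z = 6
  grid[1, 1, 1] <- r1; grid[3, 1, 1] <- r2
  map <- structure(list(grid = grid, cell = c(8, 8, 8, 90, 90, 90),
                        mean = map0$mean, sd = map0$sd), class = "DensityMap")
  res <- make_residue("GLY", c("N", "CA"), xyz = rbind(c(0, 0, 0), c(2, 0, 0)))
  expect_equal(residue_fit_scores(res, map)$all_atoms, 0.6, tolerance = 1e-9)
})

test_that("displacing a residue off its own density worsens its fit", {
  spec <- fixture_spec(seed = 77, n_residues = 6, sequence = "ALA")
  fx <- synthetic_model(spec)
  map <- synthetic_map(fx$model, resolution = 2)
  spec_d <- spec; spec_d$displace <- list(chain = 1, pos = 3, dist = 3)
  fxd <- synthetic_model(spec_d)
  res_ok <- fx$model$chains[[1]]$residues[[3]]
  res_bad <- fxd$model$chains[[1]]$residues[[3]]
  expect_gt(residue_fit_scores(res_bad, map)$all_atoms,
            residue_fit_scores(res_ok, map)$all_atoms)
})

test_that("reflection text files round-trip", {
  refl <- reflection_set(rbind(c(1, 0, 0), c(0, 2, 1)), c(3.5, 1.25),
                         c(0, 45.5), p1_cell)
  path <- withr::local_tempfile(fileext = ".hkl")
  write_reflections_txt(refl, path)
  r2 <- read_reflections_txt(path)
  expect_equal(r2$hkl, refl$hkl, ignore_attr = TRUE)
  expect_equal(r2$f, refl$f)
  expect_equal(r2$phi, refl$phi)
  expect_equal(r2$cell, refl$cell)
})

test_that("CCP4 map files round-trip at single precision", {
  fx <- synthetic_model(fixture_spec(seed = 15, n_residues = 3, sequence = "ALA"))
  map <- synthetic_map(fx$model, resolution = 3)
  path <- withr::local_tempfile(fileext = ".map")
  write_ccp4_map(map, path)
  map2 <- read_ccp4_map(path)
  expect_equal(dim(map2$grid), dim(map$grid))
  expect_equal(map2$cell, map$cell, tolerance = 1e-6)
  expect_equal(map2$origin, map$origin, tolerance = 1e-5)
  expect_equal(map2$grid, map$grid, tolerance = 1e-6)
  # fit scores computed from the re-read map agree
  res <- fx$model$chains[[1]]$residues[[2]]
  expect_equal(residue_fit_scores(res, map2)$all_atoms,
               residue_fit_scores(res, map)$all_atoms, tolerance = 1e-5)
})
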