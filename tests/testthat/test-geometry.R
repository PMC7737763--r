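# B-factor statistics, backbone torsions, and Ramachandran scoring.

test_that("bfactor_summary computes population statistics over included atoms", {
  r <- make_residue("ALA", c("N", "CA", "C"), b = c(10, 10, 10))
  s <- bfactor_summary(r)
  expect_equal(unlist(s[c("minimum", "maximum", "mean", "sd")]),
               c(minimum = 10, maximum = 10, mean = 10, sd = 0))

  r <- make_residue("ALA", c("N", "CA"), b = c(10, 20))
  s <- bfactor_summary(r)
  expect_equal(s$mean, 15)
  expect_equal(s$sd, 5)  # population SD, not sample

  r <- make_residue("HOH", "O", b = 42)
  s <- bfactor_summary(r)
  expect_equal(unlist(s[c("minimum", "maximum", "mean", "sd")]),
               c(minimum = 42, maximum = 42, mean = 42, sd = 0))
})

test_that("hydrogens are excluded from aggregation unless requested", {
  r <- make_residue("ALA", c("N", "CA", "H"), b = c(10, 20, 100),
                    elements = c("N", "C", "H"))
  expect_equal(bfactor_summary(r)$mean, 15)
  expect_equal(bfactor_summary(r, include_hydrogens = TRUE)$mean, 130 / 3)
})

test_that("a residue with no included atoms yields a flagged absent result", {
  r <- make_residue("ALA", "H", b = 5, elements = "H")
  s <- bfactor_summary(r)
  expect_equal(s$n_atoms, 0L)
  expect_true(is.na(s$mean))
})

test_that("bfactor_summary matches brute-force recomputation on random residues", {
  set.seed(42)
  for (k in 1:25) {
    n <- sample(1:12, 1)
    b <- round(runif(n, 2, 120), 2)
    r <- make_residue("LYS", sprintf("C%d", seq_len(n)), b = b)
    s <- bfactor_summary(r)
    expect_equal(s$minimum, min(b))
    expect_equal(s$maximum, max(b))
    expect_equal(s$mean, sum(b) / n)
    expect_equal(s$sd, sqrt(sum((b - mean(b))^2) / n))
    expect_true(s$minimum <= s$mean && s$mean <= s$maximum)
  }
})

test_that("backbone torsions recover construction angles and respect termini", {
  fx <- synthetic_model(fixture_spec(seed = 1, n_residues = 6,
                                     sequence = "ALA"))
  ch <- fx$model$chains[[1]]
  t1 <- backbone_torsions(ch, 1)
  expect_true(is.na(t1["phi"]))
  expect_false(is.na(t1["psi"]))
  tn <- backbone_torsions(ch, 6)
  expect_true(is.na(tn["psi"]))
  for (i in 2:5) {
    tor <- backbone_torsions(ch, i)
    expect_equal(unname(tor["phi"]), -57, tolerance = 1 / 57)
    expect_equal(unname(tor["psi"]), -47, tolerance = 1 / 47)
  }
  # full-precision fixture round-trip
  che <- fx$model_exact$chains[[1]]
  for (i in 2:5) {
    tor <- backbone_torsions(che, i)
    expect_equal(unname(tor["phi"]), -57, tolerance = 1e-3 / 57)
    expect_equal(unname(tor["psi"]), -47, tolerance = 1e-3 / 47)
  }
})

test_that("a long peptide bond is treated as a chain break", {
  fx <- synthetic_model(fixture_spec(seed = 1, n_residues = 4, sequence = "ALA",
                                     displace = list(chain = 1, pos = 3, dist = 8)))
  ch <- fx$model$chains[[1]]
  expect_true(is.na(backbone_torsions(ch, 3)["phi"]))  # C(2)-N(3) broken
  expect_true(is.na(backbone_torsions(ch, 2)["psi"]))
  expect_false(is.na(backbone_torsions(ch, 2)["phi"]))
})

test_that("degenerate collinear geometry yields an absent torsion", {
  expect_true(is.na(dihedral(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 0, 0))))
})

test_that("torsions are invariant under rigid-body motion", {
  fx <- synthetic_model(fixture_spec(seed = 9, n_residues = 5, sequence = "ALA",
                                     torsions = "random"))
  ch <- fx$model_exact$chains[[1]]
  before <- lapply(2:4, function(i) backbone_torsions(ch, i))
  th <- 0.7; ax <- c(1, 2, 3) / sqrt(14)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  shift <- c(11, -4, 7)
  ch2 <- ch
  for (i in seq_along(ch2$residues)) {
    xyz <- as.matrix(ch2$residues[[i]]$atoms[, c("x", "y", "z")])
    xyz2 <- t(R %*% t(xyz) + shift)
    ch2$residues[[i]]$atoms[, c("x", "y", "z")] <- xyz2
  }
  after <- lapply(2:4, function(i) backbone_torsions(ch2, i))
  for (k in seq_along(before))
    expect_equal(after[[k]], before[[k]], tolerance = 1e-6)
})

test_that("dihedral agrees with an independent torsion implementation", {
  skip_if_not_installed("bio3d")
  set.seed(7)
  for (k in 1:20) {
    pts <- matrix(rnorm(12, sd = 3), 4, 3)
    mine <- dihedral(pts[1, ], pts[2, ], pts[3, ], pts[4, ])
    if (is.na(mine)) next
    ref <- bio3d::torsion.xyz(as.numeric(t(pts)))
    expect_equal(chainview:::wrap_diff(mine - ref), 0, tolerance = 1e-6)
  }
})

test_that("rama_probability interpolates bilinearly on the periodic grid", {
  uni <- rama_table("general", matrix(0.5, 36, 36))
  expect_equal(rama_probability(12.3, -155.2, uni), 0.5)

  g <- matrix(0, 36, 36)
  g[10, 20] <- 0.8
  tab <- rama_table("general", g)
  phi <- -180 + 9 * 10; psi <- -180 + 19 * 10
  expect_equal(rama_probability(phi, psi, tab), 0.8)  # exact node
  # midpoint of 4 nodes valued {0, 0, 1, 1} -> 0.5
  g2 <- matrix(0, 4, 4)
  g2[2, 2] <- 1; g2[2, 3] <- 1   # one phi row fully 1 across the psi pair
  tab2 <- rama_table("general", g2)
  phi_mid <- -180 + 90 * 0.5 + 90  # halfway between nodes 2 and 3 in phi
  psi_node_mid <- -180 + 90 * 1.5
  expect_equal(rama_probability(phi_mid, psi_node_mid, tab2), 0.5)
  # periodicity: +360 on both axes changes nothing
  expect_equal(rama_probability(phi_mid + 360, psi_node_mid - 360, tab2), 0.5)
})

test_that("rama_classify partitions [0,1] with inclusive boundaries", {
  thr <- c(favored_min = 0.02, allowed_min = 0.002)
  expect_equal(rama_classify(0.02, thr), "favored")
  expect_equal(rama_classify(0, thr), "outlier")
  expect_equal(rama_classify(0.01, thr), "allowed")
  expect_equal(rama_classify(0.002, thr), "allowed")
  expect_equal(rama_classify(NA, thr), "unknown")
  # exactly one class for each p, monotone in p
  order_of <- c(outlier = 1, allowed = 2, favored = 3)
  ps <- sort(c(seq(0, 1, by = 0.001), 0.002, 0.02))
  cls <- vapply(ps, rama_classify, "", thresholds = thr)
  expect_true(all(cls %in% names(order_of)))
  expect_true(all(diff(order_of[cls]) >= 0))
})

test_that("rama categories follow residue identity and proline context", {
  expect_equal(rama_category("GLY", "PRO"), "GLY")
  expect_equal(rama_category("PRO"), "PRO")
  expect_equal(rama_category("ALA", "PRO"), "pre-PRO")
  expect_equal(rama_category("VAL", "ALA"), "ILE/VAL")
  expect_equal(rama_category("LYS"), "general")
})

test_that("rama tables round-trip through the text format", {
  tab <- test_refdata$rama_tables$general
  path <- withr::local_tempfile(fileext = ".txt")
  write_rama_table(tab, path)
  tab2 <- read_rama_table(path)
  expect_equal(tab2$category, tab$category)
  expect_equal(tab2$grid, tab$grid, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(tab2$phi_spacing, tab$phi_spacing)
})
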