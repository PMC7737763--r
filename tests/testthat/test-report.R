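# Chain-view / residue-view SVG rendering and HTML report assembly.

count_nodes <- function(doc, xpath) length(xml2::xml_find_all(doc, xpath))

simple_records <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(
    chain = "A", seq_num = seq_len(n), icode = "",
    name = rep_len(c("ALA", "SER", "LEU"), n),
    b_min = runif(n, 5, 15), b_max = runif(n, 30, 60),
    b_mean = runif(n, 15, 35), b_sd = runif(n, 0, 5),
    phi = -57, psi = -47,
    rama_prob = runif(n), rama_class = sample(c("favored", "allowed", "outlier"),
                                              n, TRUE, prob = c(0.8, 0.15, 0.05)),
    rot_score = runif(n, 0, 4),
    rot_class = sample(c("favored", "allowed", "outlier", "unknown"),
                       n, TRUE, prob = c(0.7, 0.15, 0.1, 0.05)),
    rot_flag = "", fit_all = runif(n, 0.3, 1.5), fit_backbone = runif(n, 0.3, 1.5),
    fit_side = runif(n, 0.3, 1.5),
    pct_b_mean = sample(0:100, n, TRUE), pct_b_max = sample(0:100, n, TRUE),
    pct_fit_all = sample(0:100, n, TRUE), pct_fit_side = sample(0:100, n, TRUE),
    stringsAsFactors = FALSE)
}

test_that("axis_transform flips polarity, skews, and stays in [0,1]", {
  # higher-is-worse B-factors: worst residue innermost
  fr <- axis_transform(c(10, 20, 30), higher_is_worse = TRUE, gamma = 2)
  expect_equal(fr, c(1, 0.25, 0))
  # gamma = 1 is plain flipped min-max scaling
  expect_equal(axis_transform(c(10, 20, 30), TRUE, gamma = 1), c(1, 0.5, 0))
  # power rule: flipped value 0.5 with gamma 2 -> 0.25
  expect_equal(axis_transform(c(0, 0.5, 1), FALSE, gamma = 2)[2], 0.25)
  # all-constant input -> no trough
  expect_equal(axis_transform(c(7, 7, 7), TRUE, 2), c(1, 1, 1))
  # NA propagates, everything else within bounds
  fr <- axis_transform(c(1, NA, 3, 10), TRUE, 2)
  expect_true(is.na(fr[2]))
  expect_true(all(fr[!is.na(fr)] >= 0 & fr[!is.na(fr)] <= 1))
})

test_that("axis_transform is monotone for fixed polarity", {
  set.seed(2)
  v <- sort(runif(50, 0, 100))
  up <- axis_transform(v, higher_is_worse = FALSE, gamma = 2)
  dn <- axis_transform(v, higher_is_worse = TRUE, gamma = 2)
  expect_true(all(diff(up) >= 0))
  expect_true(all(diff(dn) <= 0))
})

test_that("chain-view SVG has one segment per residue and parses as XML", {
  for (n in c(3, 100)) {
    svg <- chain_view_svg(simple_records(n))
    doc <- xml2::read_xml(svg)
    expect_equal(count_nodes(doc, "//*[@class='cv-seg']"), n)
    expect_equal(count_nodes(doc, "//*[@class='cv-selector']"), 1)
  }
})

test_that("discrete ring color tokens match the input class counts", {
  rec <- simple_records(60, seed = 9)
  svg <- chain_view_svg(rec)
  doc <- xml2::read_xml(svg)
  for (cl in c("favored", "allowed", "outlier", "unknown")) {
    got <- count_nodes(doc, sprintf(
      "//*[@class='cv-disc'][@data-metric='rot_class'][@data-class='%s']", cl))
    expect_equal(got, sum(rec$rot_class == cl), info = cl)
  }
  # unknown rotamers are *rendered* with the outlier color
  unk <- xml2::xml_find_first(doc,
    "//*[@class='cv-disc'][@data-metric='rot_class'][@data-class='unknown']")
  out <- xml2::xml_find_first(doc,
    "//*[@class='cv-disc'][@data-metric='rot_class'][@data-class='outlier']")
  expect_equal(xml2::xml_attr(unk, "fill"), xml2::xml_attr(out, "fill"))
})

test_that("rendering is deterministic", {
  rec <- simple_records(25, seed = 3)
  expect_identical(chain_view_svg(rec), chain_view_svg(rec))
  lst <- list(A = rec)
  expect_identical(build_report(lst)$html, build_report(lst)$html)
})

test_that("residue-view bars coincide with the dashed mean line at the chain mean", {
  rec <- simple_records(10, seed = 4)
  rec$pct_b_mean <- 40L  # constant chain: min = max = mean = 40, sd = 0
  dist <- chain_percentile_distribution(rec)
  expect_equal(dist$b_mean, list(min = 40, max = 40, mean = 40, sd = 0))
  svg <- residue_view_svg(rec[1, ], dist)
  doc <- xml2::read_xml(svg)
  marker <- xml2::xml_find_first(doc, "//*[@class='rv-marker'][@data-metric='b_mean']")
  dashes <- xml2::xml_find_all(doc, "//*[@class='rv-dash']")
  marker_y <- xml2::xml_attr(marker, "y1")
  dash_ys <- unique(xml2::xml_attr(dashes, "y1"))
  expect_true(marker_y %in% dash_ys)
})

test_that("the radar layout adapts its vertex count to the metric count", {
  rec <- simple_records(10, seed = 5)
  rec$pct_rama_prob <- 55L
  rec$pct_rot_score <- 60L
  dist6 <- chain_percentile_distribution(rec)
  expect_length(dist6, 6)
  doc6 <- xml2::read_xml(residue_view_svg(rec[1, ], dist6, layout = "radar"))
  expect_equal(count_nodes(doc6, "//*[@class='rv-vertex']"), 6)
  poly6 <- xml2::xml_find_first(doc6, "//*[@class='rv-poly']")
  expect_equal(length(strsplit(xml2::xml_attr(poly6, "points"), " ")[[1]]), 6)

  dist5 <- dist6[1:5]
  doc5 <- xml2::read_xml(residue_view_svg(rec[1, ], dist5, layout = "radar"))
  expect_equal(count_nodes(doc5, "//*[@class='rv-vertex']"), 5)
})

test_that("full reports carry extra sections; minimized reports do not", {
  lst <- list(A = simple_records(12))
  full <- build_report(lst, mode = "full")$html
  mini <- build_report(lst, mode = "minimized")$html
  expect_match(full, "report-extra")
  expect_false(grepl("report-extra", mini))
  expect_match(mini, "cv-panel")
  # both parse as strict XML
  expect_no_error(xml2::read_xml(full))
  expect_no_error(xml2::read_xml(mini))
})

test_that("the version toggle appears only for two-version input", {
  single <- list(A = simple_records(8))
  expect_false(grepl('id="cv-toggle"', build_report(single)$html))

  rec <- simple_records(8)
  rec$missing_latest <- FALSE
  rec$missing_previous <- c(rep(FALSE, 6), TRUE, TRUE)
  rec$prev_b_mean <- rec$b_mean + 2
  rec$prev_b_max <- rec$b_max
  rec$prev_fit_all <- rec$fit_all
  rec$prev_fit_side <- rec$fit_side
  rec$prev_rama_class <- rec$rama_class
  rec$prev_rot_class <- rec$rot_class
  html <- build_report(list(A = rec))$html
  expect_match(html, "cv-toggle")
  doc <- xml2::read_xml(html)
  expect_equal(count_nodes(doc, "//*[@class='cv-missing']"), 2)
})

test_that("legacy compatibility mode avoids modern script keywords", {
  lst <- list(A = simple_records(6))
  legacy <- build_report(lst, compat = "legacy")$html
  modern <- build_report(lst, compat = "modern")$html
  for (tok in c("let ", "const ", "=>", "`")) {
    expect_false(grepl(tok, legacy, fixed = TRUE), info = tok)
  }
  expect_true(any(vapply(c("const ", "=>", "`"), grepl, logical(1),
                         x = modern, fixed = TRUE)))
  # interaction hooks exposed under both modes
  for (html in list(legacy, modern)) {
    expect_match(html, "function selectResidue")
    expect_match(html, "function toggleVersion")
  }
})

test_that("external flag markers are drawn at the rim", {
  rec <- simple_records(10)
  flags <- data.frame(chain = "A", seq_num = c(2, 5), flag = "clash")
  svg <- chain_view_svg(rec, flags = flags)
  doc <- xml2::read_xml(svg)
  expect_equal(count_nodes(doc, "//*[@class='cv-flag']"), 2)
})

test_that("reports without analyzable chains carry an explicit empty state", {
  html <- build_report(list())$html
  expect_match(html, "cv-empty")
  expect_no_error(xml2::read_xml(html))
})

test_that("chain selector appears for multi-chain reports", {
  lst <- list(A = simple_records(5), B = simple_records(7))
  html <- build_report(lst)$html
  expect_match(html, "cv-chain-select")
  doc <- xml2::read_xml(html)
  expect_equal(count_nodes(doc, "//*[@id='cv-chain-select']/*"), 2)
})
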