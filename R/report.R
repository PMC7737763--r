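# Rendering: radial chain-view SVG, residue-view SVG, and the full/minimized
# HTML report with selector and two-version toggle interactivity.
#
# All output is deterministic (no timestamps, no RNG) and XML-well-formed;
# scripts are wrapped in CDATA so reports parse with strict parsers.

#' Chain-view configuration
#'
#' @param rings ordered list (inner to outer) of
#'   `list(metric =, kind = "discrete"|"continuous", polarity =)` where
#'   `polarity = TRUE` means higher raw values are poorer (flipped inward).
#' @param gamma skew exponent (> 0); values above 1 exaggerate troughs on the
#'   poor (inner) side of continuous axes.
#' @param radii inner and outer radius bounds of the ring stack, SVG units
#'   (viewBox is 1000 x 1000).
#' @param colors named colors for the discrete classes.
#' @param gap_deg angular gap reserved for the residue selector arm, degrees.
#' @param selector_pos initial selected position (1-based).
#' @param animation_ms toggle animation duration.
#' @param scale_per `"chain"` (default) or `"model"`: range used for min-max
#'   scaling of continuous axes.
#' @return object of class `ChainViewConfig`.
#' @export
chain_view_config <- function(rings = default_rings(), gamma = 2,
                              radii = c(150, 440),
                              colors = c(favored = "#2e7d32",
                                         allowed = "#f9a825",
                                         outlier = "#c62828",
                                         unknown = "#c62828"),
                              gap_deg = 10, selector_pos = 1,
                              animation_ms = 800, scale_per = "chain") {
  stopifnot(length(rings) >= 1, gamma > 0, radii[2] > radii[1],
            scale_per %in% c("chain", "model"))
  structure(list(rings = rings, gamma = gamma, radii = radii, colors = colors,
                 gap_deg = gap_deg, selector_pos = selector_pos,
                 animation_ms = animation_ms, scale_per = scale_per),
            class = "ChainViewConfig")
}

#' @rdname chain_view_config
#' @export
default_rings <- function() {
  list(list(metric = "rama_class", kind = "discrete", label = "Ramachandran"),
       list(metric = "rot_class", kind = "discrete", label = "Rotamer"),
       list(metric = "b_mean", kind = "continuous", polarity = TRUE,
            label = "Mean B"),
       list(metric = "b_max", kind = "continuous", polarity = TRUE,
            label = "Max B"),
       list(metric = "fit_all", kind = "continuous", polarity = TRUE,
            label = "Fit (all)"),
       list(metric = "fit_side", kind = "continuous", polarity = TRUE,
            label = "Fit (side)"))
}

#' Radial fractions for a continuous axis
#'
#' Min-max scales values within the chain (or supplied range), flips when the
#' metric's polarity is higher-is-worse so poor values point inward, and
#' skews with `r^gamma` so the poor (small-radius) side is exaggerated.
#' All-constant input maps to 1 everywhere (no trough). `NA` stays `NA`.
#'
#' @param values numeric metric values.
#' @param higher_is_worse logical polarity flag.
#' @param gamma skew exponent, > 0.
#' @param range optional `c(min, max)` overriding the within-chain range
#'   (used for per-model scaling).
#' @return numeric vector of radial fractions in `[0, 1]`.
#' @export
axis_transform <- function(values, higher_is_worse = TRUE, gamma = 2,
                           range = NULL) {
  ok <- is.finite(values)
  if (!any(ok)) return(rep(NA_real_, length(values)))
  rng <- if (is.null(range)) c(min(values[ok]), max(values[ok])) else range
  out <- rep(NA_real_, length(values))
  if (diff(rng) <= 0) {
    out[ok] <- 1
    return(out)
  }
  r <- (values[ok] - rng[1]) / (rng[2] - rng[1])
  r <- pmin(pmax(r, 0), 1)
  if (higher_is_worse) r <- 1 - r
  out[ok] <- r^gamma
  out
}

# --- low-level svg helpers ---------------------------------------------------

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

fmt <- function(x) sprintf("%.2f", x)

# Point on a circle; angles in degrees, 0 = 12 o'clock, clockwise positive.
polar_xy <- function(cx, cy, r, angle_deg) {
  a <- deg2rad(angle_deg - 90)
  c(cx + r * cos(a), cy + r * sin(a))
}

annular_sector_path <- function(cx, cy, r0, r1, a0, a1) {
  p1 <- polar_xy(cx, cy, r0, a0); p2 <- polar_xy(cx, cy, r1, a0)
  p3 <- polar_xy(cx, cy, r1, a1); p4 <- polar_xy(cx, cy, r0, a1)
  large <- if ((a1 - a0) %% 360 > 180) 1 else 0
  sprintf("M %s %s L %s %s A %s %s 0 %d 1 %s %s L %s %s A %s %s 0 %d 0 %s %s Z",
          fmt(p1[1]), fmt(p1[2]), fmt(p2[1]), fmt(p2[2]),
          fmt(r1), fmt(r1), large, fmt(p3[1]), fmt(p3[2]),
          fmt(p4[1]), fmt(p4[2]), fmt(r0), fmt(r0), large,
          fmt(p1[1]), fmt(p1[2]))
}

# Path through radial points; NA radii break the stroke.
radial_path <- function(cx, cy, radii, angles) {
  ok <- is.finite(radii)
  if (!any(ok)) return("")
  cmds <- character(0)
  pen_down <- FALSE
  for (i in seq_along(radii)) {
    if (!ok[i]) { pen_down <- FALSE; next }
    p <- polar_xy(cx, cy, radii[i], angles[i])
    cmds <- c(cmds, sprintf("%s %s %s", if (pen_down) "L" else "M",
                            fmt(p[1]), fmt(p[2])))
    pen_down <- TRUE
  }
  paste(cmds, collapse = " ")
}

# --- chain view --------------------------------------------------------------

# Ring radius bands: discrete rings get weight 1, continuous weight 2.
ring_bands <- function(config) {
  w <- vapply(config$rings, function(r) if (r$kind == "discrete") 1 else 2,
              numeric(1))
  edges <- config$radii[1] +
    cumsum(c(0, w)) / sum(w) * diff(config$radii)
  lapply(seq_along(config$rings), function(i) {
    c(edges[i] + 1, edges[i + 1] - 1)  # 1-unit visual gap between rings
  })
}

#' Render the radial chain-view SVG
#'
#' One angular segment per alignment position, one concentric ring per
#' configured metric. Discrete rings color segments by class; continuous
#' rings draw a radial polyline of [axis_transform()] fractions. When
#' two-version collated records are supplied, the previous version's geometry
#' is embedded in `data-prev` attributes for the toggle animation, and
#' positions missing from either version carry black rim markers.
#'
#' @param records collated per-position metrics data frame (from
#'   [collate_metrics()], or a plain [chain_metrics()] frame for
#'   single-version display).
#' @param config a `ChainViewConfig`.
#' @param chain_index 0-based index used in the JS interaction hooks.
#' @param ranges optional named list `metric -> c(min, max)` for per-model
#'   scaling.
#' @param flags optional data frame of external per-residue markers with
#'   columns `seq_num` and `flag` (e.g. clash); drawn at the rim.
#' @return character scalar: a standalone SVG document.
#' @export
chain_view_svg <- function(records, config = chain_view_config(),
                           chain_index = 0, ranges = NULL, flags = NULL) {
  n <- nrow(records)
  stopifnot(n >= 1)
  two_versions <- "missing_previous" %in% names(records) &&
    any(!is.na(records$missing_previous))
  cx <- 500; cy <- 500
  step <- (360 - config$gap_deg) / n
  a0 <- config$gap_deg / 2 + (seq_len(n) - 1) * step
  a1 <- a0 + step
  mid <- (a0 + a1) / 2
  bands <- ring_bands(config)
  rim <- config$radii[2]
  out <- c(sprintf(paste0(
    '<svg xmlns="http://www.w3.org/2000/svg" viewBox="0 0 1000 1000" ',
    'class="cv-root" data-chain="%d" data-animation-ms="%d">'),
    chain_index, config$animation_ms))

  # ring band outlines
  for (b in bands)
    out <- c(out, sprintf(
      '<circle cx="500" cy="500" r="%s" fill="none" stroke="#e0e0e0" stroke-width="0.5"/>',
      fmt(b[2])))

  # continuous rings first (under the segment groups)
  for (ri in seq_along(config$rings)) {
    ring <- config$rings[[ri]]
    if (ring$kind != "continuous") next
    band <- bands[[ri]]
    vals <- records[[ring$metric]]
    rng <- if (!is.null(ranges)) ranges[[ring$metric]] else NULL
    fr <- axis_transform(vals, isTRUE(ring$polarity), config$gamma, rng)
    radii <- band[1] + fr * (band[2] - band[1])
    d <- radial_path(cx, cy, radii, mid)
    prev_d <- ""
    if (two_versions) {
      pv <- records[[paste0("prev_", ring$metric)]]
      pfr <- axis_transform(pv, isTRUE(ring$polarity), config$gamma, rng)
      prev_d <- radial_path(cx, cy, band[1] + pfr * (band[2] - band[1]), mid)
    }
    if (nzchar(d) || nzchar(prev_d))
      out <- c(out, sprintf(
        '<path class="cv-line" data-metric="%s" d="%s" data-prev="%s" fill="none" stroke="#1565c0" stroke-width="1.6"/>',
        ring$metric, if (nzchar(d)) d else prev_d, xml_escape(prev_d)))
  }

  # per-position segment groups: discrete sectors + click wedge
  classes <- c("favored", "allowed", "outlier", "unknown")
  for (i in seq_len(n)) {
    seg <- sprintf('<g class="cv-seg" data-pos="%d">', i - 1L)
    for (ri in seq_along(config$rings)) {
      ring <- config$rings[[ri]]
      if (ring$kind != "discrete") next
      band <- bands[[ri]]
      cl <- records[[ring$metric]][i]
      cl <- if (is.na(cl) || !(cl %in% classes)) "unknown" else cl
      prev_cl <- ""
      if (two_versions) {
        pv <- records[[paste0("prev_", ring$metric)]][i]
        prev_cl <- if (is.na(pv) || !(pv %in% classes)) "unknown" else pv
      }
      seg <- c(seg, sprintf(
        '<path class="cv-disc" data-metric="%s" data-class="%s" data-prev-class="%s" d="%s" fill="%s" stroke="none"/>',
        ring$metric, cl, prev_cl, annular_sector_path(cx, cy, band[1], band[2],
                                                      a0[i], a1[i]),
        config$colors[[cl]]))
    }
    # invisible click target spanning the whole ring stack
    seg <- c(seg, sprintf(
      '<path class="cv-click" d="%s" fill="#000000" fill-opacity="0" onclick="selectResidue(%d,%d)"/>',
      annular_sector_path(cx, cy, config$radii[1], rim + 22, a0[i], a1[i]),
      chain_index, i - 1L))
    out <- c(out, seg, "</g>")
  }

  # missing-residue markers (black spots at the rim)
  if (two_versions) {
    for (i in seq_len(n)) {
      for (ver in c("latest", "previous")) {
        if (isTRUE(records[[paste0("missing_", ver)]][i])) {
          p <- polar_xy(cx, cy, rim + 10, mid[i])
          out <- c(out, sprintf(
            '<circle class="cv-missing" data-version="%s" data-pos="%d" cx="%s" cy="%s" r="%s" fill="#000000"/>',
            ver, i - 1L, fmt(p[1]), fmt(p[2]), fmt(max(2, min(5, step)))))
        }
      }
    }
  }

  # external flag markers (e.g. clash) at the rim
  if (!is.null(flags) && nrow(flags)) {
    for (k in seq_len(nrow(flags))) {
      i <- match(flags$seq_num[k], records$seq_num)
      if (is.na(i)) next
      p <- polar_xy(cx, cy, rim + 18, mid[i])
      out <- c(out, sprintf(
        '<circle class="cv-flag" data-flag="%s" data-pos="%d" cx="%s" cy="%s" r="3.5" fill="#6a1b9a"><title>%s</title></circle>',
        xml_escape(flags$flag[k]), i - 1L, fmt(p[1]), fmt(p[2]),
        xml_escape(flags$flag[k])))
    }
  }

  # selector arm in the reserved gap, pointing at the selected position
  sel <- min(max(config$selector_pos, 1), n)
  ps <- polar_xy(cx, cy, rim + 26, mid[sel])
  out <- c(out, sprintf(
    '<line class="cv-selector" data-pos="%d" x1="500" y1="500" x2="%s" y2="%s" stroke="#212121" stroke-width="2.5"/>',
    sel - 1L, fmt(ps[1]), fmt(ps[2])))
  # per-residue anchors for external 3D viewers
  cid <- records$chain[!is.na(records$chain)]
  cid <- if (length(cid)) cid[1] else "?"
  anchor_ids <- sprintf("res-%s-%s%s", xml_escape(cid),
                        ifelse(is.na(records$seq_num), paste0("gap", seq_len(n)),
                               records$seq_num),
                        ifelse(is.na(records$icode) | records$icode == "", "",
                               records$icode))
  out <- c(out, sprintf('<g class="cv-anchors">%s</g>',
                        paste(sprintf('<a id="%s"></a>', anchor_ids),
                              collapse = "")))
  out <- c(out, "</svg>")
  paste(out, collapse = "\n")
}

# --- residue view ------------------------------------------------------------

# Chain-level distribution (min, max, mean, sd) of each percentile column.
chain_percentile_distribution <- function(records) {
  pcts <- grep("^pct_", names(records), value = TRUE)
  out <- lapply(pcts, function(cn) {
    v <- records[[cn]][is.finite(records[[cn]])]
    if (!length(v)) return(NULL)
    list(min = min(v), max = max(v), mean = mean(v),
         sd = sqrt(mean((v - mean(v))^2)))
  })
  names(out) <- sub("^pct_", "", pcts)
  out[!vapply(out, is.null, logical(1))]
}

.metric_labels <- c(b_mean = "Mean B", b_max = "Max B", fit_all = "Fit (all)",
                    fit_side = "Fit (side)", rama_prob = "Ramachandran",
                    rot_score = "Rotamer")

#' Render the residue-view SVG
#'
#' Default layout: traffic-light boxes for the discrete classifications plus
#' one vertical bar per continuous metric on the percentile scale. Each bar's
#' spectrum spans the chain's min to max percentile, with dashed lines at the
#' chain mean and one SD either side, and a marker at the residue's own
#' percentile. Radar layout: one polygon vertex per metric on the percentile
#' scale, with hover bubbles carrying absolute and percentile values; the
#' polygon adapts to the number of metrics.
#'
#' @param record one-row data frame (a collated or chain metrics row).
#' @param chain_dist per-metric distribution list from
#'   [chain_percentile_distribution()].
#' @param layout `"default"` or `"radar"`.
#' @param colors discrete class palette.
#' @return character scalar: a standalone SVG document.
#' @export
residue_view_svg <- function(record, chain_dist, layout = "default",
                             colors = c(favored = "#2e7d32",
                                        allowed = "#f9a825",
                                        outlier = "#c62828",
                                        unknown = "#9e9e9e")) {
  layout <- match.arg(layout, c("default", "radar"))
  metrics <- names(chain_dist)
  label_of <- function(m) .metric_labels[[m]] %||% m
  title <- sprintf("%s %s%s %s", record$chain %||% "?", record$seq_num,
                   record$icode %||% "", record$name)
  out <- c('<svg xmlns="http://www.w3.org/2000/svg" viewBox="0 0 420 460" class="rv-root">',
           sprintf('<text class="rv-title" x="210" y="24" text-anchor="middle" font-size="16">%s</text>',
                   xml_escape(title)))

  if (layout == "default") {
    # discrete traffic lights
    disc <- c(rama_class = "Ramachandran", rot_class = "Rotamer")
    x <- 40
    for (dm in names(disc)) {
      cl <- record[[dm]]
      cl <- if (is.null(cl) || is.na(cl)) "unknown" else cl
      out <- c(out, sprintf(
        '<rect class="rv-disc" data-metric="%s" data-class="%s" x="%d" y="44" width="26" height="26" rx="4" fill="%s"/>',
        dm, cl, x, colors[[cl]]),
        sprintf('<text x="%d" y="62" font-size="12">%s</text>', x + 34, disc[[dm]]))
      x <- x + 190
    }
    # continuous percentile bars
    bar_top <- 110; bar_bot <- 420
    yscale <- function(p) bar_bot - p / 100 * (bar_bot - bar_top)
    bw <- 26
    n <- length(metrics)
    xs <- if (n) seq(60, 360, length.out = max(n, 2))[seq_len(n)] else numeric(0)
    for (k in seq_along(metrics)) {
      m <- metrics[k]; d <- chain_dist[[m]]
      xk <- xs[k]
      out <- c(out,
        sprintf('<rect class="rv-axis" x="%s" y="%s" width="%d" height="%s" fill="#f5f5f5" stroke="#bdbdbd"/>',
                fmt(xk - bw / 2), fmt(yscale(100)), bw,
                fmt(yscale(0) - yscale(100))),
        sprintf('<rect class="rv-spectrum" data-metric="%s" x="%s" y="%s" width="%d" height="%s" fill="#90caf9"/>',
                m, fmt(xk - bw / 2), fmt(yscale(d$max)), bw,
                fmt(max(yscale(d$min) - yscale(d$max), 0.5))))
      for (ln in c(d$mean - d$sd, d$mean, d$mean + d$sd)) {
        ln <- min(max(ln, 0), 100)
        out <- c(out, sprintf(
          '<line class="rv-dash" x1="%s" x2="%s" y1="%s" y2="%s" stroke="#424242" stroke-dasharray="3,2" stroke-width="1"/>',
          fmt(xk - bw / 2), fmt(xk + bw / 2), fmt(yscale(ln)), fmt(yscale(ln))))
      }
      p <- record[[paste0("pct_", m)]]
      if (!is.null(p) && !is.na(p))
        out <- c(out, sprintf(
          '<line class="rv-marker" data-metric="%s" data-pct="%d" x1="%s" x2="%s" y1="%s" y2="%s" stroke="#b71c1c" stroke-width="2.5"/>',
          m, as.integer(p), fmt(xk - bw / 2 - 4), fmt(xk + bw / 2 + 4),
          fmt(yscale(p)), fmt(yscale(p))))
      out <- c(out, sprintf(
        '<text x="%s" y="444" text-anchor="middle" font-size="10">%s</text>',
        fmt(xk), xml_escape(label_of(m))))
    }
  } else {
    # radar: vertex per metric, percentile scale
    cx <- 210; cy <- 250; rmax <- 170
    n <- length(metrics)
    ang <- (seq_len(n) - 1) * 360 / max(n, 1)
    for (gfrac in c(0.25, 0.5, 0.75, 1)) {
      pts <- vapply(ang, function(a) {
        paste(fmt(polar_xy(cx, cy, rmax * gfrac, a)), collapse = ",")
      }, character(1))
      out <- c(out, sprintf(
        '<polygon class="rv-grid" points="%s" fill="none" stroke="#e0e0e0"/>',
        paste(pts, collapse = " ")))
    }
    verts <- character(0)
    for (k in seq_len(n)) {
      m <- metrics[k]
      p <- record[[paste0("pct_", m)]]
      p <- if (is.null(p) || is.na(p)) 0 else p
      xy <- polar_xy(cx, cy, rmax * p / 100, ang[k])
      verts <- c(verts, paste(fmt(xy), collapse = ","))
      lab <- polar_xy(cx, cy, rmax + 18, ang[k])
      absval <- record[[m]]
      bubble <- sprintf("%s: %s (percentile %d)", label_of(m),
                        if (is.null(absval) || is.na(absval)) "n/a"
                        else sprintf("%.3g", absval), as.integer(p))
      out <- c(out,
        sprintf('<circle class="rv-vertex" data-metric="%s" data-pct="%d" cx="%s" cy="%s" r="5" fill="#1565c0"><title>%s</title></circle>',
                m, as.integer(p), fmt(xy[1]), fmt(xy[2]), xml_escape(bubble)),
        sprintf('<text x="%s" y="%s" text-anchor="middle" font-size="9">%s</text>',
                fmt(lab[1]), fmt(lab[2]), xml_escape(label_of(m))))
    }
    if (n >= 3)
      out <- c(out, sprintf(
        '<polygon class="rv-poly" points="%s" fill="#1565c0" fill-opacity="0.25" stroke="#1565c0"/>',
        paste(verts, collapse = " ")))
  }
  out <- c(out, "</svg>")
  paste(out, collapse = "\n")
}
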