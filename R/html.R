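# HTML report assembly: embeds the chain-view and residue-view SVGs, the
# per-chain data payload, styles, and the interaction script (modern or
# archaic-keyword JavaScript) into one self-contained XML-well-formed file.

report_css <- function() {
  paste(
    ".cv-report { font-family: sans-serif; color: #212121; margin: 0 auto; max-width: 1400px; }",
    ".cv-panel { display: flex; flex-wrap: wrap; gap: 16px; align-items: flex-start; }",
    ".cv-chart { flex: 2 1 560px; min-width: 320px; }",
    ".cv-side { flex: 1 1 300px; min-width: 260px; }",
    ".cv-controls { margin: 8px 0; }",
    ".cv-controls button, .cv-controls select { font-size: 14px; padding: 4px 10px; margin-right: 8px; }",
    ".cv-hidden { display: none; }",
    ".cv-click { cursor: pointer; }",
    ".cv-report table { border-collapse: collapse; margin: 12px 0; }",
    ".cv-report th, .cv-report td { border: 1px solid #bdbdbd; padding: 4px 10px; font-size: 13px; }",
    ".cv-empty { padding: 40px; text-align: center; color: #757575; }",
    "@media (prefers-reduced-motion: reduce) { .cv-root * { transition: none; } }",
    sep = "\n")
}

# Interaction script. Both variants expose the same named hooks --
# selectResidue(chainIndex, positionIndex), toggleVersion(), selectChain(i) --
# so host GUIs can drive the panel. The legacy variant restricts itself to
# archaic keywords (var/function, string concatenation) for embedded browsers.
report_js <- function(compat = c("modern", "legacy")) {
  compat <- match.arg(compat)
  if (compat == "modern") {
    paste(
      "const cvColors = {favored:'#2e7d32', allowed:'#f9a825', outlier:'#c62828', unknown:'#c62828'};",
      "const cvState = {chain: 0, version: 'latest', anim: null};",
      "const cvData = () => JSON.parse(document.getElementById('cv-data').textContent);",
      "function cvRoot(ci) { return document.querySelector(`.cv-chart[data-chain='${ci}']`); }",
      "function cvPath(angles, radii) {",
      "  let d = '', pen = false;",
      "  for (let i = 0; i < angles.length; i++) {",
      "    if (radii[i] === null) { pen = false; continue; }",
      "    const a = (angles[i] - 90) * Math.PI / 180;",
      "    const x = 500 + radii[i] * Math.cos(a), y = 500 + radii[i] * Math.sin(a);",
      "    d += (pen ? ' L ' : ' M ') + x.toFixed(2) + ' ' + y.toFixed(2);",
      "    pen = true;",
      "  }",
      "  return d.trim();",
      "}",
      "function selectChain(ci) {",
      "  cvState.chain = ci;",
      "  document.querySelectorAll('.cv-chart').forEach(el => {",
      "    el.classList.toggle('cv-hidden', Number(el.dataset.chain) !== ci);",
      "  });",
      "  selectResidue(ci, 0);",
      "}",
      "function selectResidue(ci, pos) {",
      "  const data = cvData().chains[ci];",
      "  if (!data || !data.positions[pos]) return;",
      "  const rec = data.positions[pos];",
      "  const root = cvRoot(ci);",
      "  if (root) {",
      "    const arm = root.querySelector('.cv-selector');",
      "    const a = (rec.angle - 90) * Math.PI / 180, r = data.rim + 26;",
      "    arm.setAttribute('x2', (500 + r * Math.cos(a)).toFixed(2));",
      "    arm.setAttribute('y2', (500 + r * Math.sin(a)).toFixed(2));",
      "    arm.dataset.pos = pos;",
      "  }",
      "  const rv = document.querySelector('.cv-side');",
      "  if (!rv) return;",
      "  const title = rv.querySelector('.rv-title');",
      "  if (title) title.textContent = rec.label;",
      "  rv.querySelectorAll('.rv-disc').forEach(box => {",
      "    const cl = rec.classes[box.dataset.metric] || 'unknown';",
      "    box.dataset.class = cl;",
      "    box.setAttribute('fill', cvColors[cl]);",
      "  });",
      "  rv.querySelectorAll('.rv-marker').forEach(mk => {",
      "    const p = rec.percentiles[mk.dataset.metric];",
      "    if (p === null || p === undefined) { mk.setAttribute('visibility', 'hidden'); return; }",
      "    mk.setAttribute('visibility', 'visible');",
      "    const y = (420 - p / 100 * 310).toFixed(2);",
      "    mk.setAttribute('y1', y); mk.setAttribute('y2', y);",
      "    mk.dataset.pct = p;",
      "  });",
      "}",
      "function toggleVersion() {",
      "  const to = cvState.version === 'latest' ? 'previous' : 'latest';",
      "  cvState.version = to;",
      "  const data = cvData().chains[cvState.chain];",
      "  const root = cvRoot(cvState.chain);",
      "  if (!root || !data) return;",
      "  root.querySelectorAll('.cv-disc').forEach(p => {",
      "    const cl = to === 'latest' ? p.dataset.class : (p.dataset.prevClass || p.dataset.class);",
      "    p.setAttribute('fill', cvColors[cl] || cvColors.unknown);",
      "  });",
      "  const dur = Number(root.querySelector('.cv-root').dataset.animationMs) || 0;",
      "  const reduce = window.matchMedia && window.matchMedia('(prefers-reduced-motion: reduce)').matches;",
      "  root.querySelectorAll('.cv-line').forEach(line => {",
      "    const m = line.dataset.metric;",
      "    const from = to === 'latest' ? data.prev_radii[m] : data.radii[m];",
      "    const dest = to === 'latest' ? data.radii[m] : data.prev_radii[m];",
      "    if (!dest) return;",
      "    if (reduce || dur <= 0 || !from) { line.setAttribute('d', cvPath(data.angles, dest)); return; }",
      "    const t0 = performance.now();",
      "    const stepFn = now => {",
      "      const t = Math.min((now - t0) / dur, 1);",
      "      const mix = from.map((v, i) => (v === null || dest[i] === null) ? dest[i] : v + (dest[i] - v) * t);",
      "      line.setAttribute('d', cvPath(data.angles, mix));",
      "      if (t < 1) requestAnimationFrame(stepFn);",
      "    };",
      "    requestAnimationFrame(stepFn);",
      "  });",
      "  const btn = document.getElementById('cv-toggle');",
      "  if (btn) btn.textContent = 'Showing: ' + to;",
      "}",
      sep = "\n")
  } else {
    paste(
      "var cvColors = {favored:'#2e7d32', allowed:'#f9a825', outlier:'#c62828', unknown:'#c62828'};",
      "var cvState = {chain: 0, version: 'latest'};",
      "function cvData() { return JSON.parse(document.getElementById('cv-data').textContent); }",
      "function cvAll(root, sel) { return root.querySelectorAll(sel); }",
      "function cvRoot(ci) {",
      "  var charts = document.querySelectorAll('.cv-chart');",
      "  for (var i = 0; i < charts.length; i++) {",
      "    if (Number(charts[i].getAttribute('data-chain')) === ci) { return charts[i]; }",
      "  }",
      "  return null;",
      "}",
      "function cvPath(angles, radii) {",
      "  var d = '', pen = false, i, a, x, y;",
      "  for (i = 0; i < angles.length; i++) {",
      "    if (radii[i] === null) { pen = false; continue; }",
      "    a = (angles[i] - 90) * Math.PI / 180;",
      "    x = 500 + radii[i] * Math.cos(a); y = 500 + radii[i] * Math.sin(a);",
      "    d += (pen ? ' L ' : ' M ') + x.toFixed(2) + ' ' + y.toFixed(2);",
      "    pen = true;",
      "  }",
      "  return d.replace(/^\\s+/, '');",
      "}",
      "function selectChain(ci) {",
      "  cvState.chain = ci;",
      "  var charts = document.querySelectorAll('.cv-chart');",
      "  for (var i = 0; i < charts.length; i++) {",
      "    if (Number(charts[i].getAttribute('data-chain')) === ci) {",
      "      charts[i].className = 'cv-chart';",
      "    } else {",
      "      charts[i].className = 'cv-chart cv-hidden';",
      "    }",
      "  }",
      "  selectResidue(ci, 0);",
      "}",
      "function selectResidue(ci, pos) {",
      "  var data = cvData().chains[ci];",
      "  if (!data || !data.positions[pos]) { return; }",
      "  var rec = data.positions[pos];",
      "  var root = cvRoot(ci);",
      "  if (root) {",
      "    var arm = root.querySelector('.cv-selector');",
      "    var a = (rec.angle - 90) * Math.PI / 180;",
      "    var r = data.rim + 26;",
      "    arm.setAttribute('x2', (500 + r * Math.cos(a)).toFixed(2));",
      "    arm.setAttribute('y2', (500 + r * Math.sin(a)).toFixed(2));",
      "    arm.setAttribute('data-pos', pos);",
      "  }",
      "  var rv = document.querySelector('.cv-side');",
      "  if (!rv) { return; }",
      "  var title = rv.querySelector('.rv-title');",
      "  if (title) { title.textContent = rec.label; }",
      "  var boxes = cvAll(rv, '.rv-disc');",
      "  for (var i = 0; i < boxes.length; i++) {",
      "    var cl = rec.classes[boxes[i].getAttribute('data-metric')] || 'unknown';",
      "    boxes[i].setAttribute('data-class', cl);",
      "    boxes[i].setAttribute('fill', cvColors[cl]);",
      "  }",
      "  var marks = cvAll(rv, '.rv-marker');",
      "  for (var j = 0; j < marks.length; j++) {",
      "    var p = rec.percentiles[marks[j].getAttribute('data-metric')];",
      "    if (p === null || p === undefined) {",
      "      marks[j].setAttribute('visibility', 'hidden');",
      "    } else {",
      "      marks[j].setAttribute('visibility', 'visible');",
      "      var yy = (420 - p / 100 * 310).toFixed(2);",
      "      marks[j].setAttribute('y1', yy); marks[j].setAttribute('y2', yy);",
      "      marks[j].setAttribute('data-pct', p);",
      "    }",
      "  }",
      "}",
      "function toggleVersion() {",
      "  var to = cvState.version === 'latest' ? 'previous' : 'latest';",
      "  cvState.version = to;",
      "  var data = cvData().chains[cvState.chain];",
      "  var root = cvRoot(cvState.chain);",
      "  if (!root || !data) { return; }",
      "  var discs = cvAll(root, '.cv-disc');",
      "  for (var i = 0; i < discs.length; i++) {",
      "    var cl = to === 'latest' ? discs[i].getAttribute('data-class')",
      "                             : (discs[i].getAttribute('data-prev-class') || discs[i].getAttribute('data-class'));",
      "    discs[i].setAttribute('fill', cvColors[cl] || cvColors.unknown);",
      "  }",
      "  var lines = cvAll(root, '.cv-line');",
      "  for (var k = 0; k < lines.length; k++) {",
      "    var m = lines[k].getAttribute('data-metric');",
      "    var dest = to === 'latest' ? data.radii[m] : data.prev_radii[m];",
      "    if (dest) { lines[k].setAttribute('d', cvPath(data.angles, dest)); }",
      "  }",
      "  var btn = document.getElementById('cv-toggle');",
      "  if (btn) { btn.textContent = 'Showing: ' + to; }",
      "}",
      sep = "\n")
  }
}

# Per-chain JSON payload backing the interaction script.
report_payload <- function(collated_list, config) {
  chains <- lapply(seq_along(collated_list), function(ci) {
    rec <- collated_list[[ci]]
    n <- nrow(rec)
    step <- (360 - config$gap_deg) / n
    mid <- config$gap_deg / 2 + (seq_len(n) - 1) * step + step / 2
    bands <- ring_bands(config)
    radii <- list(); prev_radii <- list()
    for (ri in seq_along(config$rings)) {
      ring <- config$rings[[ri]]
      if (ring$kind != "continuous") next
      band <- bands[[ri]]
      fr <- axis_transform(rec[[ring$metric]], isTRUE(ring$polarity), config$gamma)
      radii[[ring$metric]] <- round(band[1] + fr * (band[2] - band[1]), 2)
      pcol <- paste0("prev_", ring$metric)
      if (pcol %in% names(rec) && any(is.finite(rec[[pcol]]))) {
        pfr <- axis_transform(rec[[pcol]], isTRUE(ring$polarity), config$gamma)
        prev_radii[[ring$metric]] <- round(band[1] + pfr * (band[2] - band[1]), 2)
      }
    }
    positions <- lapply(seq_len(n), function(i) {
      pcts <- list()
      for (m in names(.metric_labels)) {
        cn <- paste0("pct_", m)
        if (cn %in% names(rec)) pcts[[m]] <- rec[[cn]][i]
      }
      list(
        label = sprintf("%s %s%s %s",
                        rec$chain[i] %||% "?",
                        ifelse(is.na(rec$seq_num[i]), "-", rec$seq_num[i]),
                        ifelse(is.na(rec$icode[i]) | rec$icode[i] == "", "",
                               rec$icode[i]),
                        ifelse(is.na(rec$name[i]), "(gap)", rec$name[i])),
        angle = round(mid[i], 3),
        classes = list(rama_class = rec$rama_class[i],
                       rot_class = rec$rot_class[i]),
        percentiles = pcts
      )
    })
    list(chain_id = names(collated_list)[ci], rim = config$radii[2],
         angles = round(mid, 3), radii = radii, prev_radii = prev_radii,
         positions = positions)
  })
  jsonlite::toJSON(list(chains = chains), auto_unbox = TRUE, digits = 3,
                   null = "null", na = "null")
}

#' Assemble the HTML validation report
#'
#' Produces a single self-contained XML-well-formed HTML file embedding the
#' chain-view and residue-view SVGs, the data payload, styles, and the
#' interaction script. `mode = "full"` appends per-chain summary tables;
#' `mode = "minimized"` emits just the graphical panel (suitable for iframe
#' insertion). `compat = "legacy"` restricts the script to archaic, widely
#' supported JavaScript keywords and keeps all styles under namespaced
#' classes so the markup can be inserted into a host page.
#'
#' @param collated_list named list (by chain id) of collated metrics data
#'   frames (from [collate_metrics()] or [chain_metrics()]).
#' @param mode `"full"` or `"minimized"`.
#' @param compat `"modern"` or `"legacy"`.
#' @param config a `ChainViewConfig`.
#' @param flags optional external per-residue flag table with columns
#'   `chain`, `seq_num`, `flag`.
#' @param output_dir directory to write `report.html` into, or `NULL` to just
#'   return the HTML string.
#' @return list with `html` (character scalar) and `path` (`NULL` unless
#'   written).
#' @export
build_report <- function(collated_list, mode = c("full", "minimized"),
                         compat = c("modern", "legacy"),
                         config = chain_view_config(), flags = NULL,
                         output_dir = NULL) {
  mode <- match.arg(mode)
  compat <- match.arg(compat)

  if (length(collated_list) == 0L) {
    body <- '<div class="cv-report"><p class="cv-empty">No analyzable protein chains were found in the input model(s).</p></div>'
    html <- report_shell(body, "", compat)
    return(finish_report(html, output_dir))
  }

  two_versions <- any(vapply(collated_list, function(df) {
    "missing_previous" %in% names(df) && any(!is.na(df$missing_previous))
  }, logical(1)))

  charts <- vapply(seq_along(collated_list), function(ci) {
    rec <- collated_list[[ci]]
    fl <- NULL
    if (!is.null(flags)) {
      fl <- flags[flags$chain == names(collated_list)[ci], , drop = FALSE]
      if (!nrow(fl)) fl <- NULL
    }
    svg <- chain_view_svg(rec, config, chain_index = ci - 1L, flags = fl)
    sprintf('<div class="cv-chart%s" data-chain="%d">%s</div>',
            if (ci == 1) "" else " cv-hidden", ci - 1L, svg)
  }, character(1))

  first <- collated_list[[1]]
  rv <- residue_view_svg(first[min(config$selector_pos, nrow(first)), ,
                               drop = FALSE],
                         chain_percentile_distribution(first))

  controls <- c('<div class="cv-controls">')
  if (length(collated_list) > 1) {
    opts <- paste(sprintf('<option value="%d">Chain %s</option>',
                          seq_along(collated_list) - 1L,
                          xml_escape(names(collated_list))), collapse = "")
    controls <- c(controls, sprintf(
      '<select id="cv-chain-select" onchange="selectChain(Number(this.value))">%s</select>', opts))
  }
  if (two_versions)
    controls <- c(controls,
                  '<button id="cv-toggle" onclick="toggleVersion()">Showing: latest</button>')
  controls <- c(controls, "</div>")

  payload <- report_payload(collated_list, config)
  body <- c(
    '<div class="cv-report">',
    if (mode == "full") "<h1>Model validation report</h1>",
    paste(controls, collapse = ""),
    '<div class="cv-panel">',
    charts,
    sprintf('<div class="cv-side">%s</div>', rv),
    "</div>",
    if (mode == "full") summary_sections(collated_list),
    sprintf('<script type="application/json" id="cv-data">%s</script>', payload),
    "</div>")
  html <- report_shell(paste(body, collapse = "\n"), report_js(compat), compat)
  finish_report(html, output_dir)
}

summary_sections <- function(collated_list) {
  rows <- vapply(names(collated_list), function(cid) {
    df <- collated_list[[cid]]
    present <- !(df$missing_latest %||% rep(FALSE, nrow(df)))
    present[is.na(present)] <- TRUE
    d <- df[present, , drop = FALSE]
    sprintf("<tr><td>%s</td><td>%d</td><td>%d</td><td>%d</td><td>%s</td><td>%s</td></tr>",
            xml_escape(cid), nrow(d),
            sum(d$rama_class %in% c("outlier"), na.rm = TRUE),
            sum(d$rot_class %in% c("outlier", "unknown"), na.rm = TRUE),
            if (all(is.na(d$b_mean))) "n/a" else sprintf("%.1f", mean(d$b_mean, na.rm = TRUE)),
            if (all(is.na(d$fit_all))) "n/a" else sprintf("%.3f", mean(d$fit_all, na.rm = TRUE)))
  }, character(1))
  paste0('<section class="report-extra"><h2>Chain summaries</h2><table>',
         "<tr><th>Chain</th><th>Residues</th><th>Ramachandran outliers</th>",
         "<th>Rotamer outliers/unknown</th><th>Mean B</th><th>Mean fit</th></tr>",
         paste(rows, collapse = ""), "</table></section>")
}

report_shell <- function(body, js, compat) {
  paste(c(
    "<!DOCTYPE html>",
    '<html xmlns="http://www.w3.org/1999/xhtml">',
    "<head>",
    '<meta charset="utf-8"/>',
    "<title>Model validation report</title>",
    sprintf("<style>\n%s\n</style>", report_css()),
    "</head>",
    "<body>",
    body,
    if (nzchar(js))
      sprintf("<script>\n/*<![CDATA[*/\n%s\n/*]]>*/\n</script>", js),
    "</body>",
    "</html>"), collapse = "\n")
}

finish_report <- function(html, output_dir) {
  path <- NULL
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    path <- file.path(output_dir, "report.html")
    writeLines(html, path)
  }
  list(html = html, path = path)
}
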