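# Inline assets for the exported report. Everything the document needs ships
# in these strings; there are deliberately no external URLs anywhere.

REPORT_CSS <- r"[
body { font-family: sans-serif; margin: 1.5em; color: #222; }
h1 { font-size: 1.3em; }
h2 { font-size: 1.05em; margin-bottom: 0.2em; }
.meta { color: #555; font-size: 0.85em; margin: 0.15em 0; }
#layout { display: flex; flex-wrap: wrap; gap: 1.5em; }
#controls { margin: 0.6em 0; font-size: 0.9em; }
#controls select { margin: 0 1em 0 0.3em; }
svg { background: #fcfcfc; border: 1px solid #ddd; }
.axis line, .axis path { stroke: #999; stroke-width: 1; }
.axis text { font-size: 10px; fill: #444; }
.thr { stroke: #888; stroke-dasharray: 5 4; }
.qlab { font-size: 10px; fill: #999; }
circle.pt { stroke: #333; stroke-width: 0.5; cursor: pointer; opacity: 0.8; }
circle.pt.sel { stroke: #000; stroke-width: 2; opacity: 1; }
#tooltip { position: absolute; display: none; background: #fff;
  border: 1px solid #888; padding: 6px 8px; font-size: 11px;
  pointer-events: none; box-shadow: 2px 2px 4px rgba(0,0,0,0.2); }
#tooltip td { padding: 0 4px 0 0; }
.legend { font-size: 0.8em; color: #444; }
.swatch { display: inline-block; width: 10px; height: 10px;
  border-radius: 5px; margin: 0 3px 0 10px; }
#detail { min-width: 480px; }
button { font-size: 0.85em; }
]"

REPORT_BODY_HTML <- r"[
<div id="controls"></div>
<div id="layout">
  <div>
    <h2>eDISH: peak transaminase vs peak bilirubin</h2>
    <div id="edish"></div>
    <div class="legend">
      <span class="swatch" style="background:#d62728"></span>ALT and
      bilirubin peaks within the concordance window
      <span class="swatch" style="background:#1f77b4"></span>peaks separated
      beyond the window
    </div>
  </div>
  <div id="detail">
    <h2 id="detail-title">Participant drill-down</h2>
    <p class="meta">Click a point to display the participant profile and the
    hysteresis animation.</p>
    <div id="profile"></div>
    <div id="hyst-controls" style="display:none; margin:0.4em 0;">
      <button id="hyst-play">Play</button>
      <button id="hyst-step">Step</button>
      <span class="meta" id="hyst-frame"></span>
    </div>
    <div id="hysteresis"></div>
  </div>
</div>
<div id="tooltip"></div>
]"

REPORT_JS <- r"[
'use strict';
// SVG namespace taken from a parsed element so the document carries no
// URL literals at all.
const SVGNS = (() => {
  const probe = document.createElement('div');
  probe.innerHTML = '<svg></svg>';
  return probe.firstChild.namespaceURI;
})();
const COL_IN = '#d62728', COL_OUT = '#1f77b4';
const ANCOL = {ALT: '#1b9e77', AST: '#d95f02', ALP: '#7570b3', TB: '#e7298a',
               R: '#666666'};
const pts = EDISH.points, tips = EDISH.tips;

function el(tag, attrs, parent) {
  const node = document.createElementNS(SVGNS, tag);
  for (const k in attrs) node.setAttribute(k, attrs[k]);
  if (parent) parent.appendChild(node);
  return node;
}
function scaleFor(lo, hi, r0, r1, log) {
  if (log) {
    const a = Math.log10(lo), b = Math.log10(hi);
    return v => r0 + (Math.log10(Math.max(v, 1e-9)) - a) / (b - a) * (r1 - r0);
  }
  return v => r0 + (v - lo) / (hi - lo) * (r1 - r0);
}
function logTicks(lo, hi) {
  const out = [];
  for (let e = Math.floor(Math.log10(lo)); e <= Math.ceil(Math.log10(hi)); e++)
    for (const m of [1, 2, 5]) {
      const v = m * Math.pow(10, e);
      if (v >= lo * 0.999 && v <= hi * 1.001) out.push(v);
    }
  return out;
}
function linTicks(lo, hi) {
  const span = hi - lo, step = Math.pow(10, Math.floor(Math.log10(span / 4)));
  const out = [];
  for (let v = Math.ceil(lo / step) * step; v <= hi; v += step)
    out.push(+v.toPrecision(8));
  return out.filter((v, i) => out.length <= 8 || i % 2 === 0);
}
function fmtTick(v) { return v < 0.01 || v >= 1000 ? v.toExponential(0) : +v.toPrecision(3); }

function drawAxes(svg, sx, sy, xt, yt, W, H, M, xlab, ylab) {
  const ax = el('g', {class: 'axis'}, svg);
  el('path', {d: `M${M.l},${H - M.b}H${W - M.r}`, fill: 'none',
              stroke: '#999'}, ax);
  el('path', {d: `M${M.l},${M.t}V${H - M.b}`, fill: 'none', stroke: '#999'},
     ax);
  for (const v of xt) {
    const x = sx(v);
    el('line', {x1: x, x2: x, y1: H - M.b, y2: H - M.b + 4, stroke: '#999'}, ax);
    const t = el('text', {x: x, y: H - M.b + 14, 'text-anchor': 'middle'}, ax);
    t.textContent = fmtTick(v);
  }
  for (const v of yt) {
    const y = sy(v);
    el('line', {x1: M.l - 4, x2: M.l, y1: y, y2: y, stroke: '#999'}, ax);
    const t = el('text', {x: M.l - 6, y: y + 3, 'text-anchor': 'end'}, ax);
    t.textContent = fmtTick(v);
  }
  const tx = el('text', {x: (M.l + W - M.r) / 2, y: H - 4,
                         'text-anchor': 'middle'}, ax);
  tx.textContent = xlab;
  const ty = el('text', {x: 10, y: (M.t + H - M.b) / 2, 'text-anchor': 'middle',
    transform: `rotate(-90 10 ${(M.t + H - M.b) / 2})`}, ax);
  ty.textContent = ylab;
}

let selectedId = null;
function renderEdish() {
  const host = document.getElementById('edish');
  host.innerHTML = '';
  const W = 560, H = 440, M = {l: 55, r: 15, t: 15, b: 40};
  const svg = el('svg', {width: W, height: H});
  host.appendChild(svg);
  const log = EDISH.axes.log;
  const valid = pts.filter(p => p.x != null && p.y != null);
  const xs = valid.map(p => p.x).concat([EDISH.thresholds.x]);
  const ys = valid.map(p => p.y).concat([EDISH.thresholds.y]);
  const xlo = Math.min(...xs) * (log ? 0.7 : 0.9),
        xhi = Math.max(...xs) * 1.25,
        ylo = Math.min(...ys) * (log ? 0.7 : 0.9),
        yhi = Math.max(...ys) * 1.25;
  const sx = scaleFor(xlo, xhi, M.l, W - M.r, log);
  const sy = scaleFor(ylo, yhi, H - M.b, M.t, log);
  drawAxes(svg, sx, sy, log ? logTicks(xlo, xhi) : linTicks(xlo, xhi),
           log ? logTicks(ylo, yhi) : linTicks(ylo, yhi),
           W, H, M, EDISH.axes.xlab, EDISH.axes.ylab);
  el('line', {x1: sx(EDISH.thresholds.x), x2: sx(EDISH.thresholds.x),
              y1: M.t, y2: H - M.b, class: 'thr'}, svg);
  el('line', {x1: M.l, x2: W - M.r, y1: sy(EDISH.thresholds.y),
              y2: sy(EDISH.thresholds.y), class: 'thr'}, svg);
  const lab = [['possible Hy&apos;s Law', W - M.r - 4, M.t + 12, 'end'],
               ['hyperbilirubinemia', M.l + 4, M.t + 12, 'start'],
               ['Temple&apos;s corollary', W - M.r - 4, H - M.b - 6, 'end'],
               ['within range', M.l + 4, H - M.b - 6, 'start']];
  for (const q of lab) {
    const t = el('text', {x: q[1], y: q[2], 'text-anchor': q[3],
                          class: 'qlab'}, svg);
    t.innerHTML = q[0];
  }
  const tooltip = document.getElementById('tooltip');
  valid.forEach((p, i) => {
    const c = el('circle', {cx: sx(p.x), cy: sy(p.y),
      r: 3 + 5 * (p.size - 0.5), class: 'pt',
      fill: p.within_window ? COL_IN : COL_OUT,
      'data-id': p.subject_id}, svg);
    c.addEventListener('mousemove', ev => {
      const tip = tips.find(t => t.subject === p.subject_id);
      let rows = '';
      for (const k in tip) rows += `<tr><td>${k}</td><td><b>${tip[k]}</b></td></tr>`;
      tooltip.innerHTML = `<table>${rows}</table>`;
      tooltip.style.display = 'block';
      tooltip.style.left = (ev.pageX + 12) + 'px';
      tooltip.style.top = (ev.pageY + 12) + 'px';
    });
    c.addEventListener('mouseleave', () => tooltip.style.display = 'none');
    c.addEventListener('click', () => selectSubject(p.subject_id));
  });
  applyFilters();
}

function renderControls() {
  const host = document.getElementById('controls');
  const dims = Object.assign({}, EDISH.filters,
    {quadrant: [...new Set(pts.map(p => p.quadrant))].sort()});
  for (const dim in dims) {
    const label = document.createElement('label');
    label.textContent = 'Filter ' + dim + ':';
    const select = document.createElement('select');
    select.id = 'filter-' + dim;
    select.dataset.dim = dim;
    const all = document.createElement('option');
    all.value = ''; all.textContent = 'all';
    select.appendChild(all);
    for (const v of dims[dim]) {
      const o = document.createElement('option');
      o.value = v; o.textContent = v;
      select.appendChild(o);
    }
    select.addEventListener('change', applyFilters);
    label.appendChild(select);
    host.appendChild(label);
  }
}
function applyFilters() {
  const selects = document.querySelectorAll('#controls select');
  document.querySelectorAll('circle.pt').forEach(c => {
    const p = pts.find(q => q.subject_id === c.getAttribute('data-id'));
    let show = true;
    selects.forEach(s => {
      if (s.value !== '' && String(p[s.dataset.dim]) !== s.value) show = false;
    });
    c.style.display = show ? '' : 'none';
  });
}

function drawSeriesChart(hostId, seriesList, xlab, ylab) {
  const host = document.getElementById(hostId);
  host.innerHTML = '';
  const W = 460, H = 260, M = {l: 50, r: 70, t: 12, b: 36};
  const svg = el('svg', {width: W, height: H});
  host.appendChild(svg);
  const allX = [], allY = [];
  for (const s of seriesList)
    for (let i = 0; i < s.days.length; i++) {
      allX.push(s.days[i]); allY.push(s.vals[i]);
    }
  if (!allX.length) return;
  const sx = scaleFor(Math.min(...allX), Math.max(...allX) || 1,
                      M.l, W - M.r, false);
  const ylo = Math.min(...allY, 0.1) * 0.8, yhi = Math.max(...allY, 1) * 1.3;
  const sy = scaleFor(ylo, yhi, H - M.b, M.t, true);
  drawAxes(svg, sx, sy, linTicks(Math.min(...allX), Math.max(...allX) || 1),
           logTicks(ylo, yhi), W, H, M, xlab, ylab);
  let li = 0;
  for (const s of seriesList) {
    if (!s.days.length) { li++; continue; }
    let d = '';
    for (let i = 0; i < s.days.length; i++)
      d += (i ? 'L' : 'M') + sx(s.days[i]) + ',' + sy(s.vals[i]);
    el('path', {d: d, fill: 'none', stroke: s.col, 'stroke-width': 1.5,
                'stroke-dasharray': s.dash || 'none'}, svg);
    for (let i = 0; i < s.days.length; i++)
      el('circle', {cx: sx(s.days[i]), cy: sy(s.vals[i]), r: 2.2,
                    fill: s.col}, svg);
    const t = el('text', {x: W - M.r + 6, y: M.t + 12 + 14 * li,
                          fill: s.col, 'font-size': 10}, svg);
    t.textContent = s.name;
    li++;
  }
}

let hystTimer = null, hystFrame = 0;
function renderHysteresis(id) {
  const path = EDISH.paths[id];
  const controls = document.getElementById('hyst-controls');
  const host = document.getElementById('hysteresis');
  host.innerHTML = '';
  if (!path || !path.days.length) { controls.style.display = 'none'; return; }
  controls.style.display = '';
  hystFrame = path.days.length;
  drawHystFrame(id);
}
function drawHystFrame(id) {
  const path = EDISH.paths[id];
  const host = document.getElementById('hysteresis');
  host.innerHTML = '';
  const W = 460, H = 280, M = {l: 50, r: 20, t: 12, b: 36};
  const svg = el('svg', {width: W, height: H});
  host.appendChild(svg);
  const xlo = Math.min(...path.alt, EDISH.config.alt_fold_threshold) * 0.7,
        xhi = Math.max(...path.alt, EDISH.config.alt_fold_threshold) * 1.3,
        ylo = Math.min(...path.tb, EDISH.config.tb_fold_threshold) * 0.7,
        yhi = Math.max(...path.tb, EDISH.config.tb_fold_threshold) * 1.3;
  const sx = scaleFor(xlo, xhi, M.l, W - M.r, true);
  const sy = scaleFor(ylo, yhi, H - M.b, M.t, true);
  drawAxes(svg, sx, sy, logTicks(xlo, xhi), logTicks(ylo, yhi), W, H, M,
           'ALT (fold ULN)', 'Bilirubin (fold ULN)');
  el('line', {x1: sx(EDISH.config.alt_fold_threshold),
              x2: sx(EDISH.config.alt_fold_threshold),
              y1: M.t, y2: H - M.b, class: 'thr'}, svg);
  el('line', {x1: M.l, x2: W - M.r, y1: sy(EDISH.config.tb_fold_threshold),
              y2: sy(EDISH.config.tb_fold_threshold), class: 'thr'}, svg);
  const k = Math.max(1, Math.min(hystFrame, path.days.length));
  let d = '';
  for (let i = 0; i < k; i++)
    d += (i ? 'L' : 'M') + sx(path.alt[i]) + ',' + sy(path.tb[i]);
  el('path', {d: d, fill: 'none', stroke: '#555', 'stroke-width': 1.2}, svg);
  for (let i = 0; i < k; i++)
    el('circle', {cx: sx(path.alt[i]), cy: sy(path.tb[i]),
                  r: i === k - 1 ? 5 : 2.5,
                  fill: i === k - 1 ? '#d62728' : '#999'}, svg);
  document.getElementById('hyst-frame').textContent =
    `day ${path.days[k - 1]} (frame ${k}/${path.days.length})`;
}
document.getElementById('hyst-step').addEventListener('click', () => {
  if (!selectedId) return;
  const n = EDISH.paths[selectedId].days.length;
  hystFrame = hystFrame % n + 1;
  drawHystFrame(selectedId);
});
document.getElementById('hyst-play').addEventListener('click', () => {
  if (!selectedId) return;
  if (hystTimer) { clearInterval(hystTimer); hystTimer = null; return; }
  hystFrame = 0;
  const n = EDISH.paths[selectedId].days.length;
  hystTimer = setInterval(() => {
    hystFrame++;
    drawHystFrame(selectedId);
    if (hystFrame >= n) { clearInterval(hystTimer); hystTimer = null; }
  }, 600);
});

function selectSubject(id) {
  selectedId = id;
  document.querySelectorAll('circle.pt').forEach(c =>
    c.classList.toggle('sel', c.getAttribute('data-id') === id));
  document.getElementById('detail-title').textContent =
    'Participant ' + id;
  const prof = EDISH.profiles[id];
  if (prof) {
    const seriesList = [];
    for (const an of ['ALT', 'AST', 'ALP', 'TB'])
      seriesList.push({name: an, col: ANCOL[an],
                       days: prof.series[an].days,
                       vals: prof.series[an].folds});
    seriesList.push({name: 'R ratio', col: ANCOL.R, dash: '4 3',
                     days: prof.r.days, vals: prof.r.ratios});
    drawSeriesChart('profile', seriesList, 'Study day', 'Fold ULN / ratio');
  }
  renderHysteresis(id);
}

renderControls();
renderEdish();
]"
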