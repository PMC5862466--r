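# SVG gauge: the three probabilities (pre-test, post-test, threshold) on a
# logarithmic probability axis styled as a mechanical gauge, plus a
# fixed-width plain-text fallback. All geometry lives in gauge_spec(); output
# is byte-deterministic for identical inputs.

#' Gauge geometry and styling
#'
#' The axis maps probability onto the arc affinely in `log10(p)`, from
#' `min_probability` at `start_angle` to 1 at `end_angle`. Probabilities
#' below `min_probability` (including an exact 0 from a perfectly sensitive
#' negative test) clamp to the axis start; a log scale cannot show zero, so
#' the needle label then reads "~0".
#'
#' @param min_probability Lower axis clamp, in `(0, 1)`.
#' @param ticks Strictly increasing tick probabilities within
#'   `[min_probability, 1]`.
#' @param start_angle,end_angle Arc angles in degrees (mathematical
#'   convention: counter-clockwise from the positive x axis).
#' @param zone_colors Named colors for the three zones.
#' @param width,height,cx,cy,radius Canvas and arc geometry in pixels.
#' @return An object of class `sah_gauge_spec`.
#' @export
gauge_spec <- function(min_probability = 1e-4,
                       ticks = c(1e-4, 1e-3, 1e-2, 1e-1, 1),
                       start_angle = 210, end_angle = -30,
                       zone_colors = c(green = "#2e8b57",
                                       yellow = "#e0a800",
                                       red = "#c0392b"),
                       width = 480, height = 340,
                       cx = 240, cy = 210, radius = 150) {
  stopifnot(min_probability > 0, min_probability < 1,
            all(diff(ticks) > 0), ticks[1] >= min_probability,
            ticks[length(ticks)] <= 1,
            start_angle != end_angle,
            all(c("green", "yellow", "red") %in% names(zone_colors)))
  structure(
    list(min_probability = min_probability, ticks = ticks,
         start_angle = start_angle, end_angle = end_angle,
         zone_colors = zone_colors, width = width, height = height,
         cx = cx, cy = cy, radius = radius),
    class = "sah_gauge_spec"
  )
}

#' Map a probability onto the gauge arc
#'
#' Affine in `log10(p)`: `min_probability` maps to `start_angle`, 1 maps to
#' `end_angle`, and values below the clamp map to the axis start. Vectorised.
#'
#' @param p Probabilities in `[0, 1]`.
#' @param spec A [gauge_spec()].
#' @return Angle(s) in degrees.
#' @export
probability_to_angle <- function(p, spec = gauge_spec()) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("probabilities must lie in [0, 1]")
  }
  p <- pmax(p, spec$min_probability)
  frac <- (log10(p) - log10(spec$min_probability)) / -log10(spec$min_probability)
  spec$start_angle + frac * (spec$end_angle - spec$start_angle)
}

# Angular geometry shared by the renderer and its tests: needle angle and the
# zone arc boundaries in probability and angle space.
#' Gauge geometry for an estimate/recommendation pair
#'
#' Exposes the angular layout the renderer draws: the needle angle at the
#' post-test probability, the pre-test marker angle, and for each zone its
#' probability span and arc span. Zone boundaries sit at
#' `threshold / yellow_band_ratio` and `threshold * yellow_band_ratio`
#' mapped through [probability_to_angle()].
#'
#' @param estimate An `sah_estimate`.
#' @param rec An `sah_recommendation`.
#' @param spec A [gauge_spec()].
#' @param yellow_band_ratio Multiplicative half-width of the yellow zone.
#' @return List with `needle_angle`, `pretest_angle`, `threshold_angle`, and
#'   `zones` (data frame: zone, p_low, p_high, angle_low, angle_high).
#' @export
gauge_geometry <- function(estimate, rec, spec = gauge_spec(),
                           yellow_band_ratio = 3) {
  thr <- rec$threshold
  lo <- max(thr / yellow_band_ratio, spec$min_probability)
  hi <- min(thr * yellow_band_ratio, 1)
  zones <- data.frame(
    zone = c("red", "yellow", "green"),
    p_low = c(spec$min_probability, lo, hi),
    p_high = c(lo, hi, 1),
    stringsAsFactors = FALSE
  )
  zones$angle_low <- probability_to_angle(zones$p_low, spec)
  zones$angle_high <- probability_to_angle(zones$p_high, spec)
  list(
    needle_angle = probability_to_angle(rec$posttest, spec),
    pretest_angle = probability_to_angle(rec$pretest, spec),
    threshold_angle = probability_to_angle(thr, spec),
    zones = zones
  )
}

polar_xy <- function(spec, angle, r = spec$radius) {
  c(x = spec$cx + r * cos(angle * pi / 180),
    y = spec$cy - r * sin(angle * pi / 180))
}

fmt_px <- function(x) sprintf("%.3f", x)

arc_path <- function(spec, a1, a2, r = spec$radius) {
  p1 <- polar_xy(spec, a1, r)
  p2 <- polar_xy(spec, a2, r)
  large <- if (abs(a1 - a2) > 180) 1 else 0
  sweep <- if (a2 < a1) 1 else 0  # decreasing math angle = clockwise on screen
  sprintf("M %s %s A %s %s 0 %d %d %s %s",
          fmt_px(p1["x"]), fmt_px(p1["y"]), fmt_px(r), fmt_px(r),
          large, sweep, fmt_px(p2["x"]), fmt_px(p2["y"]))
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

# Wrap the narrative into lines that fit the canvas.
wrap_lines <- function(text, width = 76) {
  strwrap(text, width = width)
}

#' Render the gauge as an SVG document
#'
#' Emits a standalone SVG 1.1 document: the three zone arcs spanning the
#' threshold-band boundaries, a needle at the post-test probability, a marker
#' at the pre-test probability, a threshold tick, labelled axis ticks, and
#' the recommendation narrative. Rendering is pure text generation, so two
#' renders of the same input are byte-identical.
#'
#' @param estimate An `sah_estimate`.
#' @param rec An `sah_recommendation` for the same patient.
#' @param spec A [gauge_spec()].
#' @param yellow_band_ratio Multiplicative half-width of the yellow zone;
#'   must match the registry value used to produce `rec`.
#' @return The SVG document as a single character string.
#' @export
render_gauge <- function(estimate, rec, spec = gauge_spec(),
                         yellow_band_ratio = 3) {
  stopifnot(inherits(estimate, "sah_estimate"),
            inherits(rec, "sah_recommendation"),
            inherits(spec, "sah_gauge_spec"))
  geo <- gauge_geometry(estimate, rec, spec, yellow_band_ratio)
  out <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" version="1.1" width="%d" height="%d" viewBox="0 0 %d %d">',
            spec$width, spec$height, spec$width, spec$height),
    sprintf('<rect width="%d" height="%d" fill="#fafafa"/>', spec$width, spec$height),
    '<g font-family="monospace" font-size="12">'
  )
  for (i in seq_len(nrow(geo$zones))) {
    z <- geo$zones[i, ]
    if (z$p_high <= z$p_low) next
    out <- c(out, sprintf(
      '<path d="%s" fill="none" stroke="%s" stroke-width="22" stroke-linecap="butt"/>',
      arc_path(spec, z$angle_low, z$angle_high),
      spec$zone_colors[[z$zone]]))
  }
  # axis ticks and labels
  for (tp in spec$ticks) {
    a <- probability_to_angle(tp, spec)
    p1 <- polar_xy(spec, a, spec$radius - 14)
    p2 <- polar_xy(spec, a, spec$radius + 14)
    lab <- polar_xy(spec, a, spec$radius + 30)
    out <- c(out,
      sprintf('<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="#333" stroke-width="1"/>',
              fmt_px(p1["x"]), fmt_px(p1["y"]), fmt_px(p2["x"]), fmt_px(p2["y"])),
      sprintf('<text x="%s" y="%s" text-anchor="middle">%s</text>',
              fmt_px(lab["x"]), fmt_px(lab["y"]), xml_escape(format_prob(tp))))
  }
  # threshold marker
  tmark1 <- polar_xy(spec, geo$threshold_angle, spec$radius - 22)
  tmark2 <- polar_xy(spec, geo$threshold_angle, spec$radius + 18)
  out <- c(out, sprintf(
    '<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="#000" stroke-width="2" stroke-dasharray="4 3"/>',
    fmt_px(tmark1["x"]), fmt_px(tmark1["y"]),
    fmt_px(tmark2["x"]), fmt_px(tmark2["y"])))
  # pre-test marker
  pm <- polar_xy(spec, geo$pretest_angle, spec$radius + 6)
  out <- c(out, sprintf(
    '<circle cx="%s" cy="%s" r="5" fill="none" stroke="#1f5fa8" stroke-width="2"/>',
    fmt_px(pm["x"]), fmt_px(pm["y"])))
  # needle at post-test
  np <- polar_xy(spec, geo$needle_angle, spec$radius - 26)
  out <- c(out,
    sprintf('<line x1="%d" y1="%d" x2="%s" y2="%s" stroke="#111" stroke-width="3"/>',
            spec$cx, spec$cy, fmt_px(np["x"]), fmt_px(np["y"])),
    sprintf('<circle cx="%d" cy="%d" r="6" fill="#111"/>', spec$cx, spec$cy))
  post_lab <- if (rec$posttest < spec$min_probability) "~0"
              else format_prob(rec$posttest)
  out <- c(out,
    sprintf('<text x="%d" y="%d" text-anchor="middle" font-size="16">post-test %s | pre-test %s | threshold %s</text>',
            spec$cx, spec$cy + 40, xml_escape(post_lab),
            xml_escape(format_prob(rec$pretest)),
            xml_escape(format_prob(rec$threshold))),
    sprintf('<text x="%d" y="%d" text-anchor="middle" font-size="14" fill="%s">zone %s%s</text>',
            spec$cx, spec$cy + 60, spec$zone_colors[[rec$zone]],
            toupper(rec$zone),
            if (rec$terminal) " (positive imaging: LP question moot)" else ""))
  yy <- spec$cy + 82
  for (line in wrap_lines(rec$narrative)) {
    out <- c(out, sprintf('<text x="%d" y="%d" text-anchor="middle" font-size="10">%s</text>',
                          spec$cx, yy, xml_escape(line)))
    yy <- yy + 13
  }
  out <- c(out, "</g>", "</svg>")
  paste(out, collapse = "\n")
}

#' Write the gauge SVG to a file
#'
#' @inheritParams render_gauge
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gauge <- function(estimate, rec, path, spec = gauge_spec(),
                        yellow_band_ratio = 3) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeBin(charToRaw(render_gauge(estimate, rec, spec, yellow_band_ratio)), con)
  invisible(path)
}

#' Plain-text report alternative to the SVG gauge
#'
#' Fixed-width rendering of the three probabilities and the zone, for
#' terminals and logs.
#'
#' @inheritParams render_gauge
#' @return A character vector of report lines.
#' @export
render_text_report <- function(estimate, rec) {
  c("SAH lumbar-puncture decision report",
    "-----------------------------------",
    sprintf("  pre-test probability : %10s", format_prob(rec$pretest)),
    sprintf("  post-test probability: %10s", format_prob(rec$posttest)),
    sprintf("  testing threshold    : %10s  (difficulty %g)",
            format_prob(rec$threshold), rec$difficulty),
    sprintf("  zone                 : %10s%s", toupper(rec$zone),
            if (rec$terminal) "  [positive imaging: LP moot]" else ""),
    "",
    strwrap(rec$narrative, width = 72, prefix = "  "))
}
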