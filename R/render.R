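# Glyph chart: one cluster per subject — a large circle for the primary
# outcome and small circles for the secondaries, colored by response status —
# laid out in one panel per arm and written as standalone SVG.

#' Glyph chart style
#'
#' Colors, radii and labelling for the per-subject glyph chart. The four
#' status colors must be pairwise distinct and the secondary radius ratio must
#' stay below 1 so the primary circle visibly dominates. Coordinates are SVG
#' user units with y increasing downward.
#'
#' @param color_improved,color_no_change,color_worsened,color_missing Hex fill
#'   colors for the four statuses (defaults: green, yellow, red, gray).
#' @param palette Optional named list/vector (`improved`, `no_change`,
#'   `worsened`, `missing`) overriding the individual color arguments, as used
#'   by config files.
#' @param primary_radius Radius of the primary-outcome circle (default 12).
#' @param secondary_radius_ratio Secondary radius as a fraction of the primary
#'   radius, in (0, 1) (default 0.45).
#' @param label_mode `"none"` or `"text"`: short text labels inside circles
#'   identifying outcomes (stands in for pictogram artwork).
#' @param cluster_gap Blank space between neighbouring subject clusters.
#' @return An object of class `glyph_style`.
#' @export
glyph_style <- function(color_improved = "#1E8F4E", color_no_change = "#F2C200",
                        color_worsened = "#D7301F", color_missing = "#BDBDBD",
                        palette = NULL, primary_radius = 12,
                        secondary_radius_ratio = 0.45,
                        label_mode = c("none", "text"), cluster_gap = 10) {
  if (!is.null(palette)) {
    palette <- as.list(palette)
    if (!is.null(palette$improved)) color_improved <- palette$improved
    if (!is.null(palette$no_change)) color_no_change <- palette$no_change
    if (!is.null(palette$worsened)) color_worsened <- palette$worsened
    if (!is.null(palette$missing)) color_missing <- palette$missing
  }
  cols <- c(color_improved, color_no_change, color_worsened, color_missing)
  if (anyDuplicated(cols)) stop_validation("the four status colors must be pairwise distinct")
  if (!is.numeric(primary_radius) || primary_radius <= 0) {
    stop_validation("'primary_radius' must be > 0")
  }
  if (secondary_radius_ratio <= 0 || secondary_radius_ratio >= 1) {
    stop_validation("'secondary_radius_ratio' must lie strictly between 0 and 1")
  }
  structure(list(color_improved = color_improved, color_no_change = color_no_change,
                 color_worsened = color_worsened, color_missing = color_missing,
                 primary_radius = primary_radius,
                 secondary_radius_ratio = secondary_radius_ratio,
                 label_mode = match.arg(label_mode),
                 cluster_gap = cluster_gap),
            class = "glyph_style")
}

style_fill <- function(style) {
  c(IMPROVED = style$color_improved, NO_CHANGE = style$color_no_change,
    WORSENED = style$color_worsened, MISSING = style$color_missing)
}

check_statuses <- function(statuses) {
  bad <- setdiff(unique(statuses), status_levels())
  if (length(bad) > 0) stop_validation("invalid status value(s): ", paste(bad, collapse = ", "))
  invisible(statuses)
}

# arc radius: keep secondaries clear of the primary and of each other
arc_radius <- function(style, m) {
  r_p <- style$primary_radius
  r_s <- r_p * style$secondary_radius_ratio
  base <- r_p + r_s + 0.3 * r_s
  if (m >= 2) {
    half <- pi / (2 * m)  # half the angular spacing on the 180-degree arc
    base <- max(base, (1.1 * r_s) / sin(half))
  }
  base
}

#' Lay out one subject's glyph cluster
#'
#' The primary-outcome circle sits at the cluster origin; the secondary
#' circles are spread at equal angular spacing along a 180-degree arc below
#' it, far enough out that no two circles of the cluster overlap.
#'
#' @param statuses Character vector of statuses, primary outcome first.
#' @param style A [glyph_style()].
#' @param outcome_names Optional outcome names (same order) recorded in the
#'   geometry and used for text labels.
#' @param origin Length-2 numeric, cluster origin (primary circle center).
#' @return Data frame with one row per circle: `outcome`, `role`, `status`,
#'   `cx`, `cy`, `r`, `fill`, `label`.
#' @export
layout_subject <- function(statuses, style = glyph_style(), outcome_names = NULL,
                           origin = c(0, 0)) {
  if (length(statuses) < 1L) stop_validation("at least one status (the primary) is required")
  check_statuses(statuses)
  if (is.null(outcome_names)) {
    outcome_names <- c("primary", if (length(statuses) > 1)
      paste0("secondary_", seq_len(length(statuses) - 1)))
  }
  fill <- style_fill(style)
  r_p <- style$primary_radius
  r_s <- r_p * style$secondary_radius_ratio
  m <- length(statuses) - 1L
  cx <- origin[1]; cy <- origin[2]
  if (m > 0) {
    rad <- arc_radius(style, m)
    theta <- pi * (seq_len(m) - 0.5) / m  # below the primary: y grows downward
    cx <- c(cx, origin[1] - rad * cos(theta))
    cy <- c(cy, origin[2] + rad * sin(theta))
  }
  labels <- if (style$label_mode == "text") {
    toupper(substr(gsub("[^A-Za-z0-9]", "", outcome_names), 1, 2))
  } else {
    rep("", length(statuses))
  }
  data.frame(outcome = outcome_names,
             role = c("primary", rep("secondary", m)),
             status = statuses, cx = cx, cy = cy,
             r = c(r_p, rep(r_s, m)),
             fill = unname(fill[statuses]),
             label = labels,
             stringsAsFactors = FALSE)
}

cluster_extent <- function(style, n_outcomes) {
  m <- n_outcomes - 1L
  r_p <- style$primary_radius
  r_s <- r_p * style$secondary_radius_ratio
  reach <- if (m > 0) arc_radius(style, m) + r_s else r_p
  list(half_width = max(r_p, reach), top = r_p, bottom = max(r_p, reach))
}

#' Lay out the whole-study glyph chart
#'
#' One panel per arm (in `arm_labels` order, stacked top to bottom); within a
#' panel, subject clusters flow left to right, top to bottom. The layout is a
#' pure function of the classified study, so identical inputs give identical
#' geometry.
#'
#' @param classified A `classified_study` (from [classify_study()] or
#'   [read_classified_csv()]).
#' @param style A [glyph_style()].
#' @param columns_per_panel Clusters per row (default 8, sized so a
#'   40-subject panel fits a printable page).
#' @param sort_by `"id"` (default): subjects ordered by `subject_id`;
#'   `"status"`: by primary-outcome status (improved first), ties by id.
#' @return An object of class `glyph_layout`: `circles` (one row per circle,
#'   with subject, outcome and status), `panels`, `width`, `height`, `style`.
#' @export
layout_study <- function(classified, style = glyph_style(), columns_per_panel = 8,
                         sort_by = c("id", "status")) {
  stopifnot(inherits(classified, "classified_study"))
  sort_by <- match.arg(sort_by)
  columns_per_panel <- as.integer(columns_per_panel)
  if (columns_per_panel < 1L) stop_validation("'columns_per_panel' must be >= 1")
  outs <- classified$outcomes
  prim <- primary_outcome(outs)
  ord_names <- c(prim, setdiff(names(outs), prim))
  st <- classified$statuses
  n_out <- length(ord_names)
  ext <- cluster_extent(style, n_out)
  gap <- style$cluster_gap
  cell_w <- 2 * ext$half_width + gap
  cell_h <- ext$top + ext$bottom + gap
  margin <- 12
  title_h <- 22
  n_panels <- length(classified$arm_labels)
  panel_w <- columns_per_panel * cell_w
  circles <- list()
  panels <- list()
  y0 <- margin
  for (a in classified$arm_labels) {
    rows_arm <- st[st$arm == a, , drop = FALSE]
    o <- order(rows_arm$subject_id)
    if (sort_by == "status" && nrow(rows_arm) > 0) {
      o <- order(match(rows_arm[[prim]], status_levels()), rows_arm$subject_id)
    }
    rows_arm <- rows_arm[o, , drop = FALSE]
    n_a <- nrow(rows_arm)
    n_rows <- max(1L, ceiling(n_a / columns_per_panel))
    panel_h <- title_h + n_rows * cell_h
    panels[[a]] <- data.frame(arm = a, x = margin, y = y0,
                              width = panel_w, height = panel_h,
                              title_x = margin + 4, title_y = y0 + 15,
                              stringsAsFactors = FALSE)
    for (i in seq_len(n_a)) {
      col <- (i - 1L) %% columns_per_panel
      row <- (i - 1L) %/% columns_per_panel
      origin <- c(margin + col * cell_w + cell_w / 2,
                  y0 + title_h + row * cell_h + gap / 2 + ext$top)
      g <- layout_subject(unlist(rows_arm[i, ord_names], use.names = FALSE),
                          style, outcome_names = ord_names, origin = origin)
      g$subject_id <- rows_arm$subject_id[i]
      g$arm <- a
      circles[[length(circles) + 1L]] <- g
    }
    y0 <- y0 + panel_h + margin
  }
  circles <- if (length(circles) > 0) do.call(rbind, circles) else
    data.frame(outcome = character(0), role = character(0), status = character(0),
               cx = numeric(0), cy = numeric(0), r = numeric(0),
               fill = character(0), label = character(0),
               subject_id = character(0), arm = character(0),
               stringsAsFactors = FALSE)
  structure(list(circles = circles, panels = do.call(rbind, unname(panels)),
                 width = 2 * margin + panel_w,
                 height = y0 + 40,  # room for the legend
                 style = style),
            class = "glyph_layout")
}

#' @export
print.glyph_layout <- function(x, ...) {
  cat(sprintf("<glyph_layout> %d circle(s), %d panel(s), canvas %.0f x %.0f\n",
              nrow(x$circles), if (is.null(x$panels)) 0L else nrow(x$panels),
              x$width, x$height))
  invisible(x)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

num <- function(x) formatC(x, format = "f", digits = 2)

#' Render a glyph layout to SVG
#'
#' Writes a standalone SVG 1.1 document. Every subject/outcome circle carries
#' machine-readable `data-subject`, `data-outcome` and `data-status`
#' attributes, so the status matrix can be recovered from the file (see
#' [svg_status_matrix()]). A legend (drawn with rects, so glyph circles remain
#' countable) maps the four colors to the four statuses. Output is
#' deterministic: no timestamps, no random identifiers.
#'
#' @param layout A `glyph_layout` from [layout_study()].
#' @param path Output path.
#' @param title Optional chart title.
#' @return The path, invisibly.
#' @export
render_svg <- function(layout, path, title = NULL) {
  stopifnot(inherits(layout, "glyph_layout"))
  dir_writable(path)
  style <- layout$style
  w <- layout$width; h <- layout$height
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" version="1.1" width="%s" height="%s" viewBox="0 0 %s %s">',
            num(w), num(h), num(w), num(h)),
    '<rect x="0" y="0" width="100%" height="100%" fill="#FFFFFF"/>'
  )
  if (!is.null(title)) {
    lines <- c(lines, sprintf(
      '<text x="%s" y="%s" font-family="sans-serif" font-size="14" font-weight="bold">%s</text>',
      num(8), num(14), xml_escape(title)))
  }
  if (!is.null(layout$panels)) {
    for (i in seq_len(nrow(layout$panels))) {
      p <- layout$panels[i, ]
      lines <- c(lines,
        sprintf('<rect class="panel" x="%s" y="%s" width="%s" height="%s" fill="none" stroke="#CCCCCC"/>',
                num(p$x), num(p$y), num(p$width), num(p$height)),
        sprintf('<text class="panel-title" x="%s" y="%s" font-family="sans-serif" font-size="13">%s</text>',
                num(p$title_x), num(p$title_y), xml_escape(p$arm)))
    }
  }
  cc <- layout$circles
  for (i in seq_len(nrow(cc))) {
    lines <- c(lines, sprintf(
      '<circle cx="%s" cy="%s" r="%s" fill="%s" stroke="#333333" stroke-width="0.5" data-subject="%s" data-outcome="%s" data-status="%s"/>',
      num(cc$cx[i]), num(cc$cy[i]), num(cc$r[i]), cc$fill[i],
      xml_escape(cc$subject_id[i]), xml_escape(cc$outcome[i]), cc$status[i]))
    if (nzchar(cc$label[i])) {
      lines <- c(lines, sprintf(
        '<text x="%s" y="%s" font-family="sans-serif" font-size="%s" text-anchor="middle" dominant-baseline="central">%s</text>',
        num(cc$cx[i]), num(cc$cy[i]), num(0.8 * cc$r[i]), xml_escape(cc$label[i])))
    }
  }
  # legend: rects, not circles, so circle count == classified cells
  fill <- style_fill(style)
  leg_y <- h - 26
  x <- 14
  lines <- c(lines, '<g id="legend">')
  leg_labels <- c(IMPROVED = "Improved", NO_CHANGE = "No change",
                  WORSENED = "Worsened", MISSING = "Missing data")
  for (s in status_levels()) {
    lines <- c(lines,
      sprintf('<rect class="legend-swatch" x="%s" y="%s" width="12" height="12" fill="%s" data-status="%s"/>',
              num(x), num(leg_y), fill[[s]], s),
      sprintf('<text x="%s" y="%s" font-family="sans-serif" font-size="11">%s</text>',
              num(x + 16), num(leg_y + 10), leg_labels[[s]]))
    x <- x + 16 + 7 * nchar(leg_labels[[s]]) + 18
  }
  lines <- c(lines, '</g>', '</svg>')
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Recover the status matrix from a rendered SVG
#'
#' Reads back the `data-subject` / `data-outcome` / `data-status` attributes
#' of every glyph circle, making the chart invertible (up to the numeric
#' values) for verification.
#'
#' @param path Path to an SVG written by [render_svg()].
#' @return Data frame with columns `subject_id`, `outcome`, `status`, one row
#'   per circle.
#' @export
svg_status_matrix <- function(path) {
  if (!file.exists(path)) stop_io("SVG file not found: ", path)
  doc <- xml2::read_xml(path)
  nodes <- xml2::xml_find_all(doc, "//*[local-name()='circle'][@data-status]")
  data.frame(
    subject_id = xml2::xml_attr(nodes, "data-subject"),
    outcome = xml2::xml_attr(nodes, "data-outcome"),
    status = xml2::xml_attr(nodes, "data-status"),
    stringsAsFactors = FALSE
  )
}
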