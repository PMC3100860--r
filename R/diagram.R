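#' Styling for the functional diagram
#'
#' @param zone_colors Exactly three fill colors for the low, moderate and
#'   high annuli (inner to outer).
#' @param figure_size Side length of the square SVG canvas, in pixels.
#' @param labels Draw axis labels?
#' @return A `diagram_style` list.
#' @export
diagram_style <- function(zone_colors = c(low = "#7cb97c", moderate = "#e8d56b",
                                          high = "#d96b5f"),
                          figure_size = 400,
                          labels = TRUE) {
  if (length(zone_colors) != 3) {
    stop_invalid("zone_colors", zone_colors, "must be exactly three colors")
  }
  structure(list(zone_colors = unname(zone_colors),
                 figure_size = figure_size,
                 labels = isTRUE(labels)),
            class = "diagram_style")
}

fmt_px <- function(x) sprintf("%.3f", x)

#' Render a functional diagram to an SVG file
#'
#' Draws the radar chart used to read off a patient's risk profile:
#' concentric low/moderate/high zone annuli with boundaries at radii 1.5
#' and 3.5 (so each integer score sits strictly inside its zone), one
#' labelled spoke per axis (axis 1 pointing up, proceeding clockwise), unit
#' grid rings, and the patient's closed score polygon. The SVG is plain
#' SVG 1.1 text with fixed-precision coordinates and no timestamps, so the
#' output is byte-identical across runs for the same input.
#'
#' @param scores Integer axis scores 0--5; names are used as axis labels
#'   (unnamed scores are labelled `axis1..axisN`).
#' @param path Output file path (`.svg`).
#' @param style A [diagram_style()].
#' @return `path`, invisibly.
#' @examples
#' f <- tempfile(fileext = ".svg")
#' render_diagram(c(bop = 5, pockets = 2, tooth_loss = 0, smoking = 0,
#'                  al_age = 0, diabetic = 0, dental_systemic = 0,
#'                  background = 0), f)
#' @export
render_diagram <- function(scores, path, style = diagram_style()) {
  risk_zone(scores)  # validates 0-5 integers
  if (length(scores) < 3) {
    stop_invalid("scores", scores, "diagram needs >= 3 axes")
  }
  labels <- names(scores) %||% paste0("axis", seq_along(scores))
  n <- length(scores)
  size <- style$figure_size
  c0 <- size / 2
  px <- size / 2 / 5.8  # pixels per score unit, leaving a label margin
  theta <- pi / 2 - 2 * pi * (seq_len(n) - 1) / n
  to_x <- function(r) c0 + r * cos(theta) * px
  to_y <- function(r) c0 - r * sin(theta) * px

  circle <- function(r, fill, stroke = "none", width = 1) {
    sprintf('<circle cx="%s" cy="%s" r="%s" fill="%s" stroke="%s" stroke-width="%s"/>',
            fmt_px(c0), fmt_px(c0), fmt_px(r * px), fill, stroke, fmt_px(width))
  }
  lines <- c(
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" version="1.1" width="%d" height="%d" viewBox="0 0 %d %d">',
            size, size, size, size),
    sprintf('<rect width="%d" height="%d" fill="#ffffff"/>', size, size),
    circle(5, style$zone_colors[3]),
    circle(3.5, style$zone_colors[2]),
    circle(1.5, style$zone_colors[1]),
    vapply(1:5, function(r) circle(r, "none", "#888888", 0.5), character(1)),
    sprintf('<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="#444444" stroke-width="1"/>',
            fmt_px(c0), fmt_px(c0), fmt_px(to_x(5)), fmt_px(to_y(5)))
  )
  if (style$labels) {
    lines <- c(lines, sprintf(
      '<text x="%s" y="%s" font-family="sans-serif" font-size="11" text-anchor="middle">%s</text>',
      fmt_px(to_x(5.45)), fmt_px(to_y(5.45) + 4), labels))
  }
  pts <- paste(sprintf("%s,%s", fmt_px(to_x(scores)), fmt_px(to_y(scores))),
               collapse = " ")
  lines <- c(
    lines,
    sprintf('<polygon points="%s" fill="#3355bb" fill-opacity="0.35" stroke="#223388" stroke-width="2"/>',
            pts),
    "</svg>"
  )
  if (!dir.exists(dirname(path))) {
    rlang::abort(paste0("cannot write diagram: no such directory: ",
                        dirname(path)))
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Render one diagram per patient per model into a directory
#'
#' Files are named `<patient_id>_<model_id>.svg`.
#'
#' @inheritParams score_cohort
#' @param dir Output directory (created if missing).
#' @param style A [diagram_style()].
#' @return Character vector of written file paths, invisibly.
#' @export
render_cohort_diagrams <- function(cohort, model = "modified8", dir,
                                   style = diagram_style()) {
  model <- as_pra_model(model)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  classified <- classify_cohort(cohort, model)
  paths <- purrr::map2_chr(classified$patient_id, classified$scores,
    function(pid, sc) {
      p <- file.path(dir, paste0(pid, "_", model$model_id, ".svg"))
      render_diagram(sc, p, style)
      p
    })
  invisible(paths)
}

#' Plot a functional diagram with ggplot2
#'
#' An on-screen counterpart of [render_diagram()]: zone annuli, spokes and
#' the score polygon as a ggplot object.
#'
#' @inheritParams render_diagram
#' @return A ggplot.
#' @export
plot_functional_diagram <- function(scores, style = diagram_style()) {
  risk_zone(scores)
  labels <- names(scores) %||% paste0("axis", seq_along(scores))
  n <- length(scores)
  theta_fine <- seq(0, 2 * pi, length.out = 181)
  ring <- function(r, zone) tibble::tibble(
    x = r * cos(theta_fine), y = r * sin(theta_fine), zone = zone)
  zones <- dplyr::bind_rows(ring(5, "high"), ring(3.5, "moderate"),
                            ring(1.5, "low"))
  theta <- pi / 2 - 2 * pi * (seq_len(n) - 1) / n
  spokes <- tibble::tibble(x = 5 * cos(theta), y = 5 * sin(theta),
                           label = labels)
  poly <- polygon_vertices(scores)
  ggplot2::ggplot() +
    ggplot2::geom_polygon(data = zones,
                          ggplot2::aes(.data$x, .data$y, fill = .data$zone)) +
    ggplot2::scale_fill_manual(values = stats::setNames(
      style$zone_colors, c("low", "moderate", "high"))) +
    ggplot2::geom_segment(data = spokes,
                          ggplot2::aes(x = 0, y = 0, xend = .data$x,
                                       yend = .data$y),
                          colour = "grey30", linewidth = 0.3) +
    ggplot2::geom_polygon(data = poly, ggplot2::aes(.data$x, .data$y),
                          fill = "#3355bb", alpha = 0.35,
                          colour = "#223388", linewidth = 0.8) +
    ggplot2::geom_text(data = spokes,
                       ggplot2::aes(1.12 * .data$x, 1.12 * .data$y,
                                    label = .data$label), size = 3) +
    ggplot2::coord_fixed(clip = "off") +
    ggplot2::theme_void() +
    ggplot2::labs(fill = "risk zone")
}
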