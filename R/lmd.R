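#' Teaching points for LMD calibration
#'
#' Three landmarks selected in the optical image that are also visible in
#' the LMD live image. The first is the origin: all exported coordinates
#' are recalculated relative to it, so it maps to `(0, 0)`.
#'
#' @param origin,landmark_2,landmark_3 `(x, y)` coordinates in the optical
#'   frame; must be distinct and non-collinear.
#' @return an object of class `"teaching_points"`.
#' @export
teaching_points <- function(origin, landmark_2, landmark_3) {
  pts <- as_points(rbind(origin, landmark_2, landmark_3))
  if (max_triangle_area(pts) <= 1e-9)
    stop("teaching points are collinear (or coincident)")
  structure(list(origin = pts[1, ], landmark_2 = pts[2, ],
                 landmark_3 = pts[3, ]),
            class = "teaching_points")
}

#' Read teaching points from a CSV of 3 rows
#'
#' Columns `x,y`, header required; row 1 is the origin.
#' @param path file path.
#' @return a [teaching_points()] object.
#' @export
read_teaching_points <- function(path) {
  tab <- utils::read.csv(path)
  if (nrow(tab) != 3) stop("teaching point file must have exactly 3 rows")
  teaching_points(as.numeric(tab[1, 1:2]), as.numeric(tab[2, 1:2]),
                  as.numeric(tab[3, 1:2]))
}

#' LMD shape document
#'
#' The content of an LMD-compatible XML file: three integer calibration
#' points (the teaching points relative to the origin) and a list of
#' closed integer shapes, one per ROI polygon.
#'
#' @param calibration_points 3 x 2 integer matrix.
#' @param shapes list of entries `list(segment_id =, vertices =)` with
#'   closed integer vertex matrices.
#' @param global_coordinates logical flag emitted as `GlobalCoordinates`.
#' @return an object of class `"lmd_document"`.
#' @export
lmd_document <- function(calibration_points, shapes = list(),
                         global_coordinates = TRUE) {
  calibration_points <- as_points(calibration_points)
  if (nrow(calibration_points) != 3)
    stop("exactly 3 calibration points are required")
  if (any(calibration_points != round(calibration_points)))
    stop("calibration points must be integers")
  for (s in shapes) {
    v <- s$vertices
    if (nrow(v) < 2 || any(v != round(v)) || any(v[1, ] != v[nrow(v), ]))
      stop("every shape needs a closed integer vertex list")
  }
  structure(list(calibration_points = calibration_points, shapes = shapes,
                 global_coordinates = isTRUE(global_coordinates)),
            class = "lmd_document")
}

#' @export
print.lmd_document <- function(x, ...) {
  cat(sprintf("<lmd_document> %d shape(s), %d total vertices\n",
              length(x$shapes),
              sum(vapply(x$shapes, function(s) nrow(s$vertices), integer(1)))))
  invisible(x)
}

#' Recalculate ROI coordinates relative to the origin teaching point
#'
#' Translates every boundary vertex and the two non-origin teaching points
#' by minus the origin, so the origin itself becomes `(0, 0)`; the results
#' are rounded to integers with `floor(v + 0.5)`. Boundaries must already
#' be in the optical frame (chain transforms with
#' [transform_boundaries()] first). Optionally flips the y axis for
#' instruments expecting y-up coordinates.
#'
#' @param boundaries an [roi_boundary_set()] (optical frame), or a list of
#'   them (one per segment).
#' @param tp a [teaching_points()] object.
#' @param flip_y negate y after recentering (default `FALSE`: y-down image
#'   convention).
#' @return an [lmd_document()].
#' @export
to_lmd_coordinates <- function(boundaries, tp, flip_y = FALSE) {
  stopifnot(inherits(tp, "teaching_points"))
  if (inherits(boundaries, "roi_boundary_set")) boundaries <- list(boundaries)
  sgn <- if (flip_y) c(1, -1) else c(1, 1)
  recenter <- function(p) {
    q <- sweep(as_points(p), 2, tp$origin)
    round_half_up(sweep(q, 2, sgn, `*`))
  }
  calib <- recenter(rbind(tp$origin, tp$landmark_2, tp$landmark_3))
  shapes <- list()
  for (b in boundaries) {
    stopifnot(inherits(b, "roi_boundary_set"))
    for (poly in b$polygons)
      shapes[[length(shapes) + 1]] <-
        list(segment_id = b$segment_id, vertices = recenter(poly))
  }
  lmd_document(calib, shapes)
}

#' Write an LMD document as XML
#'
#' Serializes to the Leica-style import dialect: root `ImageData` holding
#' `GlobalCoordinates`, `X_CalibrationPoint_i` / `Y_CalibrationPoint_i`
#' for i = 1..3, `ShapeCount`, then one `Shape_i` element per shape with
#' `PointCount` and `X_j` / `Y_j` vertex elements. Output bytes are
#' deterministic for a given document.
#'
#' @param doc an [lmd_document()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_lmd_xml <- function(doc, path) {
  stopifnot(inherits(doc, "lmd_document"))
  el <- function(tag, value, ind) sprintf("%s<%s>%s</%s>", ind, tag, value, tag)
  lines <- c('<?xml version="1.0" encoding="UTF-8"?>', "<ImageData>",
             el("GlobalCoordinates", as.integer(doc$global_coordinates), "  "))
  for (i in 1:3) {
    cp <- doc$calibration_points[i, ]
    lines <- c(lines,
               el(sprintf("X_CalibrationPoint_%d", i), format(cp[1], scientific = FALSE), "  "),
               el(sprintf("Y_CalibrationPoint_%d", i), format(cp[2], scientific = FALSE), "  "))
  }
  lines <- c(lines, el("ShapeCount", length(doc$shapes), "  "))
  for (i in seq_along(doc$shapes)) {
    s <- doc$shapes[[i]]
    v <- s$vertices
    lines <- c(lines, sprintf("  <Shape_%d>", i),
               el("PointCount", nrow(v), "    "),
               el("CapID", sprintf("%d", s$segment_id), "    "))
    for (j in seq_len(nrow(v)))
      lines <- c(lines,
                 el(sprintf("X_%d", j), format(v[j, 1], scientific = FALSE), "    "),
                 el(sprintf("Y_%d", j), format(v[j, 2], scientific = FALSE), "    "))
    lines <- c(lines, sprintf("  </Shape_%d>", i))
  }
  lines <- c(lines, "</ImageData>")
  con <- file(path, "wb")  # binary mode: byte-identical output on any OS
  writeLines(lines, con, sep = "\n")
  close(con)
  invisible(path)
}

#' Read an LMD XML file back into a document
#'
#' Inverse of [write_lmd_xml()]; unknown elements are ignored with a
#' warning, and missing calibration points or count mismatches raise a
#' schema error naming the offending element.
#'
#' @param path path to the XML file.
#' @return an [lmd_document()].
#' @export
read_lmd_xml <- function(path) {
  doc <- xml2::read_xml(path)
  if (xml2::xml_name(doc) != "ImageData") stop("root element must be ImageData")
  get1 <- function(node, tag) {
    x <- xml2::xml_find_first(node, paste0("./", tag))
    if (is.na(x)) stop("missing element <", tag, "> in ", path)
    xml2::xml_text(x)
  }
  calib <- t(vapply(1:3, function(i)
    c(as.numeric(get1(doc, sprintf("X_CalibrationPoint_%d", i))),
      as.numeric(get1(doc, sprintf("Y_CalibrationPoint_%d", i)))),
    numeric(2)))
  n_shapes <- as.integer(get1(doc, "ShapeCount"))
  if (is.na(n_shapes)) stop("malformed <ShapeCount>")
  shapes <- vector("list", n_shapes)
  for (i in seq_len(n_shapes)) {
    node <- xml2::xml_find_first(doc, sprintf("./Shape_%d", i))
    if (is.na(node)) stop("ShapeCount is ", n_shapes,
                          " but element <Shape_", i, "> is missing")
    np <- as.integer(get1(node, "PointCount"))
    cap <- xml2::xml_find_first(node, "./CapID")
    seg <- if (is.na(cap)) 1L else as.integer(xml2::xml_text(cap))
    v <- t(vapply(seq_len(np), function(j)
      c(as.numeric(get1(node, sprintf("X_%d", j))),
        as.numeric(get1(node, sprintf("Y_%d", j)))), numeric(2)))
    shapes[[i]] <- list(segment_id = seg, vertices = v)
  }
  known <- c("GlobalCoordinates", "ShapeCount",
             sprintf("X_CalibrationPoint_%d", 1:3),
             sprintf("Y_CalibrationPoint_%d", 1:3),
             sprintf("Shape_%d", seq_len(n_shapes)))
  extra <- setdiff(xml2::xml_name(xml2::xml_children(doc)), known)
  if (length(extra))
    warning("ignoring unknown element(s): ", paste(extra, collapse = ", "))
  lmd_document(calib, shapes,
               as.integer(get1(doc, "GlobalCoordinates")) != 0)
}
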