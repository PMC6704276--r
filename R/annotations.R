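#' Pathologist annotation polygons
#'
#' Tumor (or other region) outlines drawn in a named frame, typically the
#' high-resolution H&E image. Each polygon is a list of `(x, y)` vertices;
#' at least 3 vertices are required.
#'
#' @param polygons list of n x 2 vertex matrices (or coercibles).
#' @param frame frame (or name) the vertices live in.
#' @return an object of class `"annotation_set"`.
#' @export
annotation_set <- function(polygons, frame = "he") {
  polygons <- lapply(polygons, as_points)
  if (length(polygons) < 1) stop("at least one polygon is required")
  nv <- vapply(polygons, nrow, integer(1))
  if (any(nv < 3))
    stop("every annotation polygon needs >= 3 vertices; got ", min(nv))
  structure(list(polygons = polygons, frame = frame_name(frame)),
            class = "annotation_set")
}

#' Read / write annotations as JSON
#'
#' Dialect: `{"frame": "he", "polygons": [[[x, y], ...], ...]}`.
#'
#' @param ann an [annotation_set()].
#' @param path file path.
#' @return `read_annotations()` returns an `annotation_set`;
#'   `write_annotations()` returns `path` invisibly.
#' @export
read_annotations <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  polys <- obj$polygons
  if (is.array(polys) && length(dim(polys)) == 3)  # homogeneous vertex counts
    polys <- lapply(seq_len(dim(polys)[1]), function(i) polys[i, , ])
  annotation_set(polys, obj$frame)
}

#' @rdname read_annotations
#' @export
write_annotations <- function(ann, path) {
  stopifnot(inherits(ann, "annotation_set"))
  jsonlite::write_json(
    list(frame = ann$frame,
         polygons = lapply(ann$polygons, function(p) unname(as.matrix(p)))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Boolean pixel mask
#'
#' A logical raster in a named frame; `values[r, c]` covers the pixel with
#' 0-based coordinates `x = c - 1`, `y = r - 1`.
#'
#' @param values logical matrix (height x width).
#' @param frame frame (or name) of the raster.
#' @return an object of class `"pixel_mask"` (a classed logical matrix).
#' @export
pixel_mask <- function(values, frame = "msi") {
  values <- as.matrix(values)
  storage.mode(values) <- "logical"
  if (any(dim(values) < 1)) stop("mask shape must be positive")
  structure(values, frame = frame_name(frame), class = c("pixel_mask", "matrix"))
}

#' @export
as.matrix.pixel_mask <- function(x, ...) {
  attributes(x) <- list(dim = dim(x))
  x
}

#' @export
print.pixel_mask <- function(x, ...) {
  cat(sprintf("<pixel_mask> %d x %d in frame '%s', %d foreground pixel(s)\n",
              nrow(x), ncol(x), attr(x, "frame"), sum(x)))
  invisible(x)
}

#' Even-odd point-in-polygon test
#'
#' Ray-crossing (even-odd) rule: a point is inside if a horizontal ray from
#' it crosses the polygon edges an odd number of times. Vectorized over
#' points.
#'
#' @param px,py point coordinates.
#' @param poly n x 2 vertex matrix (closing edge implied).
#' @return logical vector.
#' @keywords internal
point_in_polygon <- function(px, py, poly) {
  inside <- logical(length(px))
  n <- nrow(poly)
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Rasterize annotation polygons onto an MSI grid
#'
#' Transforms the annotation vertices into the MSI frame through `chain`
#' (e.g. H&E -> optical composed with optical -> MSI) and marks every grid
#' pixel whose center falls inside at least one polygon under the even-odd
#' rule. The result selects e.g. the tumor-specific MSI pixels.
#'
#' @param ann an [annotation_set()].
#' @param chain an [affine2d()] mapping the annotation frame to the MSI
#'   grid frame; use [affine_identity()] when they coincide.
#' @param grid an [msi_dataset()] supplying the grid dimensions, or a
#'   `c(height, width)` shape.
#' @return a [pixel_mask()] in the MSI frame.
#' @export
rasterize_annotations <- function(ann, chain, grid) {
  stopifnot(inherits(ann, "annotation_set"), inherits(chain, "affine2d"))
  shape <- if (inherits(grid, "msi_dataset")) grid_shape(grid)
           else as.integer(grid)
  h <- shape[1]; w <- shape[2]
  px <- rep(0:(w - 1), each = h)   # column-major over (y, x)
  py <- rep(0:(h - 1), times = w)
  inside <- logical(length(px))
  for (poly in ann$polygons) {
    tp <- transform_points(chain, poly)
    inside <- inside | point_in_polygon(px, py, tp)
  }
  pixel_mask(matrix(inside, nrow = h, ncol = w), chain$target_frame)
}

#' Restrict an MSI dataset to a pixel mask
#'
#' @param ds an [msi_dataset()].
#' @param mask a [pixel_mask()] on the same grid.
#' @return an `msi_dataset` keeping only the pixels whose mask value is
#'   `TRUE`.
#' @export
apply_mask <- function(ds, mask) {
  stopifnot(inherits(ds, "msi_dataset"), inherits(mask, "pixel_mask"))
  keep <- mask[cbind(ds$coords[, 2] + 1, ds$coords[, 1] + 1)]
  keep[is.na(keep)] <- FALSE
  if (!any(keep)) stop("mask removes every pixel")
  msi_dataset(ds$coords[keep, , drop = FALSE],
              ds$spectra[keep, , drop = FALSE], ds$mz, ds$pitch)
}
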