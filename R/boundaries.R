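#' Closed boundary polygons of one segment
#'
#' The external outlines of a segment's connected regions, as produced by
#' [trace_boundaries()]: one closed vertex list per 8-connected component
#' (first vertex repeated last), in pixel coordinates of a named frame.
#'
#' @param polygons list of closed n x 2 vertex matrices.
#' @param segment_id integer id of the segment the outlines belong to.
#' @param frame frame (or name) of the coordinates.
#' @return an object of class `"roi_boundary_set"`.
#' @export
roi_boundary_set <- function(polygons, segment_id = 1L, frame = "msi") {
  polygons <- lapply(polygons, as_points)
  for (p in polygons) {
    if (nrow(p) < 2 || any(p[1, ] != p[nrow(p), ]))
      stop("every boundary polygon must be closed (first vertex repeated last)")
  }
  structure(list(polygons = polygons, segment_id = as.integer(segment_id),
                 frame = frame_name(frame)),
            class = "roi_boundary_set")
}

#' @export
print.roi_boundary_set <- function(x, ...) {
  cat(sprintf("<roi_boundary_set> segment %d, %d polygon(s) in frame '%s'\n",
              x$segment_id, length(x$polygons), x$frame))
  invisible(x)
}

# clockwise Moore neighborhood in image coordinates (x right, y down),
# starting East
moore_dirs <- rbind(c(1, 0), c(1, 1), c(0, 1), c(-1, 1),
                    c(-1, 0), c(-1, -1), c(0, -1), c(1, -1))

# trace the outer boundary of one component (logical matrix), Moore-neighbor
# tracing with backtracking and Jacob's stopping criterion; returns a closed
# polygon of 0-based (x, y) pixel coordinates
trace_one <- function(M) {
  h <- nrow(M); w <- ncol(M)
  fg <- which(M)
  ord <- order((fg - 1) %% h, (fg - 1) %/% h)  # raster scan: row, then col
  s <- fg[ord[1]]
  sy <- (s - 1) %% h; sx <- (s - 1) %/% h      # 0-based
  at <- function(x, y) x >= 0 && x < w && y >= 0 && y < h && M[y + 1, x + 1]
  start <- c(sx, sy)
  b0 <- c(sx - 1, sy)                          # entered from the west
  verts <- list(start)
  cur <- start; bt <- b0
  limit <- 8 * length(fg) + 16
  repeat {
    rel <- bt - cur
    i0 <- which(moore_dirs[, 1] == rel[1] & moore_dirs[, 2] == rel[2])
    found <- FALSE
    for (j in 1:8) {
      idx <- (i0 + j - 1) %% 8 + 1
      cand <- cur + moore_dirs[idx, ]
      if (at(cand[1], cand[2])) {
        prev_idx <- (i0 + j - 2) %% 8 + 1
        new_bt <- cur + moore_dirs[prev_idx, ]
        verts[[length(verts) + 1]] <- cand
        cur <- cand; bt <- new_bt
        found <- TRUE
        break
      }
    }
    if (!found) break                          # isolated pixel
    if (all(cur == start) && all(bt == b0)) break
    limit <- limit - 1
    if (limit <= 0) stop("boundary tracing failed to terminate")
  }
  out <- do.call(rbind, verts)
  if (nrow(out) == 1 || any(out[nrow(out), ] != out[1, ]))
    out <- rbind(out, out[1, ])
  colnames(out) <- c("x", "y")
  out
}

#' Trace the external boundaries of a segment mask
#'
#' Finds the 8-connected foreground components of the mask and traces the
#' outer boundary of each by Moore-neighbor tracing with backtracking
#' (holes are ignored). Vertices are the 0-based pixel coordinates of the
#' boundary pixels in traversal order, closed by repeating the first
#' vertex; an isolated pixel yields the degenerate loop
#' `[(x, y), (x, y)]`.
#'
#' @param mask a [pixel_mask()] or logical matrix.
#' @param segment_id segment id recorded on the result.
#' @return a [roi_boundary_set()] with one polygon per component, in the
#'   mask's frame.
#' @export
trace_boundaries <- function(mask, segment_id = 1L) {
  fr <- attr(mask, "frame"); if (is.null(fr)) fr <- "msi"
  lab <- label_components(mask, connectivity = 8)
  polys <- lapply(seq_len(max(lab, 0)), function(id) trace_one(lab == id))
  structure(list(polygons = polys, segment_id = as.integer(segment_id),
                 frame = fr),
            class = "roi_boundary_set")
}

#' Read / write boundary polygons as JSON
#'
#' Dialect: `{"frame": ..., "segment_id": ..., "polygons": [[[x, y], ...], ...]}`.
#'
#' @param b an [roi_boundary_set()].
#' @param path file path.
#' @return `read_boundaries_json()` returns an `roi_boundary_set`;
#'   the writer returns `path` invisibly.
#' @export
write_boundaries_json <- function(b, path) {
  stopifnot(inherits(b, "roi_boundary_set"))
  jsonlite::write_json(
    list(frame = b$frame, segment_id = b$segment_id,
         polygons = lapply(b$polygons, function(p) unname(as.matrix(p)))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_boundaries_json
#' @export
read_boundaries_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  polys <- obj$polygons
  if (is.array(polys) && length(dim(polys)) == 3)
    polys <- lapply(seq_len(dim(polys)[1]), function(i) polys[i, , ])
  roi_boundary_set(polys, obj$segment_id, obj$frame)
}

#' Transform a boundary set into another frame
#'
#' @param b an [roi_boundary_set()] in `T$source_frame`.
#' @param T an [affine2d()].
#' @return the boundary set with every vertex mapped through `T`, in
#'   `T$target_frame`.
#' @export
transform_boundaries <- function(b, T) {
  stopifnot(inherits(b, "roi_boundary_set"), inherits(T, "affine2d"))
  if (!identical(b$frame, T$source_frame))
    stop(sprintf("boundaries are in frame '%s' but transform starts at '%s'",
                 b$frame, T$source_frame))
  roi_boundary_set(lapply(b$polygons, function(p) transform_points(T, p)),
                   b$segment_id, T$target_frame)
}
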