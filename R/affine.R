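#' 2-D affine transform between two named frames
#'
#' Encodes `x' = a*x + b*y + tx`, `y' = c*x + d*y + ty`, mapping points of
#' `source_frame` into `target_frame`. The transform must be invertible
#' (`a*d - b*c != 0`).
#'
#' @param params numeric vector of the six parameters, in order
#'   `a, b, tx, c, d, ty` (names optional).
#' @param source_frame,target_frame frames (or frame names) the transform
#'   maps between.
#' @return an object of class `"affine2d"`.
#' @seealso [fit_affine()], [transform_points()], [compose_affine()]
#' @examples
#' S <- affine2d(c(2, 0, 2, 0, 2, 3), "msi", "optical")
#' transform_points(S, c(1, 1))   # (4, 5)
#' @export
affine2d <- function(params, source_frame = "source", target_frame = "target") {
  params <- as.numeric(params)
  stopifnot(length(params) == 6, all(is.finite(params)))
  names(params) <- c("a", "b", "tx", "c", "d", "ty")
  det <- params["a"] * params["d"] - params["b"] * params["c"]
  if (abs(det) < 1e-12)
    stop("affine transform is singular (determinant ~ 0)")
  structure(list(params = params,
                 source_frame = frame_name(source_frame),
                 target_frame = frame_name(target_frame)),
            class = "affine2d")
}

#' @export
print.affine2d <- function(x, ...) {
  p <- x$params
  cat(sprintf("<affine2d> %s -> %s\n", x$source_frame, x$target_frame))
  cat(sprintf("  [ %9.4f %9.4f | %9.3f ]\n", p["a"], p["b"], p["tx"]))
  cat(sprintf("  [ %9.4f %9.4f | %9.3f ]\n", p["c"], p["d"], p["ty"]))
  invisible(x)
}

#' Identity transform between two frames
#' @inheritParams affine2d
#' @return an `affine2d` with unit linear part and zero translation.
#' @export
affine_identity <- function(source_frame = "source", target_frame = source_frame)
  affine2d(c(1, 0, 0, 0, 1, 0), source_frame, target_frame)

as_affine_matrix <- function(T) {
  p <- T$params
  matrix(c(p["a"], p["b"], p["tx"],
           p["c"], p["d"], p["ty"],
           0, 0, 1), nrow = 3, byrow = TRUE)
}

#' Control point set for affine fitting
#'
#' Pairs of corresponding landmark coordinates in a source and a target
#' frame, e.g. three manually selected MSI pixels matched to their visible
#' laser-shot landmarks in the optical image. At least 3 non-collinear
#' source points are required for an invertible fit.
#'
#' @param src,dst n x 2 matrices (or coercible) of `(x, y)` coordinates in
#'   the source and target frames; equal row counts.
#' @param source_frame,target_frame the two frames.
#' @return an object of class `"control_points"`.
#' @export
control_points <- function(src, dst, source_frame = "source",
                           target_frame = "target") {
  src <- as_points(src); dst <- as_points(dst)
  if (nrow(src) != nrow(dst))
    stop("source and target point counts differ")
  structure(list(src = src, dst = dst,
                 source_frame = frame_name(source_frame),
                 target_frame = frame_name(target_frame)),
            class = "control_points")
}

#' Read a control point file
#'
#' Delimited text with a header and columns `src_x, src_y, dst_x, dst_y`.
#'
#' @param path file path; the delimiter is sniffed (comma or tab).
#' @inheritParams control_points
#' @return a [control_points()] object.
#' @export
read_control_points <- function(path, source_frame = "source",
                                target_frame = "target") {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep)
  need <- c("src_x", "src_y", "dst_x", "dst_y")
  if (!all(need %in% names(tab)))
    stop("control point file must have columns ", paste(need, collapse = ", "))
  control_points(tab[, c("src_x", "src_y")], tab[, c("dst_x", "dst_y")],
                 source_frame, target_frame)
}

#' Write a control point file
#' @param cp a [control_points()] object.
#' @param path output path (CSV).
#' @return `path`, invisibly.
#' @export
write_control_points <- function(cp, path) {
  tab <- data.frame(src_x = cp$src[, 1], src_y = cp$src[, 2],
                    dst_x = cp$dst[, 1], dst_y = cp$dst[, 2])
  utils::write.table(tab, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# max triangle area over point triples; 0 for collinear point sets
max_triangle_area <- function(pts) {
  n <- nrow(pts)
  # area relative to the first two points spanning the largest baseline is
  # enough to detect collinearity: check all triples only for small n
  best <- 0
  for (i in seq_len(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    a <- pts[i, ]; b <- pts[j, ]; d <- pts[k, ]
    area <- abs((b[1] - a[1]) * (d[2] - a[2]) -
                (d[1] - a[1]) * (b[2] - a[2])) / 2
    if (area > best) best <- area
    if (best > 1e-9) return(best)
  }
  best
}

#' Fit an affine transform to control points
#'
#' Least-squares estimate of the six affine parameters from landmark pairs.
#' With exactly three non-collinear pairs the fit interpolates exactly
#' (zero residuals); with more pairs it minimizes the summed squared
#' target-space residuals. Each output coordinate is a separate linear
#' model in `(x, y, 1)`, solved by QR.
#'
#' @param cp a [control_points()] object, or an n x 2 source matrix when
#'   `dst` is given.
#' @param dst optional target matrix when `cp` is given as raw points.
#' @param source_frame,target_frame frame names used when `cp` is raw
#'   points.
#' @return an [affine2d()] from the source to the target frame.
#' @examples
#' cp <- control_points(rbind(c(0, 0), c(1, 0), c(0, 1)),
#'                      rbind(c(2, 3), c(4, 3), c(2, 5)), "msi", "optical")
#' fit_affine(cp)
#' @export
fit_affine <- function(cp, dst = NULL, source_frame = "source",
                       target_frame = "target") {
  if (!inherits(cp, "control_points"))
    cp <- control_points(cp, dst, source_frame, target_frame)
  n <- nrow(cp$src)
  if (n < 3)
    stop("at least 3 control point pairs are required, got ", n)
  if (max_triangle_area(cp$src) <= 1e-9)
    stop("source control points are collinear; affine fit is degenerate")
  A <- cbind(cp$src, 1)
  fit <- qr.coef(qr(A), cp$dst)  # 3 x 2: columns are (a,b,tx) and (c,d,ty)
  affine2d(c(fit[1, 1], fit[2, 1], fit[3, 1],
             fit[1, 2], fit[2, 2], fit[3, 2]),
           cp$source_frame, cp$target_frame)
}

#' Apply an affine transform to points
#'
#' @param T an [affine2d()].
#' @param points n x 2 matrix (or a single `c(x, y)`, a data frame, or a
#'   list of pairs) of coordinates in `T$source_frame`.
#' @return an n x 2 matrix of coordinates in `T$target_frame`.
#' @export
transform_points <- function(T, points) {
  stopifnot(inherits(T, "affine2d"))
  pts <- as_points(points)
  p <- T$params
  cbind(x = p["a"] * pts[, 1] + p["b"] * pts[, 2] + p["tx"],
        y = p["c"] * pts[, 1] + p["d"] * pts[, 2] + p["ty"])
}

#' Invert an affine transform
#' @param T an [affine2d()].
#' @return the inverse `affine2d`, with source and target frames swapped.
#' @export
affine_inverse <- function(T) {
  stopifnot(inherits(T, "affine2d"))
  M <- solve(as_affine_matrix(T))
  affine2d(c(M[1, 1], M[1, 2], M[1, 3], M[2, 1], M[2, 2], M[2, 3]),
           T$target_frame, T$source_frame)
}

#' Compose two affine transforms
#'
#' `compose_affine(outer, inner)` is the transform applying `inner` first,
#' then `outer` — the usual chaining of registration steps, e.g.
#' MSI -> optical followed by optical -> H&E. The inner target frame must
#' match the outer source frame.
#'
#' @param outer,inner [affine2d()] objects with
#'   `inner$target_frame == outer$source_frame`.
#' @return an `affine2d` from `inner$source_frame` to `outer$target_frame`.
#' @export
compose_affine <- function(outer, inner) {
  stopifnot(inherits(outer, "affine2d"), inherits(inner, "affine2d"))
  if (!identical(inner$target_frame, outer$source_frame))
    stop(sprintf("frame chain broken: inner maps to '%s' but outer starts at '%s'",
                 inner$target_frame, outer$source_frame))
  M <- as_affine_matrix(outer) %*% as_affine_matrix(inner)
  affine2d(c(M[1, 1], M[1, 2], M[1, 3], M[2, 1], M[2, 2], M[2, 3]),
           inner$source_frame, outer$target_frame)
}

#' Serialize / deserialize an affine transform as JSON
#'
#' The JSON object carries the six parameters and both frame names, so a
#' transform fitted on the command line can be reused by later steps.
#'
#' @param T an [affine2d()].
#' @param path file path.
#' @return `write_affine_json()` returns `path` invisibly;
#'   `read_affine_json()` returns an `affine2d`.
#' @export
write_affine_json <- function(T, path) {
  stopifnot(inherits(T, "affine2d"))
  jsonlite::write_json(
    list(source_frame = T$source_frame, target_frame = T$target_frame,
         params = as.list(T$params)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_affine_json
#' @export
read_affine_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  affine2d(unlist(obj$params)[c("a", "b", "tx", "c", "d", "ty")],
           obj$source_frame, obj$target_frame)
}
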