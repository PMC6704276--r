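#' Round half away from zero towards +Inf, per axis
#'
#' MATLAB-style rounding used throughout the pipeline for nearest-pixel
#' warping and integer coordinate export: `floor(v + 0.5)`, so exact halves
#' round up. `base::round()` rounds halves to even and would not be
#' bit-compatible.
#'
#' @param v numeric vector or matrix
#' @return integer-valued numeric of the same shape
#' @keywords internal
round_half_up <- function(v) floor(v + 0.5)

#' Evaluate an expression with a temporary RNG seed
#'
#' Restores the caller's `.Random.seed` afterwards so library functions do
#' not clobber user-level randomness.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Coerce a point list to an n x 2 numeric matrix
#' @keywords internal
#' @noRd
as_points <- function(points) {
  if (is.matrix(points)) {
    stopifnot(ncol(points) == 2)
    return(matrix(as.numeric(points), ncol = 2,
                  dimnames = list(NULL, c("x", "y"))))
  }
  if (is.data.frame(points)) {
    stopifnot(ncol(points) >= 2)
    return(as_points(as.matrix(points[, 1:2])))
  }
  if (is.numeric(points) && length(points) == 2)
    return(matrix(points, ncol = 2, dimnames = list(NULL, c("x", "y"))))
  if (is.list(points))
    return(as_points(do.call(rbind, lapply(points, function(p) p[1:2]))))
  stop("cannot interpret 'points' as (x, y) coordinates")
}
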