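#' Per-step registration error summary
#'
#' Mean and standard deviation of the absolute per-axis deviations (in
#' micrometers) between landmark positions and their co-registered
#' counterparts, as tabulated per co-registration step.
#'
#' @param mean_x,mean_y mean absolute deviation per axis (um).
#' @param sd_x,sd_y standard deviation of the absolute deviations (um).
#' @param n number of landmark measurements.
#' @return an object of class `"registration_error"`.
#' @seealso [estimate_error()], [propagate_errors()]
#' @export
registration_error <- function(mean_x, sd_x, mean_y, sd_y, n = 1L) {
  vals <- c(mean_x = mean_x, sd_x = sd_x, mean_y = mean_y, sd_y = sd_y)
  stopifnot(all(is.finite(vals)), all(vals >= 0), n >= 1)
  structure(c(as.list(vals), list(n = as.integer(n))),
            class = "registration_error")
}

#' @export
print.registration_error <- function(x, ...) {
  cat(sprintf("<registration error, n = %d>\n  x: %.2f +/- %.2f um\n  y: %.2f +/- %.2f um\n",
              x$n, x$mean_x, x$sd_x, x$mean_y, x$sd_y))
  invisible(x)
}

#' Estimate a registration error from landmark deviations
#'
#' Deviations are the signed per-axis offsets (in micrometers) from each
#' landmark to its co-registered position, e.g. read off as optical-image
#' pixels (~2 um each) from the center of a laser-shot landmark to the
#' matched MSI pixel. They are summarized as the mean of the absolute
#' per-axis deviations with the sample standard deviation (n - 1
#' denominator) of those absolute values; the SD is 0 for a single
#' measurement.
#'
#' @param deviations n x 2 matrix (or coercible) of signed `(dx, dy)`
#'   deviations in micrometers.
#' @return a [registration_error()].
#' @examples
#' estimate_error(cbind(c(2, -2, 4), 0))  # mean_x = 8/3, sd_x = sqrt(4/3)
#' @export
estimate_error <- function(deviations) {
  dev <- abs(as_points(deviations))
  n <- nrow(dev)
  if (n < 1) stop("at least one deviation is required")
  sdx <- if (n > 1) stats::sd(dev[, 1]) else 0
  sdy <- if (n > 1) stats::sd(dev[, 2]) else 0
  registration_error(mean(dev[, 1]), sdx, mean(dev[, 2]), sdy, n)
}

#' Mean Euclidean self-consistency distance
#'
#' Quantifies the reproducibility of manual landmark selection: after
#' co-registering an image with itself several times, the error is the mean
#' Euclidean distance between the original and the transformed positions.
#'
#' @param points_a,points_b equal-length n x 2 coordinate matrices.
#' @return mean of `sqrt((ax-bx)^2 + (ay-by)^2)` over rows.
#' @export
self_consistency_error <- function(points_a, points_b) {
  a <- as_points(points_a); b <- as_points(points_b)
  if (nrow(a) != nrow(b)) stop("point lists differ in length")
  if (nrow(a) < 1) stop("at least one point pair is required")
  mean(sqrt(rowSums((a - b)^2)))
}

#' Propagate registration errors across chained steps
#'
#' Worst-case combination assuming additive effects: per axis, the means of
#' the individual steps add linearly, and the standard deviations combine
#' in quadrature (square root of the sum of squares). For the three steps of
#' the MSI -> optical -> H&E -> LMD chain this yields the maximum expected
#' co-registration error of the whole pipeline.
#'
#' @param steps list of [registration_error()] objects (>= 1).
#' @return a [registration_error()] with `n` the number of steps.
#' @examples
#' steps <- list(registration_error(7.89, 4.06, 3.96, 4.32),
#'               registration_error(1.39, 0.33, 1.39, 0.50),
#'               registration_error(3.46, 2.62, 7.39, 3.78))
#' propagate_errors(steps)  # 12.74 +/- 4.84 in x, 12.74 +/- 5.76 in y
#' @export
propagate_errors <- function(steps) {
  if (inherits(steps, "registration_error")) steps <- list(steps)
  if (length(steps) < 1) stop("at least one step is required")
  stopifnot(all(vapply(steps, inherits, TRUE, "registration_error")))
  g <- function(f) vapply(steps, `[[`, numeric(1), f)
  registration_error(sum(g("mean_x")), sqrt(sum(g("sd_x")^2)),
                     sum(g("mean_y")), sqrt(sum(g("sd_y")^2)),
                     n = length(steps))
}
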