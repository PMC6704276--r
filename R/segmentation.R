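#' Non-negative matrix factorization by multiplicative updates
#'
#' Factorizes a non-negative pixel x channel matrix `X ~ W H` with
#' `W >= 0` (n_pixels x k scores) and `H >= 0` (k x n_channels basis
#' spectra), minimizing the Frobenius reconstruction error with the
#' classical multiplicative update rules. Initialization is uniform random
#' non-negative, derived from `seed`; with `restarts > 1` the run with the
#' lowest final loss is kept.
#'
#' @param X non-negative numeric matrix (pixels x channels).
#' @param k number of components, `1 <= k <= min(dim(X))`.
#' @param seed integer seed; the fit is reproducible given `seed`.
#' @param max_iter maximum number of update sweeps.
#' @param tol stop when the relative loss improvement per sweep falls below
#'   this.
#' @param restarts independent random restarts; best kept.
#' @return an object of class `"nnmf_model"`: `scores` (W), `basis` (H),
#'   `k`, `loss_trace` (Frobenius error per sweep, non-increasing), `seed`.
#' @export
nnmf_decompose <- function(X, k, seed = 1L, max_iter = 200L, tol = 1e-6,
                           restarts = 1L) {
  X <- as.matrix(X)
  if (any(X < 0)) stop("X must be non-negative")
  if (k < 1 || k > min(dim(X)))
    stop("k must be between 1 and min(dim(X)) = ", min(dim(X)))
  eps <- 1e-12
  run_one <- function(sub_seed) {
    with_seed(sub_seed, {
      W <- matrix(stats::runif(nrow(X) * k, 0.1, 1), nrow(X), k) *
        sqrt(mean(X) / k)
      H <- matrix(stats::runif(k * ncol(X), 0.1, 1), k, ncol(X)) *
        sqrt(mean(X) / k)
      trace <- numeric(0)
      prev <- Inf
      for (it in seq_len(max_iter)) {
        H <- H * (crossprod(W, X) / (crossprod(W) %*% H + eps))
        W <- W * (X %*% t(H) / (W %*% tcrossprod(H) + eps))
        loss <- sqrt(sum((X - W %*% H)^2))
        trace[it] <- loss
        if (is.finite(prev) && prev - loss < tol * max(prev, eps)) break
        prev <- loss
      }
      list(W = W, H = H, trace = trace)
    })
  }
  fits <- lapply(seq_len(max(1L, restarts)), function(r) run_one(seed + 1000003L * (r - 1L)))
  best <- fits[[which.min(vapply(fits, function(f) f$trace[length(f$trace)],
                                 numeric(1)))]]
  structure(list(k = as.integer(k), scores = best$W, basis = best$H,
                 loss_trace = best$trace, seed = as.integer(seed)),
            class = "nnmf_model")
}

#' @export
print.nnmf_model <- function(x, ...) {
  cat(sprintf("<nnmf_model> k = %d, %d pixels x %d channels, final loss %.6g (%d sweeps)\n",
              x$k, nrow(x$scores), ncol(x$basis),
              x$loss_trace[length(x$loss_trace)], length(x$loss_trace)))
  invisible(x)
}

#' Assign each pixel to the NNMF component with the highest score
#'
#' Ties are broken toward the lowest component index.
#'
#' @param model an [nnmf_decompose()] fit.
#' @return integer vector of segment labels in `1..k`, one per pixel.
#' @export
assign_labels <- function(model) {
  stopifnot(inherits(model, "nnmf_model"))
  apply(model$scores, 1, which.max)  # which.max takes the first maximum
}

#' Mean silhouette coefficient of a labeling
#'
#' Standard silhouette `s(i) = (b(i) - a(i)) / max(a(i), b(i))` with `a`
#' the mean intra-cluster Euclidean distance (excluding self) and `b` the
#' smallest mean distance to another cluster; members of singleton clusters
#' contribute `s = 0`. For large inputs the points are subsampled (seeded)
#' before computing the n x n distance matrix.
#'
#' @param X numeric matrix of observations (rows).
#' @param labels integer cluster labels, >= 2 distinct values.
#' @param max_points subsample cap for the distance computation.
#' @param seed seed used only when subsampling.
#' @return mean silhouette in `[-1, 1]`.
#' @export
mean_silhouette <- function(X, labels, max_points = 2000L, seed = 1L) {
  X <- as.matrix(X)
  labels <- as.integer(labels)
  stopifnot(nrow(X) == length(labels))
  if (length(unique(labels)) < 2)
    stop("silhouette needs at least 2 clusters")
  if (nrow(X) > max_points) {
    idx <- with_seed(seed, sample.int(nrow(X), max_points))
    # keep every cluster represented
    missing <- setdiff(unique(labels), unique(labels[idx]))
    for (m in missing) idx <- c(idx, which(labels == m)[1])
    X <- X[idx, , drop = FALSE]; labels <- labels[idx]
    if (length(unique(labels)) < 2) stop("subsample degenerated to one cluster")
  }
  sil <- cluster::silhouette(labels, stats::dist(X))
  if (!is.matrix(sil)) return(0)  # every cluster a singleton
  mean(sil[, "sil_width"])
}

#' Segment MSI spectra and select the number of segments
#'
#' Runs [nnmf_decompose()] plus [assign_labels()] for each candidate `k`
#' and keeps the `k` whose labeling maximizes the mean silhouette
#' coefficient of the (TIC-normalized) spectra; ties go to the smaller
#' `k`. Candidate labelings that collapse to a single non-empty cluster
#' are recorded with silhouette `-Inf` and skipped.
#'
#' @param X non-negative matrix of spectra (pixels x channels), typically
#'   TIC-normalized tumor pixels.
#' @param k_range candidate numbers of segments (default 2 to 5).
#' @param seed integer seed controlling NNMF initialization and silhouette
#'   subsampling.
#' @param restarts NNMF restarts per `k`.
#' @param ... further arguments passed to [nnmf_decompose()].
#' @return an object of class `"segmentation_result"`: `labels` (for the
#'   chosen `k`), `model`, `silhouette_by_k` (named numeric), `chosen_k`.
#' @export
select_k <- function(X, k_range = 2:5, seed = 1L, restarts = 3L, ...) {
  X <- as.matrix(X)
  if (nrow(X) < max(k_range) + 1)
    stop("need at least max(k_range) + 1 rows")
  sil <- stats::setNames(rep(-Inf, length(k_range)), k_range)
  fits <- vector("list", length(k_range))
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    model <- nnmf_decompose(X, k, seed = seed + 97L * k, restarts = restarts, ...)
    labels <- assign_labels(model)
    fits[[i]] <- list(model = model, labels = labels)
    if (length(unique(labels)) >= 2)
      sil[i] <- mean_silhouette(X, labels, seed = seed)
  }
  if (all(!is.finite(sil)))
    stop("every candidate k produced a degenerate one-cluster labeling")
  best <- which.max(sil)  # first maximum -> smaller k on ties
  structure(list(labels = fits[[best]]$labels, model = fits[[best]]$model,
                 silhouette_by_k = sil, chosen_k = as.integer(k_range[best])),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result> chosen k = %d\n", x$chosen_k))
  s <- x$silhouette_by_k
  for (i in seq_along(s))
    cat(sprintf("  k = %s: mean silhouette %s\n", names(s)[i],
                formatC(s[i], digits = 4, format = "f")))
  invisible(x)
}

#' Render per-pixel labels as a label image
#'
#' @param ds the [msi_dataset()] whose pixels were labeled.
#' @param labels integer labels, one per pixel of `ds`.
#' @param shape optional `c(height, width)`; defaults to the dataset grid.
#' @param frame frame name of the raster.
#' @return a [label_image()] with 0 where no pixel (or no label) exists.
#' @export
labels_to_image <- function(ds, labels, shape = NULL, frame = "msi") {
  stopifnot(inherits(ds, "msi_dataset"), nrow(ds$coords) == length(labels))
  if (is.null(shape)) shape <- grid_shape(ds)
  img <- matrix(0L, shape[1], shape[2])
  img[cbind(ds$coords[, 2] + 1, ds$coords[, 1] + 1)] <- as.integer(labels)
  label_image(img, frame)
}
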