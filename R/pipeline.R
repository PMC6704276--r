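#' Run the MSI-to-LMD pipeline end to end
#'
#' Chains the full workflow on in-memory objects: optional tumor masking
#' from annotation polygons, TIC normalization, NNMF segmentation with
#' silhouette-based choice of the number of segments, morphological
#' post-processing of the label image (2x2 opening, small-area removal,
#' hole filling), nearest-pixel upscaling of each segment mask to the H&E
#' frame, external boundary tracing, transfer of the boundaries to the
#' optical frame, and recalculation relative to the origin teaching point
#' into an LMD document.
#'
#' @param ds an [msi_dataset()].
#' @param msi_to_optical,optical_to_he [affine2d()] registration steps
#'   (fit them from control points with [fit_affine()]).
#' @param teaching an optional [teaching_points()] set (optical frame);
#'   when `NULL` the LMD export step is skipped.
#' @param he_shape `c(height, width)` of the H&E raster the masks are
#'   upscaled to.
#' @param annotations optional [annotation_set()] restricting the pixels
#'   (e.g. the pathologist's tumor outlines); its frame must be `"msi"`,
#'   `"optical"`, or `"he"` so the chain can be inverted automatically.
#' @param k_range candidate segment counts for [select_k()].
#' @param min_removed_area largest impurity area deleted per segment mask.
#' @param seed,restarts passed to [select_k()].
#' @return list with `segmentation` (a `"segmentation_result"`), `labels`
#'   (smoothed [label_image()]), `masks` (processed per-segment masks, MSI
#'   frame), `he_masks` (upscaled masks, H&E frame), `boundaries` (list of
#'   [roi_boundary_set()]s in the H&E frame), and `lmd` (an
#'   [lmd_document()], or `NULL`).
#' @export
run_pipeline <- function(ds, msi_to_optical, optical_to_he, teaching = NULL,
                         he_shape = NULL, annotations = NULL, k_range = 2:5,
                         min_removed_area = 30, seed = 1L, restarts = 3L) {
  stopifnot(inherits(ds, "msi_dataset"))
  msi_to_he <- compose_affine(optical_to_he, msi_to_optical)
  if (is.null(he_shape)) {
    g <- grid_shape(ds)
    corners <- transform_points(msi_to_he,
                                rbind(c(0, 0), c(g[2] - 1, 0),
                                      c(0, g[1] - 1), c(g[2] - 1, g[1] - 1)))
    he_shape <- ceiling(c(max(corners[, 2]) + 1, max(corners[, 1]) + 1))
  }
  work <- ds
  if (!is.null(annotations)) {
    chain <- switch(annotations$frame,
      msi = affine_identity("msi"),
      optical = affine_inverse(msi_to_optical),
      he = affine_inverse(msi_to_he),
      stop("cannot build a chain from frame '", annotations$frame, "' to 'msi'"))
    mask <- rasterize_annotations(annotations, chain, ds)
    work <- apply_mask(work, mask)
  }
  work <- tic_normalize(work)
  seg <- select_k(work$spectra, k_range = k_range, seed = seed,
                  restarts = restarts)
  labels <- smooth_labels(labels_to_image(work, seg$labels,
                                          shape = grid_shape(ds)))
  masks <- lapply(split_segments(labels, seg$chosen_k), function(m)
    fill_holes(remove_small_regions(m, min_removed_area)))
  he_masks <- lapply(masks, upscale_mask, T = msi_to_he,
                     target_shape = he_shape)
  boundaries <- lapply(seq_along(he_masks), function(s)
    trace_boundaries(he_masks[[s]], segment_id = s))
  lmd <- NULL
  if (!is.null(teaching)) {
    he_to_optical <- affine_inverse(optical_to_he)
    opt_bounds <- lapply(boundaries, function(b) {
      if (length(b$polygons) == 0) return(NULL)
      transform_boundaries(b, he_to_optical)
    })
    opt_bounds <- Filter(Negate(is.null), opt_bounds)
    lmd <- to_lmd_coordinates(opt_bounds, teaching)
  }
  list(segmentation = seg, labels = labels, masks = masks,
       he_masks = he_masks, boundaries = boundaries, lmd = lmd)
}
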