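#' Integer label image
#'
#' Raster of segment labels: 0 = unassigned, `1..k` = segment id. Indexed
#' like [pixel_mask()]: `values[r, c]` is the pixel at 0-based
#' `x = c - 1`, `y = r - 1`.
#'
#' @param values integer matrix (height x width), values >= 0.
#' @param frame frame (or name) of the raster.
#' @return an object of class `"label_image"`.
#' @export
label_image <- function(values, frame = "msi") {
  values <- as.matrix(values)
  if (any(values < 0) || any(values != round(values)))
    stop("labels must be non-negative integers")
  storage.mode(values) <- "integer"
  structure(values, frame = frame_name(frame), class = c("label_image", "matrix"))
}

#' @export
as.matrix.label_image <- function(x, ...) {
  attributes(x) <- list(dim = dim(x))
  x
}

#' @export
print.label_image <- function(x, ...) {
  cat(sprintf("<label_image> %d x %d in frame '%s', labels {%s}\n",
              nrow(x), ncol(x), attr(x, "frame"),
              paste(sort(unique(as.integer(x))), collapse = ", ")))
  invisible(x)
}

# shift a matrix by (dr, dc), padding with `fill`
shift_mat <- function(M, dr, dc, fill) {
  h <- nrow(M); w <- ncol(M)
  out <- matrix(fill, h, w)
  rs <- intersect(seq_len(h), seq_len(h) - dr)
  cs <- intersect(seq_len(w), seq_len(w) - dc)
  if (length(rs) && length(cs)) out[rs, cs] <- M[rs + dr, cs + dc]
  out
}

#' Morphological opening of a label image with a 2 x 2 square
#'
#' Grayscale opening (erosion then dilation) of the integer label raster
#' with a 2 x 2 structuring element anchored at its top-left pixel, i.e.
#' the erosion at `(r, c)` is the minimum over the down-right 2 x 2 window
#' and the dilation (with the reflected element) the maximum over the
#' up-left window. This smooths the segmentation image by removing
#' structures thinner than 2 pixels. Out-of-image samples act as +Inf for
#' the erosion and -Inf for the dilation, matching MATLAB's `imopen`
#' padding.
#'
#' Note that opening the label raster as a grayscale image makes the result
#' depend on the numeric order of labels; set `per_segment = TRUE` to open
#' each segment's binary mask independently instead (later segments win
#' where openings overlap, which they cannot for disjoint inputs).
#'
#' @param img a [label_image()].
#' @param per_segment open each label's binary mask separately.
#' @return the smoothed `label_image`.
#' @export
smooth_labels <- function(img, per_segment = FALSE) {
  stopifnot(inherits(img, "label_image"))
  open2x2 <- function(M) {
    e <- pmin(M,
              shift_mat(M, 0, 1, Inf),
              shift_mat(M, 1, 0, Inf),
              shift_mat(M, 1, 1, Inf))
    pmax(e,
         shift_mat(e, 0, -1, -Inf),
         shift_mat(e, -1, 0, -Inf),
         shift_mat(e, -1, -1, -Inf))
  }
  if (!per_segment)
    return(label_image(open2x2(matrix(as.numeric(img), nrow(img))),
                       attr(img, "frame")))
  out <- matrix(0, nrow(img), ncol(img))
  for (s in setdiff(sort(unique(as.integer(img))), 0L)) {
    op <- open2x2(matrix(as.numeric(img == s), nrow(img)))
    out[op > 0] <- s
  }
  label_image(out, attr(img, "frame"))
}

#' Split a label image into per-segment binary masks
#'
#' @param img a [label_image()].
#' @param k number of segments; defaults to `max(img)`.
#' @return list of `k` [pixel_mask()]s; mask `s` is true exactly where the
#'   label equals `s`. Masks are pairwise disjoint and their union is the
#'   labeled (non-zero) area.
#' @export
split_segments <- function(img, k = max(img, 0)) {
  stopifnot(inherits(img, "label_image"))
  if (max(img) > k) stop("labels exceed k = ", k)
  lapply(seq_len(k), function(s)
    pixel_mask(matrix(as.integer(img) == s, nrow(img)), attr(img, "frame")))
}

#' Label connected components of a binary mask
#'
#' Breadth-first labeling; components are numbered in raster-scan order of
#' their first pixel (top-to-bottom, then left-to-right).
#'
#' @param mask logical matrix or [pixel_mask()].
#' @param connectivity 4 (edge neighbors) or 8 (edges + diagonals).
#' @return integer matrix of component ids, 0 for background.
#' @export
label_components <- function(mask, connectivity = 4) {
  stopifnot(connectivity %in% c(4, 8))
  M <- as.matrix(mask); storage.mode(M) <- "logical"
  h <- nrow(M); w <- ncol(M)
  lab <- matrix(0L, h, w)
  offs <- if (connectivity == 4) list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
          else list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
                    c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  # raster order: rows within columns is R's native order; reorder to
  # row-major so component ids are stable top-to-bottom
  fg <- which(M)
  fg <- fg[order((fg - 1) %% h, (fg - 1) %/% h)]
  nextlab <- 0L
  for (seed in fg) {
    if (lab[seed] != 0L) next
    nextlab <- nextlab + 1L
    lab[seed] <- nextlab
    frontier <- seed
    while (length(frontier)) {
      r <- (frontier - 1L) %% h + 1L
      c <- (frontier - 1L) %/% h + 1L
      nxt <- integer(0)
      for (o in offs) {
        rr <- r + o[1]; cc <- c + o[2]
        ok <- rr >= 1 & rr <= h & cc >= 1 & cc <= w
        if (!any(ok)) next
        id <- (cc[ok] - 1L) * h + rr[ok]
        id <- id[M[id] & lab[id] == 0L]
        if (length(id)) { lab[id] <- nextlab; nxt <- c(nxt, id) }
      }
      frontier <- unique(nxt)
    }
  }
  lab
}

#' Remove small connected regions from a binary mask
#'
#' Deletes impurities: every 4-connected foreground component whose area is
#' at most `max_removed_area` pixels (default 30, so components of 31 or
#' more pixels survive intact). Anti-extensive and idempotent.
#'
#' @param mask a [pixel_mask()] or logical matrix.
#' @param max_removed_area largest component area (pixels) to delete.
#' @return the filtered [pixel_mask()].
#' @export
remove_small_regions <- function(mask, max_removed_area = 30) {
  fr <- attr(mask, "frame"); if (is.null(fr)) fr <- "msi"
  lab <- label_components(mask, connectivity = 4)
  if (max(lab) == 0) return(pixel_mask(lab > 0, fr))
  areas <- tabulate(lab)
  keep <- which(areas > max_removed_area)
  pixel_mask(matrix(lab %in% keep, nrow(lab)), fr)
}

#' Fill holes in a binary mask
#'
#' A hole is an 8-connected background component that cannot reach the
#' image border; such components become foreground. Extensive and
#' idempotent.
#'
#' @param mask a [pixel_mask()] or logical matrix.
#' @return the filled [pixel_mask()].
#' @export
fill_holes <- function(mask) {
  fr <- attr(mask, "frame"); if (is.null(fr)) fr <- "msi"
  M <- as.matrix(mask); storage.mode(M) <- "logical"
  bg <- label_components(!M, connectivity = 8)
  border_ids <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  border_ids <- setdiff(border_ids, 0L)
  pixel_mask(M | (bg != 0L & !(bg %in% border_ids)), fr)
}

#' Warp a binary mask to a target frame by nearest-pixel interpolation
#'
#' Inverse mapping: for every target pixel center `p`, the source position
#' is `inverse(T)(p)` rounded per axis with `floor(v + 0.5)`; out-of-range
#' positions map to background. Used to upscale the per-segment MSI masks
#' to the dimensions of the histological image.
#'
#' @param mask a [pixel_mask()] in `T$source_frame`.
#' @param T an invertible [affine2d()] from the mask's frame to the target
#'   frame.
#' @param target_shape `c(height, width)` of the output raster.
#' @return a [pixel_mask()] in `T$target_frame`.
#' @export
upscale_mask <- function(mask, T, target_shape) {
  stopifnot(inherits(T, "affine2d"), length(target_shape) == 2)
  M <- as.matrix(mask); storage.mode(M) <- "logical"
  h <- as.integer(target_shape[1]); w <- as.integer(target_shape[2])
  Tinv <- affine_inverse(T)
  px <- rep(0:(w - 1), each = h)
  py <- rep(0:(h - 1), times = w)
  src <- transform_points(Tinv, cbind(px, py))
  sx <- round_half_up(src[, 1]); sy <- round_half_up(src[, 2])
  ok <- sx >= 0 & sx < ncol(M) & sy >= 0 & sy < nrow(M)
  vals <- logical(length(px))
  vals[ok] <- M[cbind(sy[ok] + 1, sx[ok] + 1)]
  pixel_mask(matrix(vals, h, w), T$target_frame)
}

#' Read / write a mask or label image as 8-bit PNG
#'
#' Masks are stored as 0/255; label images store the label value directly
#' (so at most 255 segments).
#'
#' @param x a [pixel_mask()] or [label_image()].
#' @param path file path.
#' @param frame frame name to attach on read.
#' @return readers return the reconstructed object; writers return `path`
#'   invisibly.
#' @export
write_mask_png <- function(x, path) {
  M <- as.matrix(x)
  if (is.logical(M)) M <- M * 255L
  png::writePNG(M / 255, path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path, frame = "msi") {
  M <- round(png::readPNG(path) * 255)
  if (length(dim(M)) == 3) M <- M[, , 1]
  pixel_mask(M > 0, frame)
}

#' @rdname write_mask_png
#' @export
read_labels_png <- function(path, frame = "msi") {
  M <- round(png::readPNG(path) * 255)
  if (length(dim(M)) == 3) M <- M[, , 1]
  label_image(M, frame)
}
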