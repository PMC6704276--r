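#' Phantom specification
#'
#' Parameters of the synthetic data generators. Defaults emulate the study
#' conditions the pipeline targets: a regular MSI grid at 70-um pitch, a
#' nominal m/z 350-1600 lipid axis, three spatially contiguous molecular
#' populations with sparse distinct signatures, Tipp-Ex-like fiducial
#' spots relating the optical and H&E frames, and visible laser-shot
#' landmarks relating MSI to the optical image.
#'
#' @param grid_shape `c(rows, cols)` of the MSI grid.
#' @param pitch MSI pixel spacing (micrometers).
#' @param k_true number of planted clusters.
#' @param n_channels number of spectral bins across m/z 350-1600.
#' @param signature_separation peak height of a cluster's signature
#'   channels above the common baseline (arbitrary intensity units).
#' @param noise_sd SD of the additive Gaussian noise (truncated at 0).
#' @param fiducial_count number of fiducial/landmark points (>= 3).
#' @param true_transforms named list of ground-truth [affine2d()]s; keys
#'   `"msi_optical"` and `"optical_he"`. Defaults: 35x scaling (70 um MSI
#'   pixels onto ~2 um optical pixels) with an offset, and a small
#'   rotation/translation between the optical scans.
#' @param seed integer seed; all generators are deterministic given the
#'   spec.
#' @return an object of class `"phantom_spec"`.
#' @export
phantom_spec <- function(grid_shape = c(48, 48), pitch = 70, k_true = 3,
                         n_channels = 60, signature_separation = 5,
                         noise_sd = 0.25, fiducial_count = 4,
                         true_transforms = NULL, seed = 1L) {
  stopifnot(length(grid_shape) == 2, all(grid_shape >= 1), pitch > 0,
            k_true >= 1, n_channels >= k_true, signature_separation >= 0,
            noise_sd >= 0, fiducial_count >= 3)
  if (is.null(true_transforms)) {
    s <- pitch / 2     # MSI pixels onto ~2 um optical pixels
    th <- 0.02         # slight rotation between the two optical scans
    true_transforms <- list(
      msi_optical = affine2d(c(s, 0, 40, 0, s, 60), "msi", "optical"),
      optical_he = affine2d(c(cos(th), -sin(th), 8, sin(th), cos(th), -5),
                            "optical", "he"))
  }
  structure(list(grid_shape = as.integer(grid_shape), pitch = pitch,
                 k_true = as.integer(k_true), n_channels = as.integer(n_channels),
                 signature_separation = signature_separation,
                 noise_sd = noise_sd, fiducial_count = as.integer(fiducial_count),
                 true_transforms = true_transforms, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate an MSI phantom with planted spatial clusters
#'
#' Partitions the grid into `k_true` spatially contiguous regions (the
#' Voronoi cells of seeded random centers, hence convex and connected) and
#' assigns each region a distinct sparse non-negative signature: a common
#' baseline plus `signature_separation` on a few cluster-specific
#' channels. Per-pixel spectra add Gaussian noise truncated at zero.
#'
#' @param spec a [phantom_spec()].
#' @return list with `dataset` (an [msi_dataset()]), `truth` (a
#'   [label_image()] of the planted partition), and `signatures`
#'   (`k_true` x `n_channels`).
#' @export
make_msi_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  h <- spec$grid_shape[1]; w <- spec$grid_shape[2]
  k <- spec$k_true
  if (k > h * w) stop("k_true exceeds the number of pixels")
  with_seed(spec$seed, {
    cx <- stats::runif(k, 0, w - 1); cy <- stats::runif(k, 0, h - 1)
    coords <- cbind(x = rep(0:(w - 1), each = h), y = rep(0:(h - 1), times = w))
    d2 <- outer(coords[, 1], cx, `-`)^2 + outer(coords[, 2], cy, `-`)^2
    region <- max.col(-d2, ties.method = "first")

    per <- max(1L, min(3L, spec$n_channels %/% k))
    sig <- matrix(0.2, k, spec$n_channels)  # common baseline
    for (r in seq_len(k))
      sig[r, ((r - 1) * per + 1):(r * per)] <-
        0.2 + spec$signature_separation
    spectra <- sig[region, , drop = FALSE] +
      matrix(stats::rnorm(length(region) * spec$n_channels, 0, spec$noise_sd),
             ncol = spec$n_channels)
    spectra <- pmax(spectra, 0)
    ds <- msi_dataset(coords, spectra,
                      seq(350, 1600, length.out = spec$n_channels), spec$pitch)
    truth <- matrix(0L, h, w)
    truth[cbind(coords[, 2] + 1, coords[, 1] + 1)] <- region
    list(dataset = ds, truth = label_image(truth, "msi"), signatures = sig)
  })
}

#' Generate a registration phantom with known ground-truth transforms
#'
#' Places `fiducial_count` landmark points on the MSI grid, maps them into
#' the optical and H&E frames by the spec's ground-truth affines (with
#' optional Gaussian jitter emulating manual selection error), and bundles
#' the corresponding control point sets. Optionally renders simple raster
#' images with disk-shaped fiducial spots at the landmark positions.
#'
#' @param spec a [phantom_spec()].
#' @param jitter_sd SD (target-frame pixels) of landmark selection jitter;
#'   0 for exact correspondences.
#' @param render return `optical` and `he` intensity rasters with fiducial
#'   spots burned in.
#' @return list with `control_points` (named list `msi_optical`,
#'   `optical_he`), `landmarks` (per-frame coordinate matrices),
#'   `true_transforms`, and optionally `images`.
#' @export
make_registration_phantom <- function(spec, jitter_sd = 0, render = FALSE) {
  stopifnot(inherits(spec, "phantom_spec"))
  Tmo <- spec$true_transforms$msi_optical
  Toh <- spec$true_transforms$optical_he
  stopifnot(inherits(Tmo, "affine2d"), inherits(Toh, "affine2d"))
  h <- spec$grid_shape[1]; w <- spec$grid_shape[2]
  with_seed(spec$seed + 7L, {
    n <- spec$fiducial_count
    repeat {  # resample until non-collinear (degenerate draws are rare)
      msi_pts <- cbind(x = stats::runif(n, 1, w - 2), y = stats::runif(n, 1, h - 2))
      if (max_triangle_area(msi_pts) > 1) break
    }
    jit <- function(p, sd) p + matrix(stats::rnorm(length(p), 0, sd), ncol = 2)
    opt_pts <- transform_points(Tmo, msi_pts)
    he_pts <- transform_points(Toh, opt_pts)
    cps <- list(
      msi_optical = control_points(msi_pts, jit(opt_pts, jitter_sd),
                                   "msi", "optical"),
      optical_he = control_points(opt_pts, jit(he_pts, jitter_sd),
                                  "optical", "he"))
    out <- list(control_points = cps,
                landmarks = list(msi = msi_pts, optical = opt_pts, he = he_pts),
                true_transforms = spec$true_transforms)
    if (render) {
      spot_image <- function(pts, shape, radius = 3) {
        img <- matrix(0, shape[1], shape[2])
        gx <- rep(0:(shape[2] - 1), each = shape[1])
        gy <- rep(0:(shape[1] - 1), times = shape[2])
        for (i in seq_len(nrow(pts)))
          img[(gx - pts[i, 1])^2 + (gy - pts[i, 2])^2 <= radius^2] <- 1
        img
      }
      opt_shape <- ceiling(range_shape(transform_points(
        Tmo, cbind(c(0, w - 1), c(0, h - 1)))))
      he_shape <- ceiling(range_shape(transform_points(
        Toh, transform_points(Tmo, cbind(c(0, w - 1), c(0, h - 1))))))
      out$images <- list(optical = spot_image(opt_pts, opt_shape),
                         he = spot_image(he_pts, he_shape))
    }
    out
  })
}

# (height, width) raster shape just covering transformed corner points
range_shape <- function(pts) c(max(pts[, 2]) + 2, max(pts[, 1]) + 2)

#' Generate a protein phantom with planted exclusive markers
#'
#' Builds a protein LFQ table whose rows are exchangeable log-normal noise
#' except for planted markers: for each segment, `planted_per_segment`
#' proteins per requested direction have that segment's log2 intensity
#' shifted by `+effect_size` (over) or `-effect_size` (under). The ground
#' truth call list is returned alongside.
#'
#' @param n_proteins total number of proteins.
#' @param segments number of segment columns.
#' @param planted_per_segment markers planted per segment and direction.
#' @param effect_size log2 shift of the planted segment.
#' @param noise_sd SD of the per-entry log2 noise.
#' @param directions subset of `c("over", "under")` to plant.
#' @param seed integer seed.
#' @return list with `table` (a [protein_table()]) and `truth` (data frame
#'   `protein_id`, `segment`, `direction`).
#' @export
make_protein_phantom <- function(n_proteins = 1040, segments = 3,
                                 planted_per_segment = 10, effect_size = 4,
                                 noise_sd = 0.3,
                                 directions = c("over", "under"), seed = 1L) {
  directions <- match.arg(directions, several.ok = TRUE)
  n_planted <- planted_per_segment * segments * length(directions)
  if (n_planted > n_proteins)
    stop("more planted markers than proteins")
  with_seed(seed, {
    base <- stats::rnorm(n_proteins, 25, 2)   # typical log2 LFQ scale
    lmat <- base + matrix(stats::rnorm(n_proteins * segments, 0, noise_sd),
                          n_proteins, segments)
    ids <- sprintf("P%04d", seq_len(n_proteins))
    seg_names <- paste0("segment_", seq_len(segments))
    truth <- list()
    slot <- 0L
    for (dir in directions) for (s in seq_len(segments)) {
      rows <- slot + seq_len(planted_per_segment)
      slot <- slot + planted_per_segment
      lmat[rows, s] <- lmat[rows, s] +
        if (dir == "over") effect_size else -effect_size
      truth[[length(truth) + 1]] <-
        data.frame(protein_id = ids[rows], segment = seg_names[s],
                   direction = dir, stringsAsFactors = FALSE)
    }
    tab <- protein_table(ids, 2^lmat, NULL, seg_names)
    list(table = tab, truth = do.call(rbind, truth))
  })
}

#' Write a full phantom fixture set to a directory
#'
#' Materializes one coherent synthetic experiment on disk: a continuous
#' imzML/ibd pair, PNG optical and H&E images with fiducial spots, control
#' point CSVs for both registration steps, a tumor annotation JSON
#' covering the cluster regions, teaching points, and a MaxQuant-style
#' protein table.
#'
#' @param dir output directory (created if needed).
#' @param spec a [phantom_spec()].
#' @return the list of written paths, invisibly.
#' @export
write_phantom_bundle <- function(dir, spec = phantom_spec()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  msi <- make_msi_phantom(spec)
  reg <- make_registration_phantom(spec, render = TRUE)
  prot <- make_protein_phantom(seed = spec$seed)
  p <- function(f) file.path(dir, f)
  write_imzml(msi$dataset, p("phantom.imzML"))
  png::writePNG(reg$images$optical, p("optical.png"))
  png::writePNG(reg$images$he, p("he.png"))
  write_control_points(reg$control_points$msi_optical, p("cp_msi_optical.csv"))
  write_control_points(reg$control_points$optical_he, p("cp_optical_he.csv"))
  h <- spec$grid_shape[1]; w <- spec$grid_shape[2]
  full <- annotation_set(list(rbind(c(-0.5, -0.5), c(w - 0.5, -0.5),
                                    c(w - 0.5, h - 0.5), c(-0.5, h - 0.5))),
                         "msi")
  write_annotations(full, p("annotations.json"))
  tp <- reg$landmarks$optical[1:3, , drop = FALSE]
  utils::write.table(data.frame(x = tp[, 1], y = tp[, 2]),
                     p("teaching_points.csv"), sep = ",",
                     row.names = FALSE, quote = FALSE)
  lfq <- prot$table$intensities
  tab <- data.frame(`Protein IDs` = prot$table$protein_id,
                    Reverse = "", `Only identified by site` = "",
                    `Potential contaminant` = "", check.names = FALSE)
  for (s in colnames(lfq)) tab[[paste0("LFQ intensity ", s)]] <- lfq[, s]
  utils::write.table(tab, p("proteinGroups.txt"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(vapply(c("phantom.imzML", "phantom.ibd", "optical.png", "he.png",
                     "cp_msi_optical.csv", "cp_optical_he.csv",
                     "annotations.json", "teaching_points.csv",
                     "proteinGroups.txt"), p, character(1)))
}
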