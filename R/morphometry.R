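# Per-coccolith measurement from polarized-light rasters: thresholded
# connected-component segmentation with intact/isolated filtering, then mass
# from grey-level integration and apparent length from the maximum Feret
# diameter. Masks use pixel-centre, row-major coordinates with the origin at
# the top-left pixel.

#' Segment bright particles in a simulated or measured PLM raster
#'
#' Connected components (8-connectivity) of above-threshold pixels stand in
#' for individual coccoliths. Components touching the frame border or
#' smaller than `min_area_px` are flagged and excluded from downstream
#' statistics, as are components whose convex hulls overlap another
#' component's hull (not isolated): only intact, isolated particles enter
#' sample summaries.
#'
#' @param image A `plm_image` (see [render_plm()] / [read_plm_tiff()]).
#' @param threshold_policy `"otsu"` (Otsu's method on the non-background
#'   grey histogram; default) or `"fixed"`.
#' @param threshold_value Grey threshold used when `threshold_policy =
#'   "fixed"`.
#' @param min_area_px Minimum component area in pixels. Default 20.
#' @return An object of class `plm_segmentation`: list with `labels` (matrix
#'   of component labels, 0 = background), `threshold`, and `particles`, a
#'   tibble with one row per component: `particle_id`, `area_px`,
#'   `touching_border`, `isolated`, `retained` (intact and isolated).
#' @export
segment_particles <- function(image, threshold_policy = c("otsu", "fixed"),
                              threshold_value = NULL, min_area_px = 20) {
  stopifnot(inherits(image, "plm_image"))
  threshold_policy <- match.arg(threshold_policy)
  raster <- image$raster
  if (!length(raster)) stop("Empty raster.", call. = FALSE)
  maxg <- 2^image$optics$bit_depth - 1
  if (all(raster >= maxg)) {
    stop("Raster is fully saturated; grey levels carry no thickness ",
         "information.", call. = FALSE)
  }

  if (threshold_policy == "fixed") {
    if (is.null(threshold_value)) {
      stop("`threshold_value` is required with the fixed policy.", call. = FALSE)
    }
    thr <- threshold_value
  } else {
    thr <- otsu_nonbackground(raster, image$optics$background_level, maxg)
  }

  # fill enclosed holes so a bright tube ring and its central plate label as
  # one particle (the open central area and slits are interior background)
  binary <- EBImage::fillHull(raster > thr)
  labels <- EBImage::bwlabel(binary)
  n_lab <- max(labels)
  if (n_lab == 0) {
    return(structure(list(labels = labels, threshold = thr,
                          particles = empty_particle_tbl()),
                     class = "plm_segmentation"))
  }

  idx <- which(labels > 0, arr.ind = TRUE)
  lab <- labels[labels > 0]
  area <- tabulate(lab, n_lab)
  border <- vapply(seq_len(n_lab), function(k) {
    pix <- idx[lab == k, , drop = FALSE]
    any(pix[, 1] == 1 | pix[, 1] == nrow(labels) |
        pix[, 2] == 1 | pix[, 2] == ncol(labels))
  }, logical(1))

  hulls <- lapply(seq_len(n_lab), function(k) {
    pix <- idx[lab == k, , drop = FALSE]
    xy <- cbind(pix[, 2], pix[, 1])   # x = col, y = row, pixel centres
    xy[grDevices::chull(xy), , drop = FALSE]
  })
  isolated <- rep(TRUE, n_lab)
  if (n_lab > 1) {
    for (i in seq_len(n_lab - 1)) {
      for (j in (i + 1):n_lab) {
        if (convex_overlap(hulls[[i]], hulls[[j]])) {
          isolated[c(i, j)] <- FALSE
        }
      }
    }
  }

  particles <- tibble::tibble(
    particle_id = seq_len(n_lab),
    area_px = area,
    touching_border = border,
    isolated = isolated,
    retained = !border & isolated & area >= min_area_px
  )
  structure(list(labels = labels, threshold = thr, particles = particles),
            class = "plm_segmentation")
}

empty_particle_tbl <- function() {
  tibble::tibble(particle_id = integer(), area_px = integer(),
                 touching_border = logical(), isolated = logical(),
                 retained = logical())
}

#' @export
print.plm_segmentation <- function(x, ...) {
  cat(sprintf("PLM segmentation: %d component(s), %d retained (threshold %.0f)\n",
              nrow(x$particles), sum(x$particles$retained), x$threshold))
  invisible(x)
}

# Otsu threshold computed on the pixels away from the modal (background)
# grey, on a 256-bin histogram; falls back to the full histogram when the
# raster is essentially flat.
otsu_nonbackground <- function(raster, background_level, maxg) {
  v <- as.vector(raster)
  tab <- tabulate(v + 1L, maxg + 1L)
  modal <- which.max(tab) - 1L
  keep <- v > modal + 3 * max(1, sqrt(modal + 1))
  vals <- if (sum(keep) > 50) v[keep] else v
  rng <- range(vals)
  if (diff(rng) < 1) return(background_level + 1)
  EBImage::otsu(matrix((vals - rng[1]) / diff(rng), ncol = 1),
                range = c(0, 1), levels = 256) * diff(rng) + rng[1]
}

# Separating-axis test for two convex polygons (vertex matrices, columns
# x,y); TRUE when the hulls intersect
convex_overlap <- function(p, q) {
  if (nrow(p) == 0 || nrow(q) == 0) return(FALSE)
  axes <- function(poly) {
    if (nrow(poly) < 2) return(matrix(c(1, 0, 0, 1), 2, byrow = TRUE))
    e <- diff(rbind(poly, poly[1, , drop = FALSE]))
    cbind(-e[, 2], e[, 1])
  }
  for (ax in list(axes(p), axes(q))) {
    for (i in seq_len(nrow(ax))) {
      a <- ax[i, ]
      if (!any(a != 0)) next
      pp <- p %*% a; qq <- q %*% a
      if (max(pp) < min(qq) || max(qq) < min(pp)) return(FALSE)
    }
  }
  TRUE
}

#' Measure mass and apparent length of segmented particles
#'
#' Per-particle calcite mass integrates the background-subtracted grey over
#' the mask: `mass = sum((grey - background) / grey_gain) * pixel_size^2 *
#' rho_c` (thickness from the linear optics model, times pixel area, times
#' calcite density). Apparent length is the maximum Feret diameter of the
#' mask (largest pixel-centre distance across its convex hull, plus one
#' pixel for the pixel extent), in microns — robust to the concave outline
#' that slits induce.
#'
#' @param segmentation A `plm_segmentation` from [segment_particles()].
#' @param image The `plm_image` the segmentation came from.
#' @param constants A [calcite_constants()] object (`rho_c`).
#' @param retained_only Measure only intact-isolated particles (default
#'   `TRUE`).
#' @param halo_um Radius (um) by which the mask is dilated for the mass
#'   integral only: the thin distal shield sits below the segmentation
#'   threshold but still carries grey, so its calcite is recovered from the
#'   halo around the bright region (background-subtracted, the extra pixels
#'   contribute noise with zero mean). The apparent length always comes
#'   from the undilated mask. Default 0.8.
#' @return A tibble with one row per measured particle: `particle_id`,
#'   `mass_pg`, `apparent_length_um`, `centroid_x_px`, `centroid_y_px`,
#'   `area_px`, `touching_border`, `isolated`, `retained`.
#' @export
measure_particles <- function(segmentation, image,
                              constants = calcite_constants(),
                              retained_only = TRUE, halo_um = 0.8) {
  stopifnot(inherits(segmentation, "plm_segmentation"),
            inherits(image, "plm_image"))
  parts <- segmentation$particles
  if (retained_only) parts <- parts[parts$retained, ]
  if (!nrow(parts)) {
    return(tibble::tibble(particle_id = integer(), mass_pg = numeric(),
                          apparent_length_um = numeric(),
                          centroid_x_px = numeric(), centroid_y_px = numeric(),
                          area_px = integer(), touching_border = logical(),
                          isolated = logical(), retained = logical()))
  }
  labels <- segmentation$labels
  raster <- image$raster
  opt <- image$optics
  px <- opt$pixel_size

  halo_px <- max(0L, round(halo_um / px))

  res <- purrr::map_dfr(parts$particle_id, function(k) {
    pix <- which(labels == k, arr.ind = TRUE)
    if (!nrow(pix)) stop("Empty mask for particle ", k, ".", call. = FALSE)
    # mass over the mask dilated by the halo, minus other particles' pixels
    rr <- max(1, min(pix[, 1]) - halo_px):min(nrow(raster), max(pix[, 1]) + halo_px)
    cc <- max(1, min(pix[, 2]) - halo_px):min(ncol(raster), max(pix[, 2]) + halo_px)
    sub <- labels[rr, cc, drop = FALSE]
    region <- sub == k
    if (halo_px > 0) {
      brush <- EBImage::makeBrush(2L * halo_px + 1L, shape = "disc")
      region <- EBImage::dilate(region, brush) & (sub == 0 | sub == k)
    }
    grey <- raster[rr, cc, drop = FALSE][region]
    thickness <- (grey - opt$background_level) / opt$grey_gain
    mass <- sum(thickness) * px^2 * constants$rho_c
    xy <- cbind(pix[, 2], pix[, 1])
    hull <- xy[grDevices::chull(xy), , drop = FALSE]
    feret_px <- if (nrow(hull) >= 2) sqrt(max(dist(hull)^2)) else 0
    tibble::tibble(particle_id = k, mass_pg = mass,
                   apparent_length_um = (feret_px + 1) * px,
                   centroid_x_px = mean(xy[, 1]) - 0.5,
                   centroid_y_px = mean(xy[, 2]) - 0.5)
  })
  dplyr::left_join(res, segmentation$particles, by = "particle_id")
}

#' Measure particles of a micrograph in one call
#'
#' Convenience wrapper: segment, then measure retained particles.
#'
#' @inheritParams segment_particles
#' @inheritParams measure_particles
#' @return As [measure_particles()].
#' @export
measure_plm <- function(image, threshold_policy = "otsu",
                        threshold_value = NULL, min_area_px = 20,
                        constants = calcite_constants()) {
  seg <- segment_particles(image, threshold_policy, threshold_value,
                           min_area_px)
  measure_particles(seg, image, constants)
}

#' Match measured particles to the renderer's ground truth
#'
#' Joins each measured particle to the nearest ground-truth placement (by
#' centroid distance), so measurement error can be scored per coccolith.
#'
#' @param measurements Tibble from [measure_particles()].
#' @param image The `plm_image` whose `ground_truth` to match against.
#' @return `measurements` with `true_mass`, `distal_shield_length`,
#'   `variety` and `match_dist_um` columns appended.
#' @export
match_ground_truth <- function(measurements, image) {
  stopifnot(inherits(image, "plm_image"))
  gt <- image$ground_truth
  if (!nrow(gt)) stop("Image carries no ground truth.", call. = FALSE)
  px <- image$optics$pixel_size
  mx <- (measurements$centroid_x_px + 0.5) * px
  my <- (measurements$centroid_y_px + 0.5) * px
  nearest <- vapply(seq_along(mx), function(i) {
    which.min((gt$x_um - mx[i])^2 + (gt$y_um - my[i])^2)
  }, integer(1))
  measurements$true_mass <- gt$true_mass[nearest]
  measurements$distal_shield_length <- gt$distal_shield_length[nearest]
  measurements$variety <- gt$variety[nearest]
  measurements$match_dist_um <- sqrt((gt$x_um[nearest] - mx)^2 +
                                     (gt$y_um[nearest] - my)^2)
  measurements
}

#' SEM-style shape measurements from a ground-truth table
#'
#' Emulates electron-microscope morphometry on parametric shapes: the total
#' distal-shield length, the central-area-plus-tube length (shield length
#' minus the slits on both sides, `DSL - 2 * SL`), tube width, slit length
#' and central-area closure, with optional Gaussian measurement noise.
#'
#' @param shapes Tibble from [sample_shapes()] (columns
#'   `distal_shield_length`, `tube_width`, `slit_length`,
#'   `central_area_closure`; other columns are carried through).
#' @param noise_sd Standard deviation (um) of independent Gaussian noise
#'   added to the length-valued measurements; 0 (default) for exact reads.
#' @return A tibble with `total_length`, `ca_tube_length`, `tube_width`,
#'   `slit_length`, `central_area_closure`, plus any carried columns
#'   (`variety`, `true_mass`, ...).
#' @examples
#' measure_sem(tibble::tibble(distal_shield_length = 3.5, tube_width = 0.5,
#'                            slit_length = 0.4, central_area_closure = 0.2))
#' @export
measure_sem <- function(shapes, noise_sd = 0) {
  req <- c("distal_shield_length", "tube_width", "slit_length",
           "central_area_closure")
  if (!all(req %in% names(shapes))) {
    stop("`shapes` needs columns ", paste(req, collapse = ", "), ".",
         call. = FALSE)
  }
  if (!all(vapply(shapes[req], function(z) all(is.finite(z)), logical(1)))) {
    stop("Shape records must be finite.", call. = FALSE)
  }
  n <- nrow(shapes)
  noise <- function() if (noise_sd > 0) rnorm(n, 0, noise_sd) else 0
  out <- tibble::tibble(
    total_length = shapes$distal_shield_length + noise(),
    tube_width = pmax(shapes$tube_width + noise(), 1e-6),
    slit_length = pmax(shapes$slit_length + noise(), 0),
    central_area_closure = pmin(pmax(
      shapes$central_area_closure +
        (if (noise_sd > 0) rnorm(n, 0, noise_sd / 2) else 0), 0), 1)
  )
  out$ca_tube_length <- out$total_length - 2 * out$slit_length
  if (any(out$ca_tube_length < 0)) {
    stop("Derived central-area + tube length is negative: slit length ",
         "exceeds half the shield length.", call. = FALSE)
  }
  carry <- setdiff(names(shapes), c(req, names(out)))
  dplyr::bind_cols(out[, c("total_length", "ca_tube_length", "tube_width",
                           "slit_length", "central_area_closure")],
                   shapes[, carry, drop = FALSE])
}
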