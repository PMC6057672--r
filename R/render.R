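# Rendering of cross-polarized-light micrographs from ground-truth shapes.
#
# The optics model is deliberately first-order: below the first-order
# birefringence plateau of calcite (about 1.55 um retardation-equivalent
# thickness) grey level grows linearly with calcite thickness, then
# saturates. Grey = background + gain * min(thickness, saturation), plus
# additive Gaussian read noise, quantized to 16 bits.

#' Optics settings for a simulated polarized-light micrograph
#'
#' @param pixel_size Microns per pixel. Default 0.05 (x1000 magnification
#'   with a typical microscope camera).
#' @param grey_gain Grey levels per micron of calcite thickness.
#' @param saturation_thickness Thickness (um) at which the linear
#'   grey-thickness relation plateaus; 1.55 um for calcite under crossed
#'   polarizers.
#' @param background_level Mean background grey level.
#' @param noise_sd Standard deviation of additive Gaussian grey noise.
#' @param bit_depth Bits per pixel of the quantized raster (16 by default).
#' @return A list of class `plm_optics`.
#' @export
plm_optics <- function(pixel_size = 0.05, grey_gain = 38000,
                       saturation_thickness = 1.55, background_level = 400,
                       noise_sd = 50, bit_depth = 16) {
  if (pixel_size <= 0) stop("`pixel_size` must be positive.", call. = FALSE)
  if (grey_gain <= 0) stop("`grey_gain` must be positive.", call. = FALSE)
  structure(list(pixel_size = pixel_size, grey_gain = grey_gain,
                 saturation_thickness = saturation_thickness,
                 background_level = background_level, noise_sd = noise_sd,
                 bit_depth = bit_depth),
            class = "plm_optics")
}

#' Render shapes into a simulated polarized-light micrograph
#'
#' Places each ground-truth coccolith at a position (given or drawn on a
#' jittered grid that keeps shapes disjoint and away from the frame border),
#' rasterizes its thickness profile, and converts thickness to grey level
#' with the linear-plus-saturation optics model. The returned object carries
#' a ground-truth table linking every placement to its generating shape, so
#' downstream measurements can be scored exactly.
#'
#' @param shapes Tibble of shapes from [sample_shapes()] (rows are rendered
#'   in order; an empty tibble gives a background-only raster).
#' @param optics A [plm_optics()] object.
#' @param width,height Raster size in pixels.
#' @param positions Optional tibble with columns `x_um`, `y_um` (shape
#'   centres, microns from the top-left corner) and optionally `theta`
#'   (rotation, radians). When omitted, centres are laid out on a jittered
#'   grid with random orientations.
#' @param strict If `TRUE`, error when any thickness exceeds the saturation
#'   thickness (the mass of saturated pixels is not recoverable); if `FALSE`
#'   (default) such pixels are clipped.
#' @return An object of class `plm_image`: list with `raster` (height x
#'   width numeric matrix of grey levels, row-major, origin top-left),
#'   `optics`, and `ground_truth` (tibble: `particle_id`, `x_um`, `y_um`,
#'   `theta`, `variety`, `true_mass`, `distal_shield_length`).
#' @examples
#' set.seed(2)
#' img <- render_plm(sample_shapes(3, "A2"), width = 256, height = 256)
#' img
#' @export
render_plm <- function(shapes, optics = plm_optics(), width = 512,
                       height = 512, positions = NULL, strict = FALSE) {
  stopifnot(inherits(optics, "plm_optics"))
  if (width < 8 || height < 8) stop("Raster too small.", call. = FALSE)
  n <- nrow(shapes)
  px <- optics$pixel_size
  thick <- matrix(0, nrow = height, ncol = width)

  if (n > 0) {
    if (is.null(positions)) {
      positions <- grid_positions(shapes, width, height, px)
    } else {
      positions <- tibble::as_tibble(positions)
      if (!all(c("x_um", "y_um") %in% names(positions)) || nrow(positions) != n) {
        stop("`positions` needs `x_um`, `y_um` for every shape.", call. = FALSE)
      }
      if (!"theta" %in% names(positions)) positions$theta <- 0
    }
    for (i in seq_len(n)) {
      sh <- shapes[i, ]
      if (strict && max(sh$thickness_tube, sh$thickness_shield,
                        sh$thickness_central) > optics$saturation_thickness) {
        stop("Shape ", i, " exceeds the saturation thickness in strict mode.",
             call. = FALSE)
      }
      r_um <- sh$distal_shield_length / 2 + px
      # bounding box in pixel indices (pixel centres at (j - 0.5) * px)
      cx <- positions$x_um[i]; cy <- positions$y_um[i]
      jx <- max(1, floor((cx - r_um) / px)):min(width, ceiling((cx + r_um) / px) + 1)
      jy <- max(1, floor((cy - r_um) / px)):min(height, ceiling((cy + r_um) / px) + 1)
      if (!length(jx) || !length(jy)) next
      xs <- (jx - 0.5) * px - cx
      ys <- (jy - 0.5) * px - cy
      g <- expand.grid(y = ys, x = xs)
      t_sh <- shape_thickness(sh, g$x, g$y, positions$theta[i])
      block <- matrix(t_sh, nrow = length(jy), ncol = length(jx))
      thick[jy, jx] <- thick[jy, jx] + block
    }
  } else {
    positions <- tibble::tibble(x_um = numeric(), y_um = numeric(),
                                theta = numeric())
  }

  grey <- optics$background_level +
    optics$grey_gain * pmin(thick, optics$saturation_thickness)
  if (optics$noise_sd > 0) {
    grey <- grey + rnorm(length(grey), 0, optics$noise_sd)
  }
  maxg <- 2^optics$bit_depth - 1
  raster <- matrix(pmin(pmax(round(grey), 0), maxg), nrow = height)

  gt <- tibble::tibble(
    particle_id = seq_len(n),
    x_um = positions$x_um, y_um = positions$y_um, theta = positions$theta,
    variety = if (n) shapes$variety else character(),
    true_mass = if (n) shapes$true_mass else numeric(),
    distal_shield_length = if (n) shapes$distal_shield_length else numeric()
  )
  structure(list(raster = raster, optics = optics, ground_truth = gt),
            class = "plm_image")
}

# jittered grid keeping shapes disjoint and off the border
grid_positions <- function(shapes, width, height, px) {
  n <- nrow(shapes)
  r <- shapes$distal_shield_length / 2
  cell <- 2 * max(r) + 2.2     # um, keeps neighbours and their dim shields apart
  w_um <- width * px; h_um <- height * px
  ncol_g <- max(1, floor((w_um - cell) / cell))
  nrow_g <- max(1, floor((h_um - cell) / cell))
  if (n > ncol_g * nrow_g) {
    stop("Frame too small to place ", n, " disjoint shapes; enlarge the ",
         "raster or supply `positions`.", call. = FALSE)
  }
  idx <- seq_len(n) - 1
  gx <- idx %% ncol_g
  gy <- idx %/% ncol_g
  jit <- 0.15
  tibble::tibble(
    x_um = cell * (gx + 1) + runif(n, -jit, jit),
    y_um = cell * (gy + 1) + runif(n, -jit, jit),
    theta = runif(n, 0, pi)
  )
}

#' @export
print.plm_image <- function(x, ...) {
  cat(sprintf("Simulated PLM micrograph: %d x %d px (%.2f um/px), %d coccolith(s)\n",
              ncol(x$raster), nrow(x$raster), x$optics$pixel_size,
              nrow(x$ground_truth)))
  invisible(x)
}

#' @describeIn render_plm Display the raster with `ggplot2`.
#' @param object A `plm_image`.
#' @param ... Unused.
#' @method autoplot plm_image
#' @export
autoplot.plm_image <- function(object, ...) {
  df <- expand.grid(col = seq_len(ncol(object$raster)),
                    row = seq_len(nrow(object$raster)))
  df$grey <- as.vector(t(object$raster))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$grey)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (px)", y = "y (px)", fill = "grey")
}

#' Write / read a simulated micrograph as 16-bit TIFF with a YAML sidecar
#'
#' The raster is stored as a grey 16-bit TIFF; the optics metadata
#' (`pixel_size`, `grey_gain`, `saturation_thickness`, `background_level`)
#' as a YAML sidecar next to it, so a raster round-trips with everything
#' needed to convert grey back to calcite mass.
#'
#' @param image A `plm_image`.
#' @param path TIFF path; the sidecar is written to `<path>.yml`.
#' @return `write_plm_tiff` returns `path` invisibly; `read_plm_tiff`
#'   returns a `plm_image` (without ground truth, which is not stored in the
#'   image file — use [write_ground_truth()] for that).
#' @export
write_plm_tiff <- function(image, path) {
  stopifnot(inherits(image, "plm_image"))
  maxg <- 2^image$optics$bit_depth - 1
  tiff::writeTIFF(image$raster / maxg, path, bits.per.sample = 16L,
                  compression = "none")
  yaml::write_yaml(image$optics[c("pixel_size", "grey_gain",
                                  "saturation_thickness", "background_level",
                                  "noise_sd", "bit_depth")],
                   paste0(path, ".yml"))
  invisible(path)
}

#' @rdname write_plm_tiff
#' @export
read_plm_tiff <- function(path) {
  raw <- tiff::readTIFF(path)
  meta <- yaml::read_yaml(paste0(path, ".yml"))
  optics <- plm_optics(pixel_size = meta$pixel_size, grey_gain = meta$grey_gain,
                       saturation_thickness = meta$saturation_thickness,
                       background_level = meta$background_level,
                       noise_sd = meta$noise_sd %||% 0,
                       bit_depth = meta$bit_depth %||% 16)
  raster <- round(raw * (2^optics$bit_depth - 1))
  structure(list(raster = raster, optics = optics,
                 ground_truth = tibble::tibble()),
            class = "plm_image")
}

#' @rdname write_plm_tiff
#' @param file CSV path for the ground-truth table.
#' @export
write_ground_truth <- function(image, file) {
  stopifnot(inherits(image, "plm_image"))
  utils::write.csv(image$ground_truth, file, row.names = FALSE)
  invisible(file)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
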