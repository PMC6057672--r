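# Fixtures built in code: uniform-thickness discs and noiseless optics used
# across the geometry, rendering and measurement tests.

# A shape whose thickness is uniform over the whole (elliptical) outline:
# no slits, fully closed central area, all three zones at thickness `t`.
disc_shape <- function(diameter_um, t = 0.4, ellipticity = 1) {
  a <- diameter_um / 2
  tibble::tibble(
    variety = "A2",
    distal_shield_length = diameter_um,
    shield_ellipticity = ellipticity,
    tube_width = 0.3 * a,
    slit_length = 0,
    central_area_closure = 1,
    thickness_tube = t,
    thickness_shield = t,
    thickness_central = t,
    true_mass = pi * a * (a * ellipticity) * t * 2.7
  )
}

# Deterministic optics: no read noise, so grey levels are exact.
quiet_optics <- function(pixel_size = 0.05, grey_gain = 38000) {
  plm_optics(pixel_size = pixel_size, grey_gain = grey_gain, noise_sd = 0)
}

# Grid-free rasterized mass of an image: integrate background-subtracted
# grey over the whole frame (the renderer's mass bookkeeping oracle).
frame_mass <- function(image) {
  opt <- image$optics
  sum(image$raster - opt$background_level) / opt$grey_gain *
    opt$pixel_size^2 * 2.7
}

# Independent numeric mass oracle: rasterize one shape's thickness profile
# on a fine grid and sum thickness x cell area x calcite density.
numeric_mass <- function(shape, step = 0.005) {
  a <- shape$distal_shield_length / 2 + step
  g <- expand.grid(x = seq(-a, a, by = step), y = seq(-a, a, by = step))
  t <- coccolithr:::shape_thickness(shape, g$x, g$y, 0)
  sum(t) * step^2 * 2.7
}
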