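# Parametric ground-truth coccolith geometry and per-variety sampling.
#
# A coccolith is modelled as three concentric elliptical zones sharing the
# distal shield's outline (semi-major a = DSL/2, semi-minor b = a * ellipticity):
#   * distal shield rim: ellipse scale (a - SL)/a .. 1, thin calcite;
#   * tube ring:         scale (a - SL - TW)/a .. (a - SL)/a, thick calcite
#     (the optically bright region under crossed polarizers);
#   * central area:      inside the tube; a fraction `closure` is covered by
#     a calcite plate, the rest is open.
# SL (slit length) is the radial extent of the inter-element slits outside
# the tube; TW (tube width) the radial width of the tube ring. Both are
# measured along the major axis.

VARIETY_LEVELS <- c("A1", "A2", "A3a", "A3b", "BC")

#' Per-variety shape and calcification distribution settings
#'
#' Location/scale settings of the distributions each calcification variety's
#' coccoliths are drawn from. The defaults encode the qualitative contrasts
#' that define the varieties: A1 small and lightly calcified with slits
#' longer than the tube is wide, A2 intermediate with slit length close to
#' tube width, A3b large and heavily calcified with short slits, A3a with a
#' nearly or completely closed central area, and B/C small with a thin,
#' lightly calcified shield. They are free parameters of the simulator, not
#' estimates for any real population.
#'
#' @param margin Relative separation `epsilon` enforced between the SL/TW
#'   ratio classes at generation time (A1 draws satisfy
#'   `SL > TW * (1 + margin)`, A3b draws `SL < TW * (1 - margin)`, A2 draws
#'   stay within half the margin of equality). Default 0.15.
#' @param closure_cut Central-area closure fraction at or above which a
#'   coccolith reads as "nearly or completely closed" (A3a). Default 0.75.
#' @return A list of class `variety_params`: per-variety means/sds of
#'   distal-shield length (`dsl_mean`, `dsl_sd`, microns), relative tube
#'   width (`tw_rel_mean`, `tw_rel_sd`, as a fraction of the shield length,
#'   so tube and slit geometry scale with coccolith size), calcite
#'   thicknesses (`t_tube`, `t_shield`, `t_central`, microns), shield
#'   ellipticity, plus `margin` and `closure_cut`.
#' @export
variety_params <- function(margin = 0.15, closure_cut = 0.75) {
  stopifnot(margin > 0, margin < 0.5, closure_cut > 0.5, closure_cut <= 1)
  # tube width is allometric: tw_rel_* are fractions of the distal-shield
  # length, so slit/tube geometry scales with coccolith size
  tab <- tibble::tribble(
    ~variety, ~dsl_mean, ~dsl_sd, ~tw_rel_mean, ~tw_rel_sd, ~t_tube, ~t_shield, ~t_central,
    "A1",        3.0,     0.30,      0.100,       0.012,     0.35,     0.06,      0.20,
    "A2",        3.3,     0.30,      0.130,       0.014,     0.50,     0.06,      0.25,
    "A3a",       3.1,     0.28,      0.160,       0.015,     0.60,     0.06,      0.45,
    "A3b",       3.8,     0.32,      0.160,       0.016,     0.65,     0.06,      0.30,
    "BC",        2.6,     0.28,      0.105,       0.012,     0.25,     0.05,      0.15
  )
  structure(list(table = tab, ellipticity = 0.8, margin = margin,
                 closure_cut = closure_cut),
            class = "variety_params")
}

#' Draw ground-truth coccoliths of a given calcification variety
#'
#' Samples parametric coccolith shapes whose slit-length/tube-width relation
#' and central-area closure satisfy the defining rule of the requested
#' variety by construction, with the generator's separation margin. The true
#' calcite mass of each shape is the exact integral of thickness times area
#' times calcite density over the three zones (see [coccolith_mass()]).
#'
#' @param n Number of coccoliths to draw.
#' @param variety One of `"A1"`, `"A2"`, `"A3a"`, `"A3b"`, `"BC"`.
#' @param params A [variety_params()] object.
#' @param constants A [calcite_constants()] object (only `rho_c` is used).
#' @return A tibble with one row per coccolith: `variety`,
#'   `distal_shield_length`, `shield_ellipticity`, `tube_width`,
#'   `slit_length`, `central_area_closure`, `thickness_tube`,
#'   `thickness_shield`, `thickness_central` and `true_mass` (pg).
#' @examples
#' set.seed(1)
#' sample_shapes(3, "A1")
#' @export
sample_shapes <- function(n, variety, params = variety_params(),
                          constants = calcite_constants()) {
  stopifnot(inherits(params, "variety_params"), n >= 0)
  if (length(variety) != 1 || !variety %in% VARIETY_LEVELS) {
    stop("Unknown variety label: ", paste(variety, collapse = ", "),
         ". Expected one of ", paste(VARIETY_LEVELS, collapse = ", "), ".",
         call. = FALSE)
  }
  p <- params$table[params$table$variety == variety, ]
  if (any(unlist(p[, -1]) <= 0)) {
    stop("Distribution settings for ", variety, " must all be positive.",
         call. = FALSE)
  }
  if (n == 0) return(empty_shape_tbl())
  eps <- params$margin
  cut <- params$closure_cut

  dsl <- truncnorm_pos(n, p$dsl_mean, p$dsl_sd, lower = 1.5)
  tw <- dsl * truncnorm_pos(n, p$tw_rel_mean, p$tw_rel_sd, lower = 0.03)
  sl <- switch(variety,
    # A1: slits clearly longer than the tube is wide
    A1  = tw * (1 + eps + abs(rnorm(n, 0.25, 0.10)) + 0.02),
    # A2: slit length within half the margin of tube width
    A2  = tw * (1 + runif(n, -eps / 2, eps / 2)),
    # high-calcified: short slits
    A3a = tw * pmax(0.10, 1 - eps - abs(rnorm(n, 0.25, 0.10)) - 0.02),
    A3b = tw * pmax(0.10, 1 - eps - abs(rnorm(n, 0.25, 0.10)) - 0.02),
    # B/C carries no slit/tube rule; keep slits moderate
    BC  = tw * runif(n, 0.8, 1.4)
  )
  closure <- switch(variety,
    A1  = rbeta(n, 1.2, 8) * (cut - 0.05),
    A2  = rbeta(n, 1.5, 5) * (cut - 0.05),
    A3a = cut + (1 - cut) * rbeta(n, 2, 1.2),
    A3b = rbeta(n, 2, 4) * (cut - 0.05),
    BC  = rbeta(n, 1.2, 8) * (cut - 0.05)
  )
  # keep the annuli inside the shield: SL + TW <= DSL/2 (leave room for a
  # central area of at least 20% of the semi-major axis)
  a <- dsl / 2
  over <- (sl + tw) > 0.8 * a
  if (any(over)) {
    scl <- 0.8 * a[over] / (sl[over] + tw[over])
    sl[over] <- sl[over] * scl
    tw[over] <- tw[over] * scl
  }
  shapes <- tibble::tibble(
    variety = variety,
    distal_shield_length = dsl,
    shield_ellipticity = params$ellipticity,
    tube_width = tw,
    slit_length = sl,
    central_area_closure = closure,
    thickness_tube = truncnorm_pos(n, p$t_tube, 0.12 * p$t_tube, lower = 0.02),
    thickness_shield = truncnorm_pos(n, p$t_shield, 0.10 * p$t_shield, lower = 0.01),
    thickness_central = truncnorm_pos(n, p$t_central, 0.12 * p$t_central, lower = 0.01)
  )
  shapes$true_mass <- coccolith_mass(shapes, constants)
  shapes
}

empty_shape_tbl <- function() {
  tibble::tibble(
    variety = character(), distal_shield_length = numeric(),
    shield_ellipticity = numeric(), tube_width = numeric(),
    slit_length = numeric(), central_area_closure = numeric(),
    thickness_tube = numeric(), thickness_shield = numeric(),
    thickness_central = numeric(), true_mass = numeric()
  )
}

# normal truncated below at `lower` by resampling; scale must be positive
truncnorm_pos <- function(n, mean, sd, lower) {
  if (sd <= 0 || mean <= 0) stop("Non-positive scale parameter.", call. = FALSE)
  x <- rnorm(n, mean, sd)
  for (i in seq_len(50)) {
    bad <- x < lower
    if (!any(bad)) break
    x[bad] <- rnorm(sum(bad), mean, sd)
  }
  pmax(x, lower)
}

#' Analytic calcite mass of parametric coccoliths
#'
#' Exact integral of thickness x area x calcite density over the three
#' elliptical zones of the shape model. With semi-axes `a = DSL/2` and
#' `b = a * ellipticity`, the area between concentric scales `s_lo` and
#' `s_hi` of the ellipse is `pi * a * b * (s_hi^2 - s_lo^2)`; the central
#' plate covers the fraction `central_area_closure` of the inner zone.
#'
#' @param shapes Tibble of shapes as returned by [sample_shapes()].
#' @param constants A [calcite_constants()] object; `rho_c` converts calcite
#'   volume (cubic microns) to mass (pg).
#' @return Numeric vector of masses, pg.
#' @export
coccolith_mass <- function(shapes, constants = calcite_constants()) {
  a <- shapes$distal_shield_length / 2
  b <- a * shapes$shield_ellipticity
  s1 <- (a - shapes$slit_length) / a
  s2 <- (a - shapes$slit_length - shapes$tube_width) / a
  stopifnot(all(s2 > 0))
  area <- pi * a * b
  vol <- area * (1 - s1^2) * shapes$thickness_shield +
    area * (s1^2 - s2^2) * shapes$thickness_tube +
    area * s2^2 * shapes$central_area_closure * shapes$thickness_central
  vol * constants$rho_c
}

# Thickness (um) of one shape at image coordinates (x, y) in um relative to
# the shape centre, after rotating by -theta. Vectorized over x, y.
shape_thickness <- function(shape, x, y, theta = 0) {
  ct <- cos(theta); st <- sin(theta)
  xr <- ct * x + st * y
  yr <- -st * x + ct * y
  a <- shape$distal_shield_length / 2
  b <- a * shape$shield_ellipticity
  s <- sqrt((xr / a)^2 + (yr / b)^2)   # elliptical scale of the point
  s1 <- (a - shape$slit_length) / a
  s2 <- (a - shape$slit_length - shape$tube_width) / a
  s_plate <- s2 * sqrt(shape$central_area_closure)  # closed part of centre
  t <- numeric(length(s))
  t[s <= 1 & s > s1] <- shape$thickness_shield
  t[s <= s1 & s > s2] <- shape$thickness_tube
  t[s <= s_plate] <- shape$thickness_central
  t
}
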