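# Virtual west-east transect: smooth environmental gradients along
# longitude and Gaussian niche responses that turn those gradients into
# variety abundances. This is the synthetic stand-in for an oceanographic
# section — a basin whose eastern end is warmer, saltier, more alkaline and
# more oligotrophic than its Atlantic-influenced western end.

#' Default environmental gradients along the virtual transect
#'
#' Linear (or gently sigmoid) profiles of each environmental variable
#' against longitude, plus an exponential light profile against depth.
#' Values emulate a Mediterranean-like west-east section: eastward the water
#' gets warmer, saltier, more alkaline, slightly CO2-richer and markedly
#' poorer in nutrients. The profiles are simulator choices, not estimates.
#'
#' @return A named list of functions `f(longitude, depth)` returning one
#'   value per station, one entry per environmental variable.
#' @export
default_env_gradients <- function() {
  # longitude spans about -6.6 to 31 degrees E; s in [0, 1] west -> east
  sc <- function(lon) (lon + 6.6) / 37.6
  list(
    temperature = function(lon, depth) 15.5 + 5.5 * sc(lon) - 0.010 * depth,
    salinity = function(lon, depth) 36.3 + 3.1 * sc(lon),
    total_alkalinity = function(lon, depth) 2330 + 290 * sc(lon),
    ph = function(lon, depth) 8.10 - 0.06 * sc(lon),
    pco2 = function(lon, depth) 380 + 45 * sc(lon),
    carbonate_ion = function(lon, depth) 225 + 35 * sc(lon),
    nitrate_nitrite = function(lon, depth) pmax(0.05, 2.2 - 2.0 * sc(lon)) +
      0.004 * depth,
    phosphate = function(lon, depth) pmax(0.01, 0.10 - 0.085 * sc(lon)) +
      0.0002 * depth,
    par_percent = function(lon, depth) 100 * exp(-0.055 * depth)
  )
}

#' Default niche responses of the calcification varieties
#'
#' Gaussian response curves on standardized environmental variables — the
#' standard community-ecology unimodal abundance model. The signs mirror the
#' qualitative field pattern this simulator emulates: the low-calcified A1
#' prefers fresher western water, A3b saltier eastern water, A3a colder and
#' nutrient-richer water, A2 is broadly tolerant, and the B/C morphotype
#' tracks the cool Atlantic inflow.
#'
#' @return A tibble with columns `variety`, `variable`, `optimum` and
#'   `tolerance` (both on the standardized scale of the variable across the
#'   transect), and `weight` (maximum relative abundance).
#' @export
default_variety_niches <- function() {
  tibble::tribble(
    ~variety, ~variable,         ~optimum, ~tolerance, ~weight,
    "A1",     "salinity",           -1.2,      1.3,      1.00,
    "A2",     "salinity",            0.0,      3.0,      1.05,
    "A3a",    "temperature",        -1.6,      0.8,      0.55,
    "A3a",    "nitrate_nitrite",     1.2,      1.5,      1.00,
    "A3b",    "salinity",            1.5,      1.0,      0.75,
    "BC",     "temperature",        -2.0,      0.8,      0.60
  )
}

#' Configuration of a virtual sampling transect
#'
#' @param n_stations Number of stations, evenly spaced in longitude between
#'   `lon_range[1]` (west) and `lon_range[2]` (east).
#' @param depths Sampling depths in metres (every station is sampled at
#'   every depth).
#' @param coccoliths_per_sample Number of Type A + B/C coccoliths drawn per
#'   sample. Default 300, the usual per-sample counting effort for
#'   birefringence mass measurement.
#' @param env_gradients Named list of gradient functions, as
#'   [default_env_gradients()].
#' @param variety_niches Niche tibble, as [default_variety_niches()].
#' @param params A [variety_params()] object for the shape draws.
#' @param lon_range Longitude span, degrees east.
#' @param env_noise_sd Standard deviation of multiplicative log-normal
#'   station-to-station environmental scatter (on the standardized scale).
#' @return A list of class `transect_config`.
#' @export
transect_config <- function(n_stations = 20, depths = c(25),
                            coccoliths_per_sample = 300,
                            env_gradients = default_env_gradients(),
                            variety_niches = default_variety_niches(),
                            params = variety_params(),
                            lon_range = c(-6.6, 31.0),
                            env_noise_sd = 0.15) {
  stopifnot(n_stations >= 0, length(depths) >= 1,
            coccoliths_per_sample >= 1, inherits(params, "variety_params"))
  unknown <- setdiff(unique(variety_niches$variable), names(env_gradients))
  if (length(unknown)) {
    stop("Niche responses reference unknown environmental variable(s): ",
         paste(unknown, collapse = ", "), ".", call. = FALSE)
  }
  structure(list(n_stations = n_stations, depths = depths,
                 coccoliths_per_sample = coccoliths_per_sample,
                 env_gradients = env_gradients,
                 variety_niches = variety_niches, params = params,
                 lon_range = lon_range, env_noise_sd = env_noise_sd),
            class = "transect_config")
}

#' Generate a virtual transect: environment table and coccolith sets
#'
#' Evaluates the configured environmental gradients at every
#' station-by-depth sample, standardizes each variable across samples,
#' turns the Gaussian niche responses into per-variety multinomial
#' probabilities, draws variety counts, and samples ground-truth coccolith
#' shapes for every drawn coccolith. Deterministic for a fixed seed.
#'
#' @param config A [transect_config()].
#' @param seed Integer seed; the run is byte-reproducible given the same
#'   config and seed.
#' @return A list of class `transect` with `env` (one row per sample:
#'   `station`, `longitude_e`, `depth_m` and the environmental variables)
#'   and `coccoliths` (one row per coccolith: `station`, `depth_m`,
#'   `variety`, shape columns as in [sample_shapes()]).
#' @examples
#' tr <- generate_transect(transect_config(n_stations = 3,
#'                                         coccoliths_per_sample = 50),
#'                         seed = 1)
#' dplyr::count(tr$coccoliths, station)
#' @export
generate_transect <- function(config = transect_config(), seed = 1) {
  stopifnot(inherits(config, "transect_config"))
  set.seed(seed)
  if (config$n_stations == 0) {
    return(structure(list(env = empty_env_tbl(config),
                          coccoliths = dplyr::mutate(empty_shape_tbl(),
                                                     station = integer(),
                                                     depth_m = numeric(),
                                                     .before = 1)),
                     class = "transect"))
  }
  lon <- seq(config$lon_range[1], config$lon_range[2],
             length.out = max(config$n_stations, 2))[seq_len(config$n_stations)]
  grid <- tidyr::expand_grid(station = seq_len(config$n_stations),
                             depth_m = config$depths)
  grid$longitude_e <- lon[grid$station]

  env <- grid
  for (v in names(config$env_gradients)) {
    env[[v]] <- config$env_gradients[[v]](grid$longitude_e, grid$depth_m)
  }
  # small station-to-station scatter so ranks are not perfectly tied
  if (config$env_noise_sd > 0) {
    for (v in setdiff(names(config$env_gradients), "par_percent")) {
      s <- sd(env[[v]])
      if (is.finite(s) && s > 0) {
        env[[v]] <- env[[v]] + rnorm(nrow(env), 0, config$env_noise_sd * s)
      }
    }
  }
  env$par_percent <- pmin(pmax(env$par_percent, 0), 100)

  # standardized environment for the niche model
  z <- env
  for (v in names(config$env_gradients)) {
    z[[v]] <- as.numeric(scale(env[[v]]))
    if (any(!is.finite(z[[v]]))) z[[v]] <- 0   # constant variable
  }

  niches <- config$variety_niches
  varieties <- VARIETY_LEVELS
  weights <- matrix(1, nrow = nrow(env), ncol = length(varieties),
                    dimnames = list(NULL, varieties))
  for (i in seq_len(nrow(niches))) {
    v <- niches$variety[i]
    zz <- z[[niches$variable[i]]]
    weights[, v] <- weights[, v] * niches$weight[i] *
      exp(-(zz - niches$optimum[i])^2 / (2 * niches$tolerance[i]^2))
  }
  # varieties without any configured response get a small uniform floor
  no_niche <- setdiff(varieties, unique(niches$variety))
  weights[, no_niche] <- 0.1
  probs <- weights / rowSums(weights)

  coccoliths <- purrr::map_dfr(seq_len(nrow(env)), function(r) {
    counts <- as.integer(rmultinom(1, config$coccoliths_per_sample, probs[r, ]))
    sets <- purrr::map2_dfr(varieties, counts, function(v, k) {
      if (k == 0) return(empty_shape_tbl())
      sample_shapes(k, v, config$params)
    })
    dplyr::mutate(sets, station = env$station[r], depth_m = env$depth_m[r],
                  .before = 1)
  })
  structure(list(env = env, coccoliths = coccoliths), class = "transect")
}

empty_env_tbl <- function(config) {
  out <- tibble::tibble(station = integer(), depth_m = numeric(),
                        longitude_e = numeric())
  for (v in names(config$env_gradients)) out[[v]] <- numeric()
  out
}

#' @export
print.transect <- function(x, ...) {
  cat(sprintf("Virtual transect: %d sample(s), %d coccolith(s)\n",
              nrow(x$env), nrow(x$coccoliths)))
  invisible(x)
}

#' Write transect tables to CSV
#'
#' @param transect A `transect` from [generate_transect()].
#' @param dir Output directory (created if needed); writes
#'   `environment.csv` and `coccoliths.csv`.
#' @return `dir`, invisibly.
#' @export
write_transect_csv <- function(transect, dir) {
  stopifnot(inherits(transect, "transect"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(transect$env, file.path(dir, "environment.csv"),
                   row.names = FALSE)
  utils::write.csv(transect$coccoliths, file.path(dir, "coccoliths.csv"),
                   row.names = FALSE)
  invisible(dir)
}
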