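# End-to-end run over a virtual transect: simulate -> measure -> calibrate
# -> index -> classify -> ecology statistics, under one seed.

#' Emulate per-coccolith birefringence measurements from ground truth
#'
#' The fast, table-driven stand-in for rendering and re-segmenting every
#' micrograph: the apparent length of a coccolith under crossed polarizers
#' is its bright central-area-plus-tube extent (`DSL - 2 * SL`, the thin
#' distal-shield rim being too faint to segment), and the measured mass is
#' the true calcite mass, both perturbed by relative Gaussian measurement
#' noise. Use [render_plm()] + [measure_plm()] for the image-based route;
#' this emulation reproduces its error structure at transect scale.
#'
#' @param coccoliths Shape tibble (with `station` / `depth_m` columns kept
#'   if present).
#' @param mass_cv,length_cv Relative measurement noise (coefficient of
#'   variation) on mass and apparent length.
#' @return Tibble with `mass_pg`, `apparent_length_um`, `retained` and the
#'   carried columns.
#' @export
emulate_plm_measurements <- function(coccoliths, mass_cv = 0.03,
                                     length_cv = 0.02) {
  n <- nrow(coccoliths)
  apparent <- (coccoliths$distal_shield_length - 2 * coccoliths$slit_length) *
    (1 + rnorm(n, 0, length_cv))
  keys <- intersect(c("station", "depth_m", "variety"), names(coccoliths))
  dplyr::bind_cols(
    coccoliths[, keys, drop = FALSE],
    tibble::tibble(
      mass_pg = coccoliths$true_mass * (1 + rnorm(n, 0, mass_cv)),
      apparent_length_um = pmax(apparent, 0.2),
      retained = TRUE
    )
  )
}

#' Run the whole analysis over a virtual transect
#'
#' One-seed pipeline: generate the transect, take SEM-style measurements
#' and classify every Type A coccolith into its calcification variety,
#' emulate (or render) the birefringence mass/length measurements, fit the
#' apparent-length calibration on a reference subset of flat-lying
#' coccoliths, build per-sample summaries (`M_s`, `L_c`, `C_i`, variety
#' percentages), and correlate everything with the environmental table.
#'
#' @param config A [transect_config()].
#' @param seed Integer seed controlling every random draw.
#' @param policy A [classification_policy()].
#' @param calibration `"refit"` (default: fit the length correction on
#'   `n_calibration` simulated reference pairs) or a `length_calibration`
#'   object (e.g. [default_length_calibration()]).
#' @param n_calibration Number of reference coccoliths used to refit the
#'   calibration. Default 300 (six samples of fifty flat-lying coccoliths).
#' @param sem_noise_sd Measurement noise (um) on the SEM-style reads used
#'   for classification.
#' @param run_cca Also run the CCA of variety percentages against the
#'   environmental variables (needs >= 4 samples).
#' @return A list of class `transect_run`: `env`, `summaries` (per-sample
#'   tibble), `varieties` (long per-sample variety percentages),
#'   `calibration`, `correlations` (Spearman battery of `m_s_pg`, `c_i`,
#'   `l_c_um`, `typeA_pct` and variety percentages against the
#'   environmental variables), and `cca` (a `cca_result` or `NULL`).
#' @examples
#' \donttest{
#' run <- run_transect_pipeline(transect_config(n_stations = 6,
#'                                              coccoliths_per_sample = 80),
#'                              seed = 1)
#' run$summaries
#' }
#' @export
run_transect_pipeline <- function(config = transect_config(), seed = 1,
                                  policy = classification_policy(),
                                  calibration = "refit",
                                  n_calibration = 300, sem_noise_sd = 0,
                                  run_cca = TRUE) {
  tr <- generate_transect(config, seed = seed)
  if (!nrow(tr$coccoliths)) stop("Empty transect.", call. = FALSE)

  # SEM route: measure and classify the Type A coccoliths per sample
  sem <- measure_sem(tr$coccoliths, noise_sd = sem_noise_sd)
  type_a <- sem[sem$variety != "BC", ]
  classified <- classify_varieties(type_a, policy)
  varieties <- classified |>
    dplyr::group_by(.data$station, .data$depth_m) |>
    dplyr::reframe(tabulate_varieties(.data$variety))
  type_a_pct <- sem |>
    dplyr::group_by(.data$station, .data$depth_m) |>
    dplyr::summarise(typeA_pct = 100 * mean(.data$variety != "BC"),
                     .groups = "drop")

  # birefringence route: per-coccolith mass and apparent length
  plm <- emulate_plm_measurements(tr$coccoliths)

  # calibration: reference pairs of (apparent, SEM total length)
  if (identical(calibration, "refit")) {
    ref_idx <- sample(nrow(tr$coccoliths),
                      min(n_calibration, nrow(tr$coccoliths)))
    pairs <- tibble::tibble(
      apparent_length = plm$apparent_length_um[ref_idx],
      sem_total_length = sem$total_length[ref_idx]
    )
    calibration <- fit_length_correction(pairs)
  }
  stopifnot(inherits(calibration, "length_calibration"))

  summaries <- summarize_samples(plm, varieties, calibration) |>
    dplyr::left_join(type_a_pct, by = c("station", "depth_m"))

  dat <- dplyr::left_join(summaries, tr$env, by = c("station", "depth_m"))
  morph_cols <- intersect(
    c("m_s_pg", "c_i", "l_c_um", "typeA_pct",
      "A1_pct", "A2_pct", "A3a_pct", "A3b_pct"),
    names(dat))
  env_cols <- setdiff(names(tr$env), c("station", "depth_m", "longitude_e"))
  correlations <- spearman_battery(dat, morph_cols, env_cols)

  cca <- NULL
  if (run_cca && nrow(dat) >= 4) {
    taxa <- dat[, intersect(c("typeA_pct", "A1_pct", "A2_pct", "A3a_pct",
                              "A3b_pct"), names(dat)), drop = FALSE]
    taxa[is.na(taxa)] <- 0
    cca <- cca_ordination(taxa, dat[, env_cols, drop = FALSE], n_axes = 2)
  }

  structure(list(env = tr$env, summaries = summaries, varieties = varieties,
                 calibration = calibration, correlations = correlations,
                 cca = cca),
            class = "transect_run")
}

#' @export
print.transect_run <- function(x, ...) {
  cat(sprintf("Transect run: %d sample(s)\n", nrow(x$summaries)))
  cat(sprintf("  M_s %.2f-%.2f pg, L_c %.2f-%.2f um, C_i %.2f-%.2f\n",
              min(x$summaries$m_s_pg), max(x$summaries$m_s_pg),
              min(x$summaries$l_c_um), max(x$summaries$l_c_um),
              min(x$summaries$c_i), max(x$summaries$c_i)))
  sig <- sum(x$correlations$significant, na.rm = TRUE)
  cat(sprintf("  %d of %d Spearman correlations significant at p <= 0.05\n",
              sig, nrow(x$correlations)))
  invisible(x)
}
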