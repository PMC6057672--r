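# Length-correction calibration and the size-normalized calcification index.

#' Physical constants for coccolith calcite mass
#'
#' The calcification index normalizes a measured mean coccolith mass by the
#' mass expected from the mean coccolith length: `M_n = k_s * L_c^3 * rho_c`,
#' where `k_s` is a shape-dependent volumetric constant for normally
#' calcified *Emiliania huxleyi* Type A coccoliths and `rho_c` is the density
#' of calcite.
#'
#' @param k_s Dimensionless shape constant relating coccolith volume to the
#'   cube of its distal-shield length. Default 0.02 (Type A).
#' @param rho_c Density of calcite, pg per cubic micron. Default 2.7.
#' @return A list of class `calcite_constants`.
#' @examples
#' calcite_constants()
#' @export
calcite_constants <- function(k_s = 0.02, rho_c = 2.7) {
  stopifnot(is.numeric(k_s), length(k_s) == 1, is.finite(k_s),
            is.numeric(rho_c), length(rho_c) == 1, is.finite(rho_c))
  if (k_s <= 0 || rho_c <= 0) {
    stop("`k_s` and `rho_c` must both be positive.", call. = FALSE)
  }
  structure(list(k_s = k_s, rho_c = rho_c), class = "calcite_constants")
}

#' @export
print.calcite_constants <- function(x, ...) {
  cat("Calcite constants: k_s =", x$k_s, ", rho_c =", x$rho_c, "pg/um^3\n")
  invisible(x)
}

#' Fit the apparent-length correction regression
#'
#' Coccolith lengths measured on cross-polarized-light micrographs miss the
#' faint outer distal shield: the segmented bright region ends near the tube,
#' so the apparent length systematically differs from the true distal-shield
#' length seen under the electron microscope. This fits an ordinary
#' least-squares line of the reference (SEM) total length on the apparent
#' (birefringence-derived) length, to be applied to uncalibrated samples.
#'
#' @param pairs Data frame with columns `apparent_length` and
#'   `sem_total_length`, both in microns, one row per calibration coccolith.
#' @return An object of class `length_calibration` with elements `slope`,
#'   `intercept` (microns), `r_squared`, `n_pairs`, and the underlying `lm`
#'   fit. [tidy()] and [glance()] methods are provided.
#' @seealso [default_length_calibration()] for the shipped fallback
#'   coefficients, [correct_length()] to apply a model.
#' @examples
#' pairs <- tibble::tibble(apparent_length = 2:6,
#'                         sem_total_length = 0.585 * (2:6) + 0.4537)
#' fit_length_correction(pairs)
#' @export
fit_length_correction <- function(pairs) {
  pairs <- as.data.frame(pairs)
  req <- c("apparent_length", "sem_total_length")
  if (!all(req %in% names(pairs))) {
    stop("`pairs` needs columns `apparent_length` and `sem_total_length`.",
         call. = FALSE)
  }
  x <- pairs$apparent_length
  y <- pairs$sem_total_length
  if (length(x) < 2) stop("At least 2 calibration pairs are required.", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("Calibration pairs must be finite.", call. = FALSE)
  }
  if (length(unique(x)) < 2) {
    stop("Apparent lengths are all identical; the slope is unidentifiable.",
         call. = FALSE)
  }
  fit <- lm(y ~ x)
  new_length_calibration(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r_squared = suppressWarnings(summary(fit))$r.squared,
    n_pairs = length(x),
    fit = fit
  )
}

new_length_calibration <- function(slope, intercept, r_squared, n_pairs,
                                   fit = NULL) {
  structure(
    list(slope = slope, intercept = intercept, r_squared = r_squared,
         n_pairs = n_pairs, fit = fit),
    class = "length_calibration"
  )
}

#' Shipped apparent-length correction model
#'
#' The fallback calibration used when no per-dataset SEM reference pairs are
#' available: corrected length = 0.585 x apparent length + 0.4537 microns,
#' an OLS fit of SEM distal-shield length on birefringence-derived length
#' over flat-lying Type A coccoliths spanning a wide length range.
#'
#' @return A `length_calibration` object with slope 0.585 and intercept
#'   0.4537 microns (`r_squared` and the stored fit are `NA`: only the
#'   coefficients are shipped).
#' @export
default_length_calibration <- function() {
  new_length_calibration(slope = 0.585, intercept = 0.4537,
                         r_squared = NA_real_, n_pairs = NA_integer_)
}

#' @export
print.length_calibration <- function(x, ...) {
  cat(sprintf("Length calibration: corrected = %.4g * apparent + %.4g um",
              x$slope, x$intercept), "\n")
  if (is.finite(x$r_squared)) {
    cat(sprintf("  R^2 = %.4f on %d pairs\n", x$r_squared, x$n_pairs))
  }
  invisible(x)
}

#' @method tidy length_calibration
#' @export
tidy.length_calibration <- function(x, ...) {
  if (!is.null(x$fit)) {
    out <- tibble::as_tibble(suppressWarnings(summary(x$fit))$coefficients,
                             rownames = "term")
    names(out) <- c("term", "estimate", "std.error", "statistic", "p.value")
    out$term <- c("intercept", "slope")
    return(out)
  }
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = c(x$intercept, x$slope),
                 std.error = NA_real_, statistic = NA_real_,
                 p.value = NA_real_)
}

#' @method glance length_calibration
#' @export
glance.length_calibration <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, n_pairs = x$n_pairs,
                 slope = x$slope, intercept = x$intercept)
}

#' Apply a length-correction model
#'
#' @param apparent_length Numeric vector of apparent lengths, microns; must
#'   be positive.
#' @param model A `length_calibration` object. Defaults to the shipped
#'   coefficients.
#' @return Numeric vector of corrected lengths `slope * x + intercept`.
#'   Non-positive corrected lengths are replaced by `NA` with a warning: they
#'   indicate the model was applied outside its calibrated range.
#' @examples
#' correct_length(3.0)  # 0.585 * 3 + 0.4537 = 2.2087
#' @export
correct_length <- function(apparent_length, model = default_length_calibration()) {
  stopifnot(inherits(model, "length_calibration"))
  if (!all(is.finite(apparent_length)) || any(apparent_length <= 0)) {
    stop("`apparent_length` must be finite and positive.", call. = FALSE)
  }
  out <- model$slope * apparent_length + model$intercept
  bad <- out <= 0
  if (any(bad)) {
    warning(sum(bad), " corrected length(s) were non-positive; set to NA.",
            call. = FALSE)
    out[bad] <- NA_real_
  }
  out
}

#' Length-normalized coccolith mass
#'
#' The mass a coccolith of mean corrected length `L_c` would have if it were
#' a normally calcified Type A coccolith: `M_n = k_s * L_c^3 * rho_c` (volume
#' proportional to length cubed, times calcite density).
#'
#' @param l_c Corrected coccolith length, microns; positive.
#' @param constants A [calcite_constants()] object.
#' @return Normalized mass in picograms.
#' @examples
#' normalized_mass(3.45)  # 0.02 * 3.45^3 * 2.7
#' @export
normalized_mass <- function(l_c, constants = calcite_constants()) {
  stopifnot(inherits(constants, "calcite_constants"))
  if (!all(is.finite(l_c)) || any(l_c <= 0)) {
    stop("`l_c` must be finite and positive.", call. = FALSE)
  }
  constants$k_s * l_c^3 * constants$rho_c
}

#' Calcification index
#'
#' The size-normalized degree of calcification of a coccolith population:
#' the measured mean coccolith mass divided by the mass expected for a
#' normally calcified coccolith of the mean corrected length,
#' `C_i = M_s / (k_s * L_c^3 * rho_c)`. Values above 1 indicate coccoliths
#' carrying more calcite than their length alone predicts.
#'
#' @param m_s Mean measured coccolith mass of the sample, picograms.
#' @param l_c Mean corrected coccolith length of the sample, microns.
#' @param constants A [calcite_constants()] object.
#' @return Dimensionless calcification index (vectorized over `m_s`, `l_c`).
#' @examples
#' calcification_index(4.76, 3.45)
#' calcification_index(3.77, 3.25)
#' @export
calcification_index <- function(m_s, l_c, constants = calcite_constants()) {
  if (!all(is.finite(m_s)) || any(m_s <= 0)) {
    stop("`m_s` must be finite and positive.", call. = FALSE)
  }
  m_s / normalized_mass(l_c, constants)
}
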