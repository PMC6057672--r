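# Assignment of Type A coccoliths to calcification varieties from their
# SEM-style measurements.
#
# The rule set mirrors the morphological definitions of the four Type A
# calcification classes: a nearly-or-completely closed central area marks
# the high-calcified A3a regardless of the slit/tube relation; otherwise the
# ratio of slit length (SL) to tube width (TW) decides — slits clearly
# longer than the tube is wide mean low-calcified A1, clearly shorter mean
# high-calcified A3b, and anything within the tolerance band around
# equality is the medium-calcified A2. Ties at the band edges go to A2.

#' Classification policy for Type A calcification varieties
#'
#' @param epsilon Relative tolerance defining "SL approximately equal to
#'   TW": measurements with `TW * (1 - epsilon) <= SL <= TW * (1 + epsilon)`
#'   are A2. The morphological definitions leave the tolerance unquantified;
#'   0.10 is this package's operational default.
#' @param closure_cut Central-area closure fraction at or above which A3a is
#'   assigned, before any SL/TW comparison. Default 0.75 ("nearly or
#'   completely closed" is qualitative; the cut is configurable).
#' @return A list of class `classification_policy`.
#' @export
classification_policy <- function(epsilon = 0.10, closure_cut = 0.75) {
  if (!(epsilon > 0 && epsilon < 0.5)) {
    stop("`epsilon` must lie in (0, 0.5).", call. = FALSE)
  }
  if (!(closure_cut > 0.5 && closure_cut <= 1)) {
    stop("`closure_cut` must lie in (0.5, 1].", call. = FALSE)
  }
  structure(list(epsilon = epsilon, closure_cut = closure_cut),
            class = "classification_policy")
}

#' Classify Type A coccoliths into calcification varieties
#'
#' Applies the variety rules to each row of a measurement table and appends
#' a `variety` column. Every valid measurement receives exactly one of
#' `"A1"`, `"A2"`, `"A3a"`, `"A3b"`:
#' closure at or above the cut gives A3a (SL/TW ignored); otherwise
#' `SL > TW * (1 + epsilon)` gives A1, `SL < TW * (1 - epsilon)` gives A3b,
#' and the band between (edges included) gives A2.
#'
#' @param measurements Tibble with columns `slit_length`, `tube_width` and
#'   `central_area_closure` (as from [measure_sem()]).
#' @param policy A [classification_policy()].
#' @return `measurements` with a `variety` factor column appended.
#' @examples
#' m <- tibble::tibble(slit_length = c(1.3, 1.0, 0.7, 0.7),
#'                     tube_width = 1,
#'                     central_area_closure = c(0.1, 0.1, 0.95, 0.1))
#' classify_varieties(m)$variety
#' @export
classify_varieties <- function(measurements, policy = classification_policy()) {
  stopifnot(inherits(policy, "classification_policy"))
  req <- c("slit_length", "tube_width", "central_area_closure")
  if (!all(req %in% names(measurements))) {
    stop("`measurements` needs columns ", paste(req, collapse = ", "), ".",
         call. = FALSE)
  }
  sl <- measurements$slit_length
  tw <- measurements$tube_width
  cl <- measurements$central_area_closure
  if (!all(is.finite(sl)) || !all(is.finite(tw)) || !all(is.finite(cl))) {
    stop("Measurements must be finite.", call. = FALSE)
  }
  open_bad_tube <- cl < policy$closure_cut & tw <= 0
  if (any(open_bad_tube)) {
    stop("Non-positive tube width with an open central area in row(s) ",
         paste(utils::head(which(open_bad_tube), 5), collapse = ", "), ".",
         call. = FALSE)
  }
  variety <- dplyr::case_when(
    cl >= policy$closure_cut ~ "A3a",
    sl > tw * (1 + policy$epsilon) ~ "A1",
    sl < tw * (1 - policy$epsilon) ~ "A3b",
    TRUE ~ "A2"
  )
  out <- tibble::as_tibble(measurements)
  out$variety <- factor(variety, levels = c("A1", "A2", "A3a", "A3b"))
  out
}

#' Tabulate calcification-variety relative abundances
#'
#' Counts and percentages of the four Type A varieties, relative to the
#' total number of Type A coccoliths in the sample, so the four percentages
#' sum to 100. Morphotype B/C coccoliths must be excluded upstream; they are
#' not part of the Type A denominator.
#'
#' @param labels Factor/character vector of variety labels, or a data frame
#'   with a `variety` column.
#' @return A tibble with one row per variety (`A1`, `A2`, `A3a`, `A3b`):
#'   `variety`, `n`, `percent`, with the sample size as attribute
#'   `n_total`.
#' @examples
#' tabulate_varieties(rep(c("A1", "A2", "A3b"), c(30, 54, 16)))
#' @export
tabulate_varieties <- function(labels) {
  if (is.data.frame(labels)) labels <- labels$variety
  labels <- as.character(labels)
  if (!length(labels)) {
    stop("No Type A coccoliths: percentages are undefined for an empty ",
         "sample.", call. = FALSE)
  }
  valid <- c("A1", "A2", "A3a", "A3b")
  if (!all(labels %in% valid)) {
    stop("Labels outside the four Type A varieties: ",
         paste(unique(setdiff(labels, valid)), collapse = ", "), ".",
         call. = FALSE)
  }
  n <- as.integer(table(factor(labels, levels = valid)))
  out <- tibble::tibble(variety = valid, n = n,
                        percent = 100 * n / sum(n))
  attr(out, "n_total") <- sum(n)
  out
}
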