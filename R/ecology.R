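# Per-sample aggregation and the ecology statistics: tie-corrected Spearman
# rank correlations and canonical correspondence analysis (CCA).

#' Summarize per-coccolith measurements into per-sample morphometrics
#'
#' Aggregates intact-isolated per-coccolith measurements into the sample
#' quantities the calcification index needs: the mean coccolith mass `M_s`,
#' the corrected mean length `L_c` (calibration applied to the mean apparent
#' length; the correction is linear, so this equals the mean of corrected
#' lengths), the normalized mass `M_n` and the calcification index `C_i`.
#' Variety percentages are joined when supplied.
#'
#' @param particles Tibble with columns `mass_pg` and `apparent_length_um`,
#'   optionally `retained` (rows with `retained = FALSE` are dropped) and
#'   grouping columns `station`, `depth_m`.
#' @param varieties Optional per-sample variety percentages: tibble with the
#'   same grouping columns plus `variety` and `percent` (long form, as from
#'   [tabulate_varieties()] applied per sample).
#' @param calibration A `length_calibration`; default the shipped model.
#' @param constants A [calcite_constants()].
#' @param method `"sample_mean"` (default): `C_i` from the sample-mean mass
#'   and the cube of the corrected mean length. `"per_coccolith"`: the mean
#'   of individual mass / normalized-length ratios.
#' @return A tibble with one row per sample: grouping columns,
#'   `n_coccoliths`, `m_s_pg`, `l_c_um`, `m_n_pg`, `c_i`, and (when
#'   `varieties` is given) `A1_pct` ... `A3b_pct`.
#' @export
summarize_samples <- function(particles, varieties = NULL,
                              calibration = default_length_calibration(),
                              constants = calcite_constants(),
                              method = c("sample_mean", "per_coccolith")) {
  method <- match.arg(method)
  stopifnot(inherits(calibration, "length_calibration"))
  req <- c("mass_pg", "apparent_length_um")
  if (!all(req %in% names(particles))) {
    stop("`particles` needs columns ", paste(req, collapse = ", "), ".",
         call. = FALSE)
  }
  if ("retained" %in% names(particles)) {
    particles <- particles[particles$retained, ]
  }
  if (!nrow(particles)) {
    stop("No retained coccoliths: sample summaries are undefined.",
         call. = FALSE)
  }
  keys <- intersect(c("station", "depth_m"), names(particles))
  out <- particles |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      n_coccoliths = dplyr::n(),
      m_s_pg = mean(.data$mass_pg),
      l_c_um = correct_length(mean(.data$apparent_length_um), calibration),
      c_i_percoccolith = mean(.data$mass_pg /
        normalized_mass(correct_length(.data$apparent_length_um, calibration),
                        constants)),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      m_n_pg = normalized_mass(.data$l_c_um, constants),
      c_i = if (method == "sample_mean") .data$m_s_pg / .data$m_n_pg
            else .data$c_i_percoccolith
    ) |>
    dplyr::select(-"c_i_percoccolith")
  if (!is.null(varieties)) {
    wide <- varieties |>
      dplyr::mutate(variety = paste0(.data$variety, "_pct")) |>
      tidyr::pivot_wider(id_cols = dplyr::all_of(intersect(keys, names(varieties))),
                         names_from = "variety", values_from = "percent")
    out <- dplyr::left_join(out, wide,
                            by = intersect(keys, names(varieties)))
  }
  out
}

#' Tie-corrected Spearman rank correlation
#'
#' Spearman's rho as the Pearson correlation of mid-ranks (average ranks for
#' ties). Two-sided p-value by the t approximation with `n - 2` degrees of
#' freedom for `n > 9`, and by exact enumeration of all `n!` permutations of
#' one margin for `n <= 9`. Coefficients at `p <= 0.05` are flagged
#' significant.
#'
#' @param x,y Numeric vectors of equal length, `n >= 3`, finite.
#' @param alpha Significance level for the flag. Default 0.05.
#' @return A one-row tibble: `rho`, `p_value`, `n`, `significant`. A
#'   constant input yields `rho = NA` and `significant = NA` (undefined
#'   ranks).
#' @examples
#' spearman_cor(1:10, c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9))
#' @export
spearman_cor <- function(x, y, alpha = 0.05) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length.",
                                   call. = FALSE)
  n <- length(x)
  if (n < 3) stop("Need n >= 3.", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("Inputs must be finite.", call. = FALSE)
  }
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (sd(rx) == 0 || sd(ry) == 0) {
    return(tibble::tibble(rho = NA_real_, p_value = NA_real_, n = n,
                          significant = NA))
  }
  rho <- cor(rx, ry)
  if (n > 9) {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  } else {
    p <- exact_spearman_p(rx, ry, rho)
  }
  p <- min(p, 1)
  tibble::tibble(rho = rho, p_value = p, n = n, significant = p <= alpha)
}

# exact two-sided permutation p over all n! reorderings of one margin
exact_spearman_p <- function(rx, ry, rho_obs) {
  n <- length(rx)
  perms <- permutations_all(n)
  rx_perm <- matrix(rx[perms], nrow = nrow(perms))
  mx <- mean(rx); my <- mean(ry)
  sx <- sd(rx); sy <- sd(ry)
  rhos <- (rx_perm %*% ry - n * mx * my) / ((n - 1) * sx * sy)
  mean(abs(rhos) >= abs(rho_obs) - 1e-12)
}

permutations_all <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_all(n - 1)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  for (i in seq_len(n)) {
    rows <- (i - 1) * nrow(sub) + seq_len(nrow(sub))
    out[rows, 1] <- i
    rest <- seq_len(n)[-i]
    out[rows, -1] <- matrix(rest[sub], nrow = nrow(sub))
  }
  out
}

#' Spearman correlation battery
#'
#' All pairwise Spearman correlations between the columns of `left` and the
#' columns of `right`, with the usual significance stars (`**` for
#' `p <= 0.01`, `*` for `p <= 0.05`).
#'
#' @param data A data frame.
#' @param left,right Character vectors of column names to correlate
#'   (rows of the result are `left`, columns-as-rows pairs with `right`).
#' @param adjust P-value adjustment method passed to [stats::p.adjust()];
#'   `"none"` (default) reports raw p-values, `"BH"` applies
#'   Benjamini-Hochberg across the battery.
#' @return A tibble with one row per pair: `left`, `right`, `rho`,
#'   `p_value`, `n`, `significant`, `stars`.
#' @export
spearman_battery <- function(data, left, right, adjust = "none") {
  missing_cols <- setdiff(c(left, right), names(data))
  if (length(missing_cols)) {
    stop("Columns not in `data`: ", paste(missing_cols, collapse = ", "),
         ".", call. = FALSE)
  }
  out <- tidyr::expand_grid(left = left, right = right) |>
    dplyr::mutate(res = purrr::map2(.data$left, .data$right, function(l, r) {
      keep <- is.finite(data[[l]]) & is.finite(data[[r]])
      spearman_cor(data[[l]][keep], data[[r]][keep])
    })) |>
    tidyr::unnest("res")
  if (adjust != "none") {
    out$p_value <- stats::p.adjust(out$p_value, method = adjust)
    out$significant <- out$p_value <= 0.05
  }
  out$stars <- dplyr::case_when(
    is.na(out$p_value) ~ "",
    out$p_value <= 0.01 ~ "**",
    out$p_value <= 0.05 ~ "*",
    TRUE ~ ""
  )
  out
}

#' Canonical correspondence analysis of abundances against environment
#'
#' Constrained ordination relating a samples-by-taxa abundance table to
#' environmental predictors: chi-square-standardized abundance residuals
#' are projected (with row-mass weights) onto the space spanned by the
#' predictors and eigen-decomposed. Wraps [vegan::cca()] and extracts
#' eigenvalues, the share of constrained inertia per axis, species and site
#' scores (scaling 2), and the intraset correlations of each environmental
#' variable with each constrained axis.
#'
#' All-zero rows and columns are removed with a warning; exactly collinear
#' environmental columns are dropped with a warning before fitting.
#'
#' @param abundance Data frame or matrix, samples x taxa, non-negative.
#' @param env Data frame, samples x environmental variables, numeric;
#'   variables are standardized internally.
#' @param n_axes Number of constrained axes to report (default all,
#'   bounded by `min(n_taxa - 1, n_variables)`).
#' @param site_scores `"wa"` (weighted-average, default) or `"lc"`
#'   (linear-combination) site scores.
#' @return An object of class `cca_result`: list with `eigenvalues`,
#'   `percent_constrained` (share of constrained inertia per axis, sums to
#'   100), `percent_total` (share of total inertia), `species_scores`,
#'   `site_scores`, `env_axis_scores` (intraset correlations), `total_inertia`,
#'   `constrained_inertia`, and the underlying vegan `ordination`.
#' @export
cca_ordination <- function(abundance, env, n_axes = NULL,
                           site_scores = c("wa", "lc")) {
  site_scores <- match.arg(site_scores)
  A <- as.matrix(abundance)
  if (any(A < 0)) stop("Abundances must be non-negative.", call. = FALSE)
  E <- as.data.frame(env)
  if (nrow(A) != nrow(E)) stop("`abundance` and `env` row counts differ.",
                               call. = FALSE)
  zero_rows <- rowSums(A) == 0
  if (any(zero_rows)) {
    warning(sum(zero_rows), " all-zero sample row(s) removed.", call. = FALSE)
    A <- A[!zero_rows, , drop = FALSE]
    E <- E[!zero_rows, , drop = FALSE]
  }
  zero_cols <- colSums(A) == 0
  if (any(zero_cols)) {
    warning(sum(zero_cols), " all-zero taxon column(s) removed.", call. = FALSE)
    A <- A[, !zero_cols, drop = FALSE]
  }
  E <- as.data.frame(scale(as.matrix(E)))
  const <- vapply(E, function(z) !all(is.finite(z)), logical(1))
  if (any(const)) {
    warning("Dropping constant environmental column(s): ",
            paste(names(E)[const], collapse = ", "), ".", call. = FALSE)
    E <- E[, !const, drop = FALSE]
  }
  # drop exactly collinear predictors (keep the first of each aliased set)
  qrE <- qr(as.matrix(E))
  if (qrE$rank < ncol(E)) {
    keep <- qrE$pivot[seq_len(qrE$rank)]
    dropped <- names(E)[-keep]
    warning("Dropping collinear environmental column(s): ",
            paste(dropped, collapse = ", "), ".", call. = FALSE)
    E <- E[, sort(keep), drop = FALSE]
  }
  ord <- vegan::cca(A ~ ., data = E)
  eig <- ord$CCA$eig
  if (is.null(n_axes)) n_axes <- length(eig)
  n_axes <- min(n_axes, length(eig))
  use <- seq_len(n_axes)
  # intraset correlations: row-mass-weighted correlation of each
  # environmental variable with the linear-combination site scores
  w <- rowSums(A) / sum(A)
  lc <- as.matrix(vegan::scores(ord, display = "lc", scaling = 1,
                                choices = seq_along(eig)))
  intraset <- matrix(NA_real_, nrow = ncol(E), ncol = ncol(lc),
                     dimnames = list(names(E), colnames(lc)))
  for (j in seq_len(ncol(lc))) {
    intraset[, j] <- vapply(E, function(e) weighted_cor(e, lc[, j], w),
                            numeric(1))
  }
  structure(list(
    eigenvalues = unname(eig[use]),
    percent_constrained = unname(100 * eig[use] / sum(eig)),
    percent_total = unname(100 * eig[use] / ord$tot.chi),
    species_scores = vegan::scores(ord, display = "species", scaling = 2,
                                   choices = use),
    site_scores = vegan::scores(ord,
                                display = if (site_scores == "wa") "sites" else "lc",
                                scaling = 2, choices = use),
    env_axis_scores = intraset[, use, drop = FALSE],
    total_inertia = ord$tot.chi,
    constrained_inertia = sum(eig),
    ordination = ord
  ), class = "cca_result")
}

weighted_cor <- function(x, y, w) {
  w <- w / sum(w)
  mx <- sum(w * x); my <- sum(w * y)
  sxy <- sum(w * (x - mx) * (y - my))
  sxx <- sum(w * (x - mx)^2); syy <- sum(w * (y - my)^2)
  sxy / sqrt(sxx * syy)
}

#' @export
print.cca_result <- function(x, ...) {
  cat("Canonical correspondence analysis\n")
  cat(sprintf("  constrained inertia: %.4f of %.4f total (%.1f%%)\n",
              x$constrained_inertia, x$total_inertia,
              100 * x$constrained_inertia / x$total_inertia))
  for (i in seq_along(x$eigenvalues)) {
    cat(sprintf("  axis %d: eigenvalue %.4f (%.2f%% of constrained)\n",
                i, x$eigenvalues[i], x$percent_constrained[i]))
  }
  invisible(x)
}

#' @method tidy cca_result
#' @export
tidy.cca_result <- function(x, ...) {
  tibble::tibble(axis = seq_along(x$eigenvalues),
                 eigenvalue = x$eigenvalues,
                 percent_constrained = x$percent_constrained,
                 percent_total = x$percent_total)
}

#' @method glance cca_result
#' @export
glance.cca_result <- function(x, ...) {
  tibble::tibble(total_inertia = x$total_inertia,
                 constrained_inertia = x$constrained_inertia,
                 prop_constrained = x$constrained_inertia / x$total_inertia,
                 n_axes = length(x$eigenvalues))
}

#' @describeIn cca_ordination Triplot of sites, taxa and environmental
#'   arrows on the first two constrained axes.
#' @param object A `cca_result`.
#' @param ... Unused.
#' @method autoplot cca_result
#' @export
autoplot.cca_result <- function(object, ...) {
  if (length(object$eigenvalues) < 2) {
    stop("Need at least two constrained axes to plot.", call. = FALSE)
  }
  sp <- as.data.frame(object$species_scores[, 1:2, drop = FALSE])
  st <- as.data.frame(object$site_scores[, 1:2, drop = FALSE])
  en <- as.data.frame(object$env_axis_scores[, 1:2, drop = FALSE])
  names(sp) <- names(st) <- names(en) <- c("axis1", "axis2")
  sp$label <- rownames(object$species_scores)
  en$label <- rownames(object$env_axis_scores)
  mult <- max(abs(c(sp$axis1, sp$axis2, st$axis1, st$axis2)))
  ggplot2::ggplot() +
    ggplot2::geom_point(data = st, ggplot2::aes(.data$axis1, .data$axis2),
                        shape = 17, colour = "grey55") +
    ggplot2::geom_segment(data = en,
                          ggplot2::aes(x = 0, y = 0, xend = .data$axis1 * mult,
                                       yend = .data$axis2 * mult),
                          arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
                          colour = "steelblue") +
    ggplot2::geom_text(data = en,
                       ggplot2::aes(.data$axis1 * mult, .data$axis2 * mult,
                                    label = .data$label),
                       colour = "steelblue", vjust = -0.6, size = 3) +
    ggplot2::geom_point(data = sp, ggplot2::aes(.data$axis1, .data$axis2),
                        colour = "navy") +
    ggplot2::geom_text(data = sp, ggplot2::aes(.data$axis1, .data$axis2,
                                               label = .data$label),
                       colour = "navy", vjust = 1.5, size = 3) +
    ggplot2::labs(
      x = sprintf("CCA1 (%.1f%% of constrained inertia)",
                  object$percent_constrained[1]),
      y = sprintf("CCA2 (%.1f%%)", object$percent_constrained[2]))
}
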