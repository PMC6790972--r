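#' Inorganic carbon fixation rate from tissue 13C enrichment
#'
#' Converts end-point tissue delta13C enrichment into a fixation rate by a
#' two-pool mixing model: the fraction of tissue carbon newly fixed during
#' the incubation equals the tissue atom percent excess divided by the atom
#' percent excess of the DIC source pool, so
#' \deqn{rate = \frac{at\%_{final} - at\%_{initial}}{excess_{DIC}}
#'   \cdot \frac{C_{tissue}}{t}}
#' with atom percents from [delta13c_to_atom_percent()].
#'
#' The source-pool excess is taken as constant at its post-mixing value;
#' open or intermittently closed incubations lose added label, which biases
#' the rate downward and any N:C ratio built on it upward. The
#' `label_retention` scalar in (0, 1] down-weights `dic_excess`
#' accordingly when a loss estimate is available.
#'
#' Tissue depletion (final below initial delta13C) is not a fixation signal:
#' the rate is set to 0 and the row flagged `depleted_tissue`.
#'
#' @param data Tibble with columns `delta13c_initial`, `delta13c_final`
#'   (per mil vs VPDB), `tissue_carbon` (umol C per g), `duration_d` (days)
#'   and `dic_excess` (atom percent 13C excess of the DIC pool, e.g. from
#'   [mix_dic_label()]). Extra columns are carried through.
#' @param label_retention Fraction of the added label effectively retained
#'   in the DIC pool over the incubation, in (0, 1].
#' @param constants Isotope constants.
#' @return `data` with columns `cfix` (umol C per g per day) and `flags`
#'   appended.
#' @export
#' @examples
#' fixation_rate(tibble::tibble(
#'   delta13c_initial = -20, delta13c_final = -10,
#'   tissue_carbon = 100, duration_d = 7, dic_excess = 4.718))
fixation_rate <- function(data, label_retention = 1,
                          constants = isotope_constants()) {
  check_cols(data, c("delta13c_initial", "delta13c_final", "tissue_carbon",
                     "duration_d", "dic_excess"), "tracer data")
  if (label_retention <= 0 || label_retention > 1) {
    abort("`label_retention` must lie in (0, 1]",
          class = "nitrosponge_validation_error")
  }
  check_positive(data$duration_d, "duration_d")
  check_positive(data$dic_excess, "dic_excess")
  check_positive(data$tissue_carbon, "tissue_carbon")
  at_i <- delta13c_to_atom_percent(data$delta13c_initial, constants)
  at_f <- delta13c_to_atom_percent(data$delta13c_final, constants)
  excess <- at_f - at_i
  rate <- excess / (data$dic_excess * label_retention) *
    data$tissue_carbon / data$duration_d
  depleted <- excess < 0
  rate[depleted] <- 0
  data |>
    mutate(cfix = rate,
           flags = ifelse(depleted, "depleted_tissue", ""))
}

#' Nitrification-to-carbon-fixation coupling (N:C ratio)
#'
#' Ordinary least squares of gross nitrification (response, umol N per g
#' per day) on carbon fixation (predictor, umol C per g per day). For an
#' autotrophic ammonia oxidizer the slope is the moles of ammonia oxidized
#' per mole of carbon fixed (the N:C ratio); values far above the 7-29
#' range typical of free-living marine AOA point to label loss or to
#' mixotrophic growth of the symbiont.
#'
#' @param data Tibble with one row per paired observation.
#' @param cfix,nitrification Column names (unquoted) holding the carbon
#'   fixation and gross nitrification rates.
#' @return An object of class `nc_coupling` with [tidy()], [glance()] and
#'   [autoplot()] methods. `glance()` reports the N:C slope, its
#'   reciprocal, Pearson r and n.
#' @export
#' @examples
#' d <- tibble::tibble(cfix = c(.1, .2, .3), nitr = 43 * cfix)
#' glance(nc_coupling(d, cfix, nitr))
nc_coupling <- function(data, cfix, nitrification) {
  x <- dplyr::pull(data, {{ cfix }})
  y <- dplyr::pull(data, {{ nitrification }})
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 2) {
    abort("need at least two finite (cfix, nitrification) pairs",
          class = "nitrosponge_validation_error")
  }
  if (stats::var(x) == 0) {
    abort("zero variance in carbon fixation rates: slope undefined",
          class = "nitrosponge_degenerate_fit")
  }
  fit <- lm(y ~ x)
  r <- stats::cor(x, y)
  structure(
    list(fit = fit, data = tibble(cfix = x, nitrification = y),
         slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         r = r, n = length(x)),
    class = "nc_coupling"
  )
}

#' @export
print.nc_coupling <- function(x, ...) {
  cat(sprintf(
    "<nc_coupling> N:C slope %.3g (1/slope %.3g), intercept %.3g, r %.3f, n %d\n",
    x$slope, 1 / x$slope, x$intercept, x$r, x$n))
  invisible(x)
}

#' @rdname nc_coupling
#' @param x An `nc_coupling` object.
#' @param ... Unused.
#' @method tidy nc_coupling
#' @export
tidy.nc_coupling <- function(x, ...) {
  tidy_lm <- summary(x$fit)$coefficients
  tibble(term = c("intercept", "cfix"),
         estimate = tidy_lm[, 1], std_error = tidy_lm[, 2],
         statistic = tidy_lm[, 3], p_value = tidy_lm[, 4])
}

#' @rdname nc_coupling
#' @method glance nc_coupling
#' @export
glance.nc_coupling <- function(x, ...) {
  p <- summary(x$fit)$coefficients[2, 4]
  tibble(nc_ratio = x$slope, cn_ratio = 1 / x$slope,
         intercept = x$intercept, r = x$r, r_squared = x$r^2,
         p_value = p, n = x$n)
}

#' @rdname nc_coupling
#' @param object An `nc_coupling` object.
#' @method autoplot nc_coupling
#' @export
autoplot.nc_coupling <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$cfix, y = .data$nitrification)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope,
                         intercept = object$intercept,
                         linetype = "dashed") +
    ggplot2::labs(
      x = expression(paste("C fixation (", mu, "mol C ", g^-1, " ", d^-1, ")")),
      y = expression(paste("Gross nitrification (", mu, "mol N ", g^-1, " ", d^-1, ")")),
      subtitle = sprintf("N:C = %.1f, r = %.2f, n = %d",
                         object$slope, object$r, object$n)) +
    ggplot2::theme_minimal()
}
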