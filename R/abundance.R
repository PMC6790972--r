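#' Fit a qPCR standard curve
#'
#' Least-squares regression of quantification cycle (Cq) on log10 template
#' copies over a serial dilution. Amplification efficiency follows from the
#' slope as `10^(-1/slope) - 1`; a perfect doubling per cycle gives a slope
#' of -3.3219 and efficiency 1. Curves with efficiency outside \[0.9, 1.1\]
#' are flagged (`efficiency_low` / `efficiency_high`); efficiency outside
#' (0, 1.2\] or a non-negative slope is an error (`inverted_curve`).
#'
#' @param data Tibble with columns `copies` (template copies per ul; > 0)
#'   and `cq` (cycles), one row per standard well. Needs at least three
#'   distinct copy levels.
#' @return An object of class `standard_curve` with fields `slope`,
#'   `intercept` (Cq at 1 copy per ul), `r2`, `efficiency`, `flags` and the
#'   calibrated `cq_range`; has [tidy()] and [glance()] methods.
#' @export
#' @examples
#' d <- tibble::tibble(copies = 10^(0:6), cq = 38 - 3.3219 * (0:6))
#' glance(fit_standard_curve(d))
fit_standard_curve <- function(data) {
  check_cols(data, c("copies", "cq"), "standard curve data")
  check_positive(data$copies, "copies")
  if (length(unique(data$copies)) < 3) {
    abort("need at least 3 distinct copy levels for a standard curve",
          class = "nitrosponge_validation_error")
  }
  fit <- lm(cq ~ log10(copies), data = data)
  slope <- unname(coef(fit)[2])
  intercept <- unname(coef(fit)[1])
  if (slope >= 0) {
    abort("standard curve slope is non-negative (Cq must fall with copies)",
          class = "nitrosponge_inverted_curve")
  }
  efficiency <- 10^(-1 / slope) - 1
  flags <- flag_string(
    if (efficiency < 0.9) "efficiency_low" else "",
    if (efficiency > 1.1) "efficiency_high" else "")
  if (efficiency > 1.2) {
    warn(sprintf("implausible amplification efficiency %.3f", efficiency))
  }
  structure(
    list(slope = slope, intercept = intercept,
         r2 = suppressWarnings(summary(fit)$r.squared),
         efficiency = efficiency,
         flags = flags, cq_range = range(data$cq), fit = fit,
         data = as_tibble(data)),
    class = "standard_curve"
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "<standard_curve> slope %.4f, intercept %.2f, R2 %.4f, efficiency %.3f%s\n",
    x$slope, x$intercept, x$r2, x$efficiency,
    if (nzchar(x$flags)) paste0(" [", x$flags, "]") else ""))
  invisible(x)
}

#' @rdname fit_standard_curve
#' @param x,object A `standard_curve`.
#' @param ... Unused.
#' @method tidy standard_curve
#' @export
tidy.standard_curve <- function(x, ...) {
  co <- summary(x$fit)$coefficients
  tibble(term = c("intercept", "log10_copies"),
         estimate = co[, 1], std_error = co[, 2])
}

#' @rdname fit_standard_curve
#' @method glance standard_curve
#' @export
glance.standard_curve <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept, r2 = x$r2,
         efficiency = x$efficiency, flags = x$flags)
}

#' @rdname fit_standard_curve
#' @method autoplot standard_curve
#' @export
autoplot.standard_curve <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = log10(.data$copies), y = .data$cq)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         linetype = "dashed") +
    ggplot2::labs(x = expression(log[10]~copies~mu*l^-1), y = "Cq",
                  subtitle = sprintf("efficiency %.2f, R2 %.3f",
                                     object$efficiency, object$r2)) +
    ggplot2::theme_minimal()
}

#' Absolute quantification of unknowns against a standard curve
#'
#' Inverts the standard curve for each sample
#' (`copies/ul = 10^((cq - intercept) / slope)`), averages duplicate wells
#' on the Cq scale first, scales from the reaction template to the full DNA
#' elution, and normalizes to tissue wet weight:
#' `copies_per_g = copies_per_ul * elution_ul / tissue_g`. Cq values
#' outside the calibrated range are still inverted but flagged
#' `extrapolated`.
#'
#' @param data Tibble of unknown wells with columns `sample_id`, `cq`,
#'   `template_ul`, `elution_ul`, `tissue_g`.
#' @param curve A [fit_standard_curve()] object.
#' @param copies_per_cell rRNA operon copies per cell used to convert gene
#'   copies to cells; marine Thaumarchaeota carry a single operon.
#' @return A tibble, one row per sample: `sample_id`, `cq` (well-averaged),
#'   `copies_per_ul`, `copies_per_g`, `copies_per_cell`, `cells_per_g`,
#'   `flags`.
#' @export
quantify_qpcr <- function(data, curve, copies_per_cell = 1) {
  stopifnot(inherits(curve, "standard_curve"))
  check_cols(data, c("sample_id", "cq", "template_ul", "elution_ul",
                     "tissue_g"), "qPCR unknowns")
  check_positive(data$template_ul, "template_ul")
  check_positive(data$elution_ul, "elution_ul")
  check_positive(data$tissue_g, "tissue_g")
  check_positive(copies_per_cell, "copies_per_cell")
  data |>
    group_by(.data$sample_id) |>
    summarise(cq = mean(.data$cq),
              template_ul = .data$template_ul[1],
              elution_ul = .data$elution_ul[1],
              tissue_g = .data$tissue_g[1], .groups = "drop") |>
    mutate(
      copies_per_ul = 10^((.data$cq - curve$intercept) / curve$slope),
      copies_per_g = .data$copies_per_ul * .data$elution_ul / .data$tissue_g,
      copies_per_cell = copies_per_cell,
      cells_per_g = .data$copies_per_g / copies_per_cell,
      flags = ifelse(.data$cq < curve$cq_range[1] |
                       .data$cq > curve$cq_range[2], "extrapolated", "")
    )
}

#' Cell-specific ammonia-oxidation rate
#'
#' Divides a biomass-specific nitrification rate by symbiont density:
#' `rate * 1e9 / (copies_per_g / copies_per_cell)` converts umol N per g
#' per day into fmol N per cell per day. With one rRNA operon per cell the
#' gene-copy and cell interpretations coincide.
#'
#' @param rate Nitrification rate, umol N per g wet weight per day.
#' @param copies_per_g 16S rRNA gene copies per g wet weight; > 0.
#' @param copies_per_cell Gene copies per cell (default 1).
#' @return fmol N per cell per day. Vectorized.
#' @export
#' @examples
#' cell_specific_rate(10.8, 1.64e10)  # ~0.66 fmol / cell / d
cell_specific_rate <- function(rate, copies_per_g, copies_per_cell = 1) {
  check_positive(copies_per_g, "copies_per_g")
  check_positive(copies_per_cell, "copies_per_cell")
  rate * 1e9 / (copies_per_g / copies_per_cell)
}

#' Relative symbiont abundance from FISH counts
#'
#' Per-image fraction of archaeal cells among all archaeal plus bacterial
#' cells, summarised as a mean percentage with its standard error across
#' images. Images with zero total cells are excluded with a warning.
#'
#' @param data Tibble with columns `image_id`, `archaeal`, `bacterial`
#'   (non-negative integer counts).
#' @return One-row tibble: `mean_percent`, `se_percent`, `n_images`, plus
#'   the per-image percentages in the `per_image` list-column.
#' @export
fish_relative_abundance <- function(data) {
  check_cols(data, c("image_id", "archaeal", "bacterial"), "FISH counts")
  check_positive(data$archaeal, "archaeal", strict = FALSE)
  check_positive(data$bacterial, "bacterial", strict = FALSE)
  total <- data$archaeal + data$bacterial
  if (any(total == 0)) {
    warn(sprintf("excluding %d image(s) with zero counts", sum(total == 0)))
    data <- data[total > 0, ]
    total <- total[total > 0]
  }
  if (!nrow(data)) {
    abort("no images with non-zero counts", class = "nitrosponge_validation_error")
  }
  pct <- 100 * data$archaeal / total
  se <- if (length(pct) > 1) sd(pct) / sqrt(length(pct)) else 0
  tibble(mean_percent = mean(pct), se_percent = se,
         n_images = length(pct),
         per_image = list(tibble(image_id = data$image_id, percent = pct)))
}
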