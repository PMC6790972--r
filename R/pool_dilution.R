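#' An incubation time series for one container
#'
#' Bundles the dissolved-inorganic-nitrogen concentration samples and the
#' 15N enrichment samples of the combined NO2-+NO3- pool for one incubation
#' container, together with the container volume and the wet weight of the
#' sponge clone it held. The NO2- and NO3- pools carry a single combined
#' 15N enrichment because the two species are recovered together by
#' sequential microdiffusion before isotope-ratio mass spectrometry.
#'
#' @param container_id Container label.
#' @param volume_l Container volume in litres; > 0.
#' @param wet_weight_g Sponge wet weight in grams; > 0.
#' @param samples Tibble with columns `time_h`, `nh4`, `no2`, `no3`
#'   (concentrations in uM); times strictly increasing.
#' @param isotope_samples Tibble with columns `time_h`, `ape_nox`
#'   (atom percent 15N excess of the combined NO2-+NO3- pool).
#' @return An object of class `incubation_series`.
#' @export
incubation_series <- function(container_id, volume_l, wet_weight_g,
                              samples, isotope_samples) {
  check_positive(volume_l, "volume_l")
  check_positive(wet_weight_g, "wet_weight_g")
  samples <- as_tibble(samples)
  isotope_samples <- as_tibble(isotope_samples)
  check_cols(samples, c("time_h", "nh4", "no2", "no3"), "samples")
  check_cols(isotope_samples, c("time_h", "ape_nox"), "isotope_samples")
  if (is.unsorted(samples$time_h, strictly = TRUE)) {
    abort("sample times must be strictly increasing",
          class = "nitrosponge_validation_error")
  }
  for (col in c("nh4", "no2", "no3")) {
    check_positive(samples[[col]], col, strict = FALSE)
  }
  check_range(isotope_samples$ape_nox, "ape_nox", 0, 100)
  structure(
    list(container_id = container_id, volume_l = volume_l,
         wet_weight_g = wet_weight_g, samples = samples,
         isotope_samples = isotope_samples),
    class = "incubation_series"
  )
}

#' @export
print.incubation_series <- function(x, ...) {
  cat(sprintf("<incubation_series> container %s: %.3g L, %.3g g wet weight\n",
              x$container_id, x$volume_l, x$wet_weight_g))
  cat(sprintf("  %d concentration samples over %.3g-%.3g h, %d isotope samples\n",
              nrow(x$samples), min(x$samples$time_h), max(x$samples$time_h),
              nrow(x$isotope_samples)))
  invisible(x)
}

#' Gross nitrification and consumption by isotope pool dilution
#'
#' Kirkham-Bartholomew two-point estimator for a product pool labelled with
#' 15N: gross production of unlabelled product dilutes the 15N enrichment of
#' the pool while consumption removes label and pool proportionally, so the
#' decline in atom percent excess separates gross production `p` from the
#' net concentration change, and consumption follows by difference.
#'
#' For a pool changing from `c0` to `ct` over `dt_d` days while enrichment
#' falls from `ape0` to `apet`:
#' \deqn{p = \frac{c_t - c_0}{\Delta t}\,
#'   \frac{\ln(APE_0/APE_t)}{\ln(c_t/c_0)}, \qquad
#'   c = p - \frac{c_t - c_0}{\Delta t}}
#' with the removable singularity at `ct == c0` handled by the limiting form
#' \eqn{p = (c_0/\Delta t)\ln(APE_0/APE_t)}.
#'
#' Only the ratio `ape0/apet` enters, so any common rescaling of the two
#' enrichments leaves the estimate unchanged. Small negative estimates
#' (within 5% of the estimate magnitude) are clamped to zero and flagged
#' `clamped_negative`; larger negatives flag `model_violation`. An
#' enrichment that increased (`apet > ape0`) violates the tracer model:
#' no number is returned and the row is flagged `enrichment_increased`.
#'
#' @param c0,ct Combined NO2-+NO3- pool at the start/end of the window, uM;
#'   `c0` includes the added 15N label mass.
#' @param ape0,apet Atom percent 15N excess at the start/end of the window.
#' @param dt_d Window length in days.
#' @param equal_pool_tol Relative tolerance below which `c0` and `ct` are
#'   treated as equal and the limiting form is used.
#' @return A tibble, one row per input element, with columns
#'   `gross_production`, `consumption`, `net_change` (all uM per day) and
#'   `flags` (";"-separated, empty when clean).
#' @export
#' @examples
#' gross_rates_ipd(10, 14, 5, 3, 20 / 24)  # p ~ 7.29, c ~ 2.49 uM / d
gross_rates_ipd <- function(c0, ct, ape0, apet, dt_d,
                            equal_pool_tol = 1e-9) {
  check_positive(c0, "c0")
  check_positive(ct, "ct")
  check_positive(ape0, "ape0")
  check_positive(apet, "apet", strict = FALSE)
  check_positive(dt_d, "dt_d")

  args <- vctrs_recycle(c0 = c0, ct = ct, ape0 = ape0, apet = apet,
                        dt_d = dt_d)
  purrr::pmap(args, function(c0, ct, ape0, apet, dt_d) {
    net <- (ct - c0) / dt_d
    if (apet > ape0) {
      return(tibble(gross_production = NA_real_, consumption = NA_real_,
                    net_change = net, flags = "enrichment_increased"))
    }
    dilution <- log(ape0 / apet)
    equal_pools <- abs(ct - c0) < equal_pool_tol * max(c0, ct)
    p <- if (equal_pools) {
      c0 / dt_d * dilution
    } else {
      net * dilution / log(ct / c0)
    }
    cons <- p - net
    clamp <- function(x, other) {
      scale <- max(abs(x), abs(other), .Machine$double.eps)
      if (x < 0 && x >= -0.05 * scale) list(0, "clamped_negative")
      else if (x < -0.05 * scale) list(x, "model_violation")
      else list(x, "")
    }
    pc <- clamp(p, cons); cc <- clamp(cons, p)
    tibble(gross_production = pc[[1]], consumption = cc[[1]],
           net_change = net, flags = flag_string(pc[[2]], cc[[2]]))
  }) |> bind_rows()
}

# minimal common-length recycling for parallel scalar arguments
vctrs_recycle <- function(...) {
  args <- list(...)
  n <- max(lengths(args))
  lapply(args, function(x) {
    if (length(x) == n) x
    else if (length(x) == 1) rep(x, n)
    else abort("arguments must have length 1 or a common length",
               class = "nitrosponge_validation_error")
  })
}

#' Normalize a volumetric rate to sponge wet weight
#'
#' Converts a container-volume rate (uM per day) into a biomass-specific
#' rate (umol N per gram wet weight per day): `rate * volume / wet_weight`.
#'
#' @param volumetric Rate in uM per day.
#' @param volume_l Container volume, litres.
#' @param wet_weight_g Sponge wet weight, grams.
#' @return Rate in umol per gram wet weight per day. Vectorized.
#' @export
to_specific_rate <- function(volumetric, volume_l, wet_weight_g) {
  check_positive(volume_l, "volume_l")
  check_positive(wet_weight_g, "wet_weight_g")
  volumetric * volume_l / wet_weight_g
}

#' Net flux of one DIN species over a time window
#'
#' Linear net flux between two window endpoints, normalized to wet weight:
#' `(C(t_end) - C(t_start)) / dt * volume / wet_weight`. Negative values
#' mean net consumption. Endpoints missing from the sampling schedule are
#' linearly interpolated from neighbouring samples when both neighbours lie
#' within `interp_tol_h` of the endpoint; otherwise the window is not
#' covered and an error of class `nitrosponge_window_uncovered` is raised.
#'
#' @param series An [incubation_series()].
#' @param species One of `"nh4"`, `"no2"`, `"no3"`.
#' @param window Numeric length-2, window start and end in hours. The
#'   default 6-18 h window avoids the initial label-equilibration transient
#'   and end-of-incubation artefacts.
#' @param interp_tol_h Maximum distance (hours) between a window endpoint
#'   and the nearest bracketing samples for interpolation.
#' @return One-row tibble: `container_id`, `kind` (`"net_flux"`),
#'   `species`, `t_start_h`, `t_end_h`, `value` (umol per g wet weight per
#'   day) and `flags`.
#' @export
net_flux <- function(series, species = c("nh4", "no2", "no3"),
                     window = c(6, 18), interp_tol_h = 1) {
  species <- match.arg(species)
  stopifnot(inherits(series, "incubation_series"))
  if (length(window) != 2 || window[2] <= window[1]) {
    abort("`window` must be c(start, end) with end > start",
          class = "nitrosponge_validation_error")
  }
  conc_at <- function(t) {
    s <- series$samples
    exact <- which(abs(s$time_h - t) < 1e-9)
    if (length(exact)) return(s[[species]][exact[1]])
    lo <- max(s$time_h[s$time_h < t], -Inf)
    hi <- min(s$time_h[s$time_h > t], Inf)
    if (!is.finite(lo) || !is.finite(hi) ||
        (t - lo) > interp_tol_h || (hi - t) > interp_tol_h) {
      abort(sprintf(
        "window endpoint %.3g h not covered by samples within %.3g h",
        t, interp_tol_h), class = "nitrosponge_window_uncovered")
    }
    y_lo <- s[[species]][s$time_h == lo]
    y_hi <- s[[species]][s$time_h == hi]
    y_lo + (y_hi - y_lo) * (t - lo) / (hi - lo)
  }
  c_start <- conc_at(window[1])
  c_end <- conc_at(window[2])
  dt_d <- (window[2] - window[1]) / 24
  value <- to_specific_rate((c_end - c_start) / dt_d,
                            series$volume_l, series$wet_weight_g)
  tibble(container_id = series$container_id, kind = "net_flux",
         species = species, t_start_h = window[1], t_end_h = window[2],
         value = value, flags = "")
}

#' Net nitrification from NO2- and NO3- net fluxes
#'
#' Net nitrification is the net accumulation of the two nitrification
#' products combined, i.e. the sum of the NO2- and NO3- net fluxes over a
#' shared window. The NO2-:NO3- accumulation ratio is attached as a
#' diagnostic (`no2_no3_ratio`); in the sponge holobiont nitrite typically
#' accumulates faster than nitrate.
#'
#' @param no2_flux,no3_flux One-row tibbles from [net_flux()] for the same
#'   container, window and normalization.
#' @return One-row tibble with `kind = "net_nitrification"`, the summed
#'   `value` and the `no2_no3_ratio` diagnostic (NA when the NO3- flux
#'   is zero).
#' @export
net_nitrification <- function(no2_flux, no3_flux) {
  for (f in list(no2_flux, no3_flux)) {
    check_cols(f, c("t_start_h", "t_end_h", "value"), "flux")
  }
  if (no2_flux$t_start_h != no3_flux$t_start_h ||
      no2_flux$t_end_h != no3_flux$t_end_h) {
    abort("NO2- and NO3- fluxes use different windows",
          class = "nitrosponge_validation_error")
  }
  ratio <- if (no3_flux$value != 0) no2_flux$value / no3_flux$value else NA_real_
  tibble(container_id = no2_flux$container_id, kind = "net_nitrification",
         species = "no2+no3",
         t_start_h = no2_flux$t_start_h, t_end_h = no2_flux$t_end_h,
         value = no2_flux$value + no3_flux$value,
         no2_no3_ratio = ratio,
         flags = flag_string(no2_flux$flags, no3_flux$flags))
}

#' Plan a 15N-nitrate label addition
#'
#' The tracer must stay small relative to the pool it labels (at most 10%)
#' so that the addition itself does not perturb turnover. Given a target
#' labelled fraction, returns the K15NO3 concentration to add and the
#' resulting initial atom percent 15N excess of the pool.
#'
#' With `fraction_basis = "post"` (default) the target is the fraction of
#' the post-addition pool, so the addition is
#' `pool * f / (1 - f)`; with `"pre"` it is simply `pool * f`.
#'
#' @param pool_concentration Pre-addition NO3- (or NOx) pool, uM; > 0.
#' @param target_fraction Labelled fraction, in (0, 0.10].
#' @param label_atom_percent Atom percent 15N of the label salt.
#' @param fraction_basis `"post"` or `"pre"`; see Details.
#' @param constants Isotope constants (for the natural 15N baseline).
#' @return One-row tibble: `addition_um`, `pool_after_um`, `ape0`
#'   (atom percent 15N excess immediately after mixing).
#' @export
#' @examples
#' plan_label_addition(10, 0.10)  # add 1.11 uM at 98 at% -> APE0 ~ 9.76
plan_label_addition <- function(pool_concentration, target_fraction,
                                label_atom_percent = 98,
                                fraction_basis = c("post", "pre"),
                                constants = isotope_constants()) {
  fraction_basis <- match.arg(fraction_basis)
  check_positive(pool_concentration, "pool_concentration")
  if (any(target_fraction <= 0 | target_fraction > 0.10)) {
    abort("`target_fraction` must lie in (0, 0.10]",
          class = "nitrosponge_validation_error")
  }
  check_range(label_atom_percent, "label_atom_percent", 0, 100)
  addition <- switch(fraction_basis,
    post = pool_concentration * target_fraction / (1 - target_fraction),
    pre = pool_concentration * target_fraction)
  pool_after <- pool_concentration + addition
  at_mixed <- (pool_concentration * constants$n15_natural +
                 addition * label_atom_percent) / pool_after
  tibble(addition_um = addition, pool_after_um = pool_after,
         ape0 = at_mixed - constants$n15_natural)
}

#' Gross nitrification rates for a whole incubation series
#'
#' Convenience wrapper: takes the first and last isotope samples of an
#' [incubation_series()] together with the combined NO2-+NO3- pool at those
#' times (interpolated from the concentration samples when needed), applies
#' [gross_rates_ipd()] and normalizes to wet weight.
#'
#' @param series An [incubation_series()] with at least two isotope samples.
#' @return One-row tibble: `container_id`, `kind` (`"gross_production"`),
#'   `t_start_h`, `t_end_h`, `value` and `consumption` (both umol per g wet
#'   weight per day), `flags`.
#' @export
gross_rates <- function(series) {
  stopifnot(inherits(series, "incubation_series"))
  iso <- series$isotope_samples
  if (nrow(iso) < 2) {
    abort("need at least two isotope samples for pool dilution",
          class = "nitrosponge_validation_error")
  }
  t0 <- iso$time_h[1]; t1 <- iso$time_h[nrow(iso)]
  nox_at <- function(t) {
    s <- series$samples
    stats::approx(s$time_h, s$no2 + s$no3, xout = t, rule = 2)$y
  }
  est <- gross_rates_ipd(nox_at(t0), nox_at(t1),
                         iso$ape_nox[1], iso$ape_nox[nrow(iso)],
                         (t1 - t0) / 24)
  tibble(container_id = series$container_id, kind = "gross_production",
         t_start_h = t0, t_end_h = t1,
         value = to_specific_rate(est$gross_production, series$volume_l,
                                  series$wet_weight_g),
         consumption = to_specific_rate(est$consumption, series$volume_l,
                                        series$wet_weight_g),
         flags = est$flags)
}
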