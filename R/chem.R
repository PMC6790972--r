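#' Isotope reference constants
#'
#' Conventional tracer-ecology constants: the Craig value for the 13C/12C
#' ratio of the VPDB standard and the natural abundance of 15N. Both are
#' plain fields so site-specific baselines can be substituted.
#'
#' @param r_vpdb 13C/12C isotope ratio of the VPDB standard (unitless).
#' @param n15_natural Natural 15N abundance, atom percent.
#' @return A list with elements `r_vpdb` and `n15_natural`.
#' @export
#' @examples
#' isotope_constants()
isotope_constants <- function(r_vpdb = 0.0112372, n15_natural = 0.3663) {
  check_positive(r_vpdb, "r_vpdb")
  check_range(n15_natural, "n15_natural", 0, 100, allow_equal = FALSE)
  list(r_vpdb = r_vpdb, n15_natural = n15_natural)
}

#' Stoichiometric dissociation exponent of ammonium in seawater
#'
#' pKa* of the NH4+/NH3 couple as a linear function of temperature and
#' salinity, a published seawater formulation adequate for speciation at
#' surface conditions:
#' \deqn{pK_a^* = 10.0423 - 0.0315536\,T + 0.003071\,S}
#'
#' @param temperature Temperature in degrees Celsius, in \[-2, 40\].
#' @param salinity Practical salinity (PSU), in \[0, 45\].
#' @return pKa* on the same pH scale as the input pH (total scale assumed).
#' @export
ammonia_pka <- function(temperature = 25, salinity = 35) {
  check_range(temperature, "temperature", -2, 40)
  check_range(salinity, "salinity", 0, 45)
  10.0423 - 0.0315536 * temperature + 0.003071 * salinity
}

#' Fraction of total ammoniacal nitrogen present as NH3
#'
#' Henderson-Hasselbalch speciation of the NH4+/NH3 couple using the
#' stoichiometric seawater pKa* from [ammonia_pka()]. NH3, not NH4+, is the
#' substrate of archaeal ammonia monooxygenase and the toxic species for the
#' host, so this fraction matters both for interpreting substrate supply and
#' for judging stress in high-ammonium incubation treatments.
#'
#' The fraction is strictly increasing in pH and temperature.
#'
#' @param temperature Temperature, degrees Celsius.
#' @param salinity Practical salinity (PSU).
#' @param ph pH (total scale assumed), in \[6, 10\]. No default: the value
#'   must come from the experiment's measured carbonate chemistry.
#' @return Fraction of total ammonia present as NH3, in (0, 1). Vectorized.
#' @export
#' @examples
#' ammonia_fraction(25, 35, 8.0)   # about 0.042
#' ammonia_fraction(25, 35, 8.05)  # about 0.045
ammonia_fraction <- function(temperature = 25, salinity = 35, ph) {
  if (missing(ph)) {
    abort("`ph` must be supplied (no universal default for incubation water)",
          class = "nitrosponge_validation_error")
  }
  check_range(ph, "ph", 6, 10)
  pka <- ammonia_pka(temperature, salinity)
  1 / (1 + 10^(pka - ph))
}

#' Convert delta13C (per mil vs VPDB) to atom percent 13C
#'
#' at% = 100 R / (1 + R) with R = r_vpdb (1 + delta/1000).
#'
#' @param delta delta13C in per mil vs VPDB; must be > -1000.
#' @param constants Isotope constants, see [isotope_constants()].
#' @return Atom percent 13C. Vectorized over `delta`.
#' @seealso [atom_percent_to_delta()] for the inverse.
#' @export
#' @examples
#' delta13c_to_atom_percent(0)  # 1.11123 at a natural-abundance baseline
delta13c_to_atom_percent <- function(delta, constants = isotope_constants()) {
  if (any(delta <= -1000, na.rm = TRUE)) {
    abort("`delta` must be > -1000 per mil (isotope ratio would be non-positive)",
          class = "nitrosponge_validation_error")
  }
  r <- constants$r_vpdb * (1 + delta / 1000)
  100 * r / (1 + r)
}

#' Convert atom percent 13C to delta13C (per mil vs VPDB)
#'
#' Exact inverse of [delta13c_to_atom_percent()].
#'
#' @param atom_percent Atom percent 13C, in \[0, 100).
#' @param constants Isotope constants, see [isotope_constants()].
#' @return delta13C in per mil vs VPDB.
#' @export
atom_percent_to_delta <- function(atom_percent, constants = isotope_constants()) {
  check_range(atom_percent, "atom_percent", 0, 100)
  r <- atom_percent / (100 - atom_percent)
  1000 * (r / constants$r_vpdb - 1)
}

#' A dissolved inorganic carbon pool
#'
#' One-row tibble describing a DIC pool by concentration and 13C enrichment.
#'
#' @param concentration Concentration in uM; >= 0.
#' @param atom_percent_13c Atom percent 13C of the pool, in \[0, 100\].
#' @return A tibble with columns `concentration` and `atom_percent_13c`.
#' @export
#' @examples
#' dic_pool(1975)                 # natural-abundance seawater bicarbonate
#' dic_pool(100, 99)              # a 99 atom% 13C-bicarbonate spike
dic_pool <- function(concentration,
                     atom_percent_13c = delta13c_to_atom_percent(0)) {
  check_positive(concentration, "concentration", strict = FALSE)
  check_range(atom_percent_13c, "atom_percent_13c", 0, 100)
  tibble(concentration = concentration, atom_percent_13c = atom_percent_13c)
}

#' Mix a background DIC pool with labelled additions
#'
#' Concentration-weighted mass balance of 13C across DIC pools: the mixed
#' concentration is the sum and the mixed atom percent the
#' concentration-weighted mean. Used to derive the source-pool enrichment
#' driving tissue 13C uptake after 13C-bicarbonate spikes into seawater
#' with a natural-abundance background.
#'
#' @param background A [dic_pool()]; the unamended pool.
#' @param additions A tibble of pools (rows) as produced by [dic_pool()],
#'   or `NULL` for no additions.
#' @return One-row tibble: `concentration`, `atom_percent_13c` and
#'   `atom_percent_excess` (mixed minus background atom percent).
#' @export
#' @examples
#' mix_dic_label(dic_pool(1975), dic_pool(100, 99))  # 2075 uM at 5.83 at%
mix_dic_label <- function(background, additions = NULL) {
  check_cols(background, c("concentration", "atom_percent_13c"), "background")
  pools <- bind_rows(background, additions)
  check_positive(pools$concentration, "concentration", strict = FALSE)
  check_range(pools$atom_percent_13c, "atom_percent_13c", 0, 100)
  total <- sum(pools$concentration)
  if (total == 0) {
    abort("total DIC concentration is zero: mixture atom percent undefined",
          class = "nitrosponge_undefined_mixture")
  }
  at <- sum(pools$concentration * pools$atom_percent_13c) / total
  tibble(
    concentration = total,
    atom_percent_13c = at,
    atom_percent_excess = at - background$atom_percent_13c[1]
  )
}
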