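#' Read incubation time series from long-format CSV files
#'
#' The sample file is long format with columns `container_id`, `time_h`,
#' `analyte` (one of `NH4`, `NO2`, `NO3`, `APE_NOx`) and `value`; the
#' containers file has `container_id`, `volume_l`, `wet_weight_g` and any
#' further metadata columns (e.g. `treatment`, `day`), which are attached
#' to each series as attribute `"meta"`.
#'
#' @param samples_path,containers_path CSV paths.
#' @return Named list of [incubation_series()] objects.
#' @export
read_incubation_long <- function(samples_path, containers_path) {
  samples <- readr::read_csv(samples_path, show_col_types = FALSE)
  containers <- readr::read_csv(containers_path, show_col_types = FALSE)
  check_cols(samples, c("container_id", "time_h", "analyte", "value"),
             "samples file")
  check_cols(containers, c("container_id", "volume_l", "wet_weight_g"),
             "containers file")
  ids <- unique(containers$container_id)
  series <- lapply(ids, function(id) {
    s <- filter(samples, .data$container_id == id)
    meta <- filter(containers, .data$container_id == id)
    conc <- s |>
      filter(.data$analyte %in% c("NH4", "NO2", "NO3")) |>
      tidyr::pivot_wider(id_cols = "time_h", names_from = "analyte",
                         values_from = "value") |>
      rename(nh4 = "NH4", no2 = "NO2", no3 = "NO3") |>
      arrange(.data$time_h)
    iso <- s |>
      filter(.data$analyte == "APE_NOx") |>
      select(time_h = "time_h", ape_nox = "value") |>
      arrange(.data$time_h)
    out <- incubation_series(id, meta$volume_l[1], meta$wet_weight_g[1],
                             conc, iso)
    attr(out, "meta") <- meta
    out
  })
  setNames(series, ids)
}

#' Write a tidy rates table
#'
#' @param rates Rates tibble (e.g. from [run_pipeline()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_rates <- function(rates, path) {
  readr::write_csv(rates, path)
  invisible(path)
}
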