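#' Configuration of a synthetic incubation experiment
#'
#' Collects the true (hidden) rates and the sampling design of a simulated
#' pool-dilution incubation. Rates are volumetric (uM per day) inside the
#' container; the simulator converts to biomass-specific units only in its
#' truth record.
#'
#' @param seed Integer seed; a fixed seed gives identical output.
#' @param gross_production True gross nitrification, uM NOx per day.
#' @param nox_consumption True NOx consumption, uM per day.
#' @param nh4_excretion Host ammonium excretion, uM per day.
#' @param volume_l Container volume, litres.
#' @param wet_weight_g Sponge wet weight, grams.
#' @param nox_initial Pre-label NO2-+NO3- pool, uM.
#' @param nh4_initial Initial ammonium, uM.
#' @param label Label plan: list with `target_fraction` and
#'   `label_atom_percent` passed to [plan_label_addition()].
#' @param conc_noise_sd Gaussian noise on sampled concentrations, uM.
#' @param ape_noise_sd Gaussian noise on sampled atom percent excess.
#' @param sample_times_h Concentration sampling times, hours.
#' @param isotope_times_h Isotope sampling times, hours (two-point design
#'   by default: just after label addition and at 20 h).
#' @param no2_fraction Fraction of the NOx pool reported as NO2- when the
#'   simulated combined pool is split into the two measured species.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              gross_production = 7.287,
                              nox_consumption = 2.487,
                              nh4_excretion = 8,
                              volume_l = 1.5,
                              wet_weight_g = 5,
                              nox_initial = 10,
                              nh4_initial = 10,
                              label = list(target_fraction = 0.10,
                                           label_atom_percent = 98),
                              conc_noise_sd = 0,
                              ape_noise_sd = 0,
                              sample_times_h = c(0, 6, 12, 18, 20),
                              isotope_times_h = c(0, 20),
                              no2_fraction = 2.8 / 3.8) {
  check_positive(c(gross_production, nox_consumption, nh4_excretion),
                 "rates", strict = FALSE)
  check_positive(c(conc_noise_sd, ape_noise_sd), "noise sd", strict = FALSE)
  check_positive(volume_l, "volume_l")
  check_positive(wet_weight_g, "wet_weight_g")
  check_positive(nox_initial, "nox_initial")
  structure(
    list(seed = as.integer(seed), gross_production = gross_production,
         nox_consumption = nox_consumption, nh4_excretion = nh4_excretion,
         volume_l = volume_l, wet_weight_g = wet_weight_g,
         nox_initial = nox_initial, nh4_initial = nh4_initial,
         label = label, conc_noise_sd = conc_noise_sd,
         ape_noise_sd = ape_noise_sd, sample_times_h = sample_times_h,
         isotope_times_h = isotope_times_h, no2_fraction = no2_fraction),
    class = "simulation_config")
}

# forward pool-dilution kinetics: production of unlabelled NOx dilutes the
# 15N enrichment, consumption removes label and pool proportionally.
#   dC/dt = p - c;  dAPE/dt = -p APE / C;  dNH4/dt = excretion - p
# Integrated with fixed-step classical Runge-Kutta (step <= 0.01 d); the
# analytic solution APE(t) = APE0 (C(t)/C0)^(-p/(p-c)) serves as a
# cross-check in the test suite.
integrate_incubation <- function(p, cons, excr, c0, ape0, nh4_0, times_d,
                                 step = 0.01) {
  deriv <- function(state) {
    if (state[1] <= 0) {
      abort("NOx pool driven negative; shorten the horizon or lower consumption",
            class = "nitrosponge_simulation_error")
    }
    c(p - cons, -p * state[2] / state[1], excr - p)
  }
  out <- matrix(NA_real_, nrow = length(times_d), ncol = 3)
  state <- c(c0, ape0, nh4_0)
  t_now <- 0
  for (i in seq_along(times_d)) {
    target <- times_d[i]
    while (t_now < target - 1e-12) {
      h <- min(step, target - t_now)
      k1 <- deriv(state)
      k2 <- deriv(state + h / 2 * k1)
      k3 <- deriv(state + h / 2 * k2)
      k4 <- deriv(state + h * k3)
      state <- state + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      t_now <- t_now + h
    }
    out[i, ] <- state
  }
  colnames(out) <- c("nox", "ape", "nh4")
  out
}

#' Simulate a pool-dilution incubation
#'
#' Forward model for one container: a 15N-nitrate label is mixed into the
#' NOx pool per the config's label plan, then the pool evolves under
#' constant gross production and consumption while production of
#' unlabelled NOx dilutes the enrichment. Samples are drawn at the config
#' times with Gaussian noise. The hidden truth (volumetric and
#' biomass-specific rates, initial enrichment) is attached as attribute
#' `"truth"` so estimators can be scored.
#'
#' @param config A [simulation_config()].
#' @return An [incubation_series()] with a `"truth"` attribute.
#' @export
simulate_incubation <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  plan <- plan_label_addition(config$nox_initial,
                              config$label$target_fraction,
                              config$label$label_atom_percent)
  c0 <- plan$pool_after_um
  ape0 <- plan$ape0
  all_times_h <- sort(unique(c(config$sample_times_h, config$isotope_times_h)))
  states <- integrate_incubation(
    config$gross_production, config$nox_consumption, config$nh4_excretion,
    c0, ape0, config$nh4_initial, all_times_h / 24)
  idx_conc <- match(config$sample_times_h, all_times_h)
  idx_iso <- match(config$isotope_times_h, all_times_h)
  nox <- states[idx_conc, "nox"] +
    rnorm(length(idx_conc), 0, config$conc_noise_sd)
  nh4 <- states[idx_conc, "nh4"] +
    rnorm(length(idx_conc), 0, config$conc_noise_sd)
  ape <- states[idx_iso, "ape"] +
    rnorm(length(idx_iso), 0, config$ape_noise_sd)
  nox <- pmax(nox, 1e-6); nh4 <- pmax(nh4, 0); ape <- pmax(ape, 1e-6)
  series <- incubation_series(
    container_id = sprintf("sim-%d", config$seed),
    volume_l = config$volume_l, wet_weight_g = config$wet_weight_g,
    samples = tibble(time_h = config$sample_times_h,
                     nh4 = nh4,
                     no2 = config$no2_fraction * nox,
                     no3 = (1 - config$no2_fraction) * nox),
    isotope_samples = tibble(time_h = config$isotope_times_h, ape_nox = ape))
  attr(series, "truth") <- list(
    gross_production = config$gross_production,
    nox_consumption = config$nox_consumption,
    gross_production_specific = to_specific_rate(
      config$gross_production, config$volume_l, config$wet_weight_g),
    nox_consumption_specific = to_specific_rate(
      config$nox_consumption, config$volume_l, config$wet_weight_g),
    c0 = c0, ape0 = ape0)
  series
}

#' Simulate tissue 13C labelling
#'
#' Inverse of [fixation_rate()]: given a true fixation rate, computes the
#' final tissue delta13C that the two-pool mixing model implies, optionally
#' adding Gaussian measurement noise to the final delta. At zero noise
#' `fixation_rate()` recovers the true rate exactly.
#'
#' @param true_rate True fixation rate, umol C per g per day.
#' @param tissue_carbon Tissue carbon content, umol C per g.
#' @param dic_excess Atom percent 13C excess of the DIC pool (e.g. the
#'   `atom_percent_excess` from [mix_dic_label()]).
#' @param duration_d Incubation duration, days.
#' @param delta13c_baseline Unlabelled tissue delta13C, per mil.
#' @param noise_sd Gaussian noise on the final delta13C, per mil.
#' @param seed Optional seed.
#' @return One-row tibble in the [fixation_rate()] input layout, with the
#'   truth attached as attribute `"truth"`.
#' @export
simulate_tissue_labeling <- function(true_rate, tissue_carbon, dic_excess,
                                     duration_d, delta13c_baseline = -20,
                                     noise_sd = 0, seed = NULL) {
  check_positive(tissue_carbon, "tissue_carbon")
  check_positive(duration_d, "duration_d")
  check_positive(dic_excess, "dic_excess")
  check_positive(true_rate, "true_rate", strict = FALSE)
  if (!is.null(seed)) set.seed(seed)
  at_i <- delta13c_to_atom_percent(delta13c_baseline)
  at_f <- at_i + true_rate * duration_d / tissue_carbon * dic_excess
  if (at_f >= 100) {
    abort("simulated tissue enrichment exceeds 100 atom percent",
          class = "nitrosponge_simulation_error")
  }
  delta_f <- atom_percent_to_delta(at_f) + rnorm(1, 0, noise_sd)
  out <- tibble(delta13c_initial = delta13c_baseline,
                delta13c_final = delta_f,
                tissue_carbon = tissue_carbon, duration_d = duration_d,
                dic_excess = dic_excess)
  attr(out, "truth") <- list(cfix = true_rate)
  out
}

#' Simulate a qPCR plate
#'
#' Log-linear standard dilution series (10^6 down to 10^0 copies per ul)
#' plus unknown wells for a sample of known true abundance, with Gaussian
#' Cq noise. The curve slope is `-1/log10(1 + efficiency)`.
#'
#' @param true_copies_per_g True abundance of the unknown sample, copies
#'   per g wet weight.
#' @param efficiency Amplification efficiency, in (0.7, 1.1].
#' @param intercept Cq at 1 copy per ul.
#' @param cq_noise_sd Gaussian noise on every Cq, cycles.
#' @param seed Optional seed.
#' @param template_ul,elution_ul,tissue_g Volume bookkeeping of the
#'   unknown sample.
#' @param n_replicate_wells Wells per standard level and per unknown.
#' @return Tibble of plate rows (`sample_id`, `well`, `cq`, `is_standard`,
#'   `standard_copies_per_ul`, `template_ul`, `elution_ul`, `tissue_g`)
#'   with truth attached as attribute `"truth"`.
#' @export
simulate_qpcr <- function(true_copies_per_g, efficiency = 1,
                          intercept = 38, cq_noise_sd = 0, seed = NULL,
                          template_ul = 1, elution_ul = 100, tissue_g = 0.1,
                          n_replicate_wells = 2) {
  if (efficiency <= 0.7 || efficiency > 1.1) {
    abort("`efficiency` must lie in (0.7, 1.1]",
          class = "nitrosponge_validation_error")
  }
  check_positive(true_copies_per_g, "true_copies_per_g")
  if (!is.null(seed)) set.seed(seed)
  slope <- -1 / log10(1 + efficiency)
  cq_of <- function(copies_per_ul) {
    intercept + slope * log10(copies_per_ul) +
      rnorm(length(copies_per_ul), 0, cq_noise_sd)
  }
  std_levels <- 10^(6:0)
  standards <- tidyr::expand_grid(standard_copies_per_ul = std_levels,
                                  replicate = seq_len(n_replicate_wells)) |>
    mutate(sample_id = sprintf("std_1e%d", log10(.data$standard_copies_per_ul)),
           well = sprintf("%s_w%d", .data$sample_id, .data$replicate),
           cq = cq_of(.data$standard_copies_per_ul),
           is_standard = TRUE,
           template_ul = template_ul, elution_ul = elution_ul,
           tissue_g = NA_real_) |>
    select(-"replicate")
  true_per_ul <- true_copies_per_g * tissue_g / elution_ul
  unknowns <- tibble(
    sample_id = "unknown", well = sprintf("unknown_w%d",
                                          seq_len(n_replicate_wells)),
    cq = cq_of(rep(true_per_ul, n_replicate_wells)),
    is_standard = FALSE, standard_copies_per_ul = NA_real_,
    template_ul = template_ul, elution_ul = elution_ul,
    tissue_g = tissue_g)
  out <- bind_rows(standards, unknowns)
  attr(out, "truth") <- list(copies_per_g = true_copies_per_g,
                             copies_per_ul = true_per_ul,
                             slope = slope, intercept = intercept)
  out
}

#' Simulate a spectral-count table
#'
#' Multinomial sampling of `depth` spectra over proteins whose sampling
#' weights are proportional to (per-protein share) x (protein length), so
#' that length-normalized NSAF aggregation recovers the per-bin shares in
#' expectation. Protein lengths are log-normal.
#'
#' @param true_shares Named numeric vector of per-bin NSAF shares, summing
#'   to 1.
#' @param n_proteins Total number of proteins.
#' @param depth Total spectra to distribute.
#' @param seed Optional seed.
#' @param sample_id Sample label for the emitted rows.
#' @return Spectral-count tibble (columns `protein_id`, `sample_id`,
#'   `spectral_count`, `length_aa`, `bin`, `category`,
#'   `exclusive_unique_peptides`, `is_decoy`) with truth attached.
#' @export
simulate_proteome <- function(true_shares, n_proteins = 100, depth = 1e5,
                              seed = NULL, sample_id = "s1") {
  if (is.null(names(true_shares)) ||
      abs(sum(true_shares) - 1) > 1e-8 || any(true_shares <= 0)) {
    abort("`true_shares` must be a named positive vector summing to 1",
          class = "nitrosponge_validation_error")
  }
  if (!is.null(seed)) set.seed(seed)
  n_per_bin <- pmax(1, round(true_shares * n_proteins))
  names(n_per_bin) <- names(true_shares)
  bins <- rep(names(true_shares), n_per_bin)
  n_tot <- length(bins)
  lengths_aa <- pmax(50L, round(rlnorm(n_tot, meanlog = 5.5, sdlog = 0.4)))
  weight <- rep(true_shares / n_per_bin, n_per_bin) # per-protein SAF share
  prob <- weight * lengths_aa
  counts <- as.integer(rmultinom(1, size = depth, prob = prob))
  tbl <- tibble(
    protein_id = sprintf("p%04d", seq_len(n_tot)),
    sample_id = sample_id,
    spectral_count = counts,
    length_aa = lengths_aa,
    bin = bins,
    category = sample(c("core", "shared", "unique"), n_tot, replace = TRUE,
                      prob = c(0.6, 0.3, 0.1)),
    exclusive_unique_peptides = 2L + stats::rpois(n_tot, 3),
    is_decoy = FALSE)
  attr(tbl, "truth") <- list(shares = true_shares)
  tbl
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_dna <- function(seq, rate) {
  bases <- strsplit(seq, "")[[1]]
  hit <- stats::runif(length(bases)) < rate
  if (any(hit)) {
    bases[hit] <- vapply(bases[hit], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1)
    }, character(1))
  }
  paste(bases, collapse = "")
}

hamming_identity <- function(a, b) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  100 * sum(x == y) / length(x)
}

#' Simulate a genome pair of controlled identity
#'
#' Genome B is a copy of genome A with every site substituted independently
#' at rate `1 - mean_identity/100`. Gene-level hit tables for both
#' directions contain the true gene pairings at their realized identities
#' plus low-scoring decoy hits, so reciprocal-best-hit selection can be
#' exercised against a known answer.
#'
#' @param n_genes Number of genes.
#' @param mean_identity Target percent identity, in (50, 100].
#' @param seed Optional seed.
#' @param gene_length Gene length in bp.
#' @return List with `genes_a`, `genes_b` (named character vectors),
#'   `genome_a`, `genome_b` (single-contig concatenations), `hits_ab`,
#'   `hits_ba` (hit tibbles) and `truth` (realized identities and the true
#'   pairing).
#' @export
simulate_genome_pair <- function(n_genes = 20, mean_identity = 98,
                                 seed = NULL, gene_length = 900) {
  if (mean_identity <= 50 || mean_identity > 100) {
    abort("`mean_identity` must lie in (50, 100]",
          class = "nitrosponge_validation_error")
  }
  if (!is.null(seed)) set.seed(seed)
  rate <- 1 - mean_identity / 100
  genes_a <- setNames(vapply(seq_len(n_genes),
                             function(i) random_dna(gene_length),
                             character(1)),
                      sprintf("a_g%03d", seq_len(n_genes)))
  genes_b <- setNames(vapply(genes_a, mutate_dna, character(1), rate = rate),
                      sprintf("b_g%03d", seq_len(n_genes)))
  ident <- vapply(seq_len(n_genes),
                  function(i) hamming_identity(genes_a[i], genes_b[i]),
                  numeric(1))
  hit_row <- function(q, s, id, score) {
    tibble(query = q, subject = s, identity = id,
           align_length = gene_length, bitscore = score,
           query_length = gene_length, subject_length = gene_length)
  }
  true_ab <- hit_row(names(genes_a), names(genes_b), ident,
                     2 * gene_length * ident / 100)
  true_ba <- hit_row(names(genes_b), names(genes_a), ident,
                     2 * gene_length * ident / 100)
  # decoys: off-diagonal pairs at background identity, always outscored
  n_decoy <- min(n_genes, 10L)
  di <- sample(n_genes, n_decoy)
  dj <- (di %% n_genes) + 1L
  decoy_id <- stats::runif(n_decoy, 20, 35)
  decoy_ab <- hit_row(names(genes_a)[di], names(genes_b)[dj], decoy_id,
                      0.3 * gene_length)
  decoy_ba <- hit_row(names(genes_b)[di], names(genes_a)[dj], decoy_id,
                      0.3 * gene_length)
  list(genes_a = genes_a, genes_b = genes_b,
       genome_a = c(contig_a = paste(genes_a, collapse = "")),
       genome_b = c(contig_b = paste(genes_b, collapse = "")),
       hits_ab = bind_rows(true_ab, decoy_ab),
       hits_ba = bind_rows(true_ba, decoy_ba),
       truth = list(identities = ident, mean_identity = mean(ident),
                    pairing = setNames(names(genes_b), names(genes_a))))
}

#' Fragment hit tables for a colinear genome pair
#'
#' Synthetic-oracle plumbing for [ani_fragment()]: both genomes are cut
#' with [fragment_genome()] and positionally corresponding fragments are
#' compared directly (the simulated pair is colinear, so position is the
#' true alignment). Emits reciprocal hit tables with identities from the
#' per-site comparison.
#'
#' @param genome_a,genome_b Assemblies as accepted by [assembly_stats()].
#' @param width Fragment width, bp.
#' @return List `a_to_b`, `b_to_a` of hit tibbles.
#' @export
colinear_fragment_hits <- function(genome_a, genome_b, width = 1020) {
  fa <- fragment_genome(genome_a, width)
  fb <- fragment_genome(genome_b, width)
  n <- min(length(fa), length(fb))
  if (n == 0) {
    abort("genomes shorter than one fragment width",
          class = "nitrosponge_validation_error")
  }
  ident <- vapply(seq_len(n),
                  function(i) hamming_identity(fa[[i]], fb[[i]]), numeric(1))
  mk <- function(q, s) {
    tibble(query = q[seq_len(n)], subject = s[seq_len(n)],
           identity = ident, align_length = width,
           bitscore = 2 * width * ident / 100,
           query_length = width, subject_length = width)
  }
  list(a_to_b = mk(names(fa), names(fb)), b_to_a = mk(names(fb), names(fa)))
}
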