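perfect_curve <- function(intercept = 38, slope = -3.3219) {
  tibble::tibble(copies = 10^(0:6), cq = intercept + slope * (0:6))
}

test_that("standard-curve slope converts to amplification efficiency", {
  sc <- fit_standard_curve(perfect_curve())
  expect_equal(sc$slope, -3.3219, tolerance = 1e-6)
  expect_equal(sc$efficiency, 1, tolerance = 1e-4)
  expect_equal(sc$r2, 1, tolerance = 1e-12)
  expect_identical(sc$flags, "")

  low <- fit_standard_curve(perfect_curve(slope = -3.6))
  expect_equal(low$efficiency, 0.8957, tolerance = 1e-4)
  expect_match(low$flags, "efficiency_low")
})

test_that("standard-curve fitting rejects degenerate input", {
  expect_error(fit_standard_curve(tibble::tibble(copies = c(10, 100),
                                                 cq = c(30, 27))),
               class = "nitrosponge_validation_error")
  expect_error(fit_standard_curve(tibble::tibble(copies = 10^(0:4),
                                                 cq = 20 + 3.3 * (0:4))),
               class = "nitrosponge_inverted_curve")
})

test_that("noise-free log-linear data is recovered to machine precision", {
  sc <- fit_standard_curve(perfect_curve(intercept = 41.7, slope = -3.45))
  expect_equal(sc$slope, -3.45, tolerance = 1e-10)
  expect_equal(sc$intercept, 41.7, tolerance = 1e-10)
})

test_that("quantification inverts the curve and scales volumes to tissue mass", {
  sc <- fit_standard_curve(perfect_curve(intercept = 38, slope = -3.32))
  unk <- tibble::tibble(sample_id = "s1", cq = 20, template_ul = 1,
                        elution_ul = 100, tissue_g = 0.1)
  q <- quantify_qpcr(unk, sc)
  expect_equal(q$copies_per_ul, 2.6405e5, tolerance = 1e-4)
  expect_equal(q$copies_per_g, 2.6405e8, tolerance = 1e-4)
  expect_equal(q$cells_per_g, q$copies_per_g)

  # Cq at the intercept means one copy per microlitre of template
  at_int <- quantify_qpcr(
    tibble::tibble(sample_id = "s2", cq = 38, template_ul = 1,
                   elution_ul = 1, tissue_g = 1), sc)
  expect_equal(at_int$copies_per_ul, 1, tolerance = 1e-9)

  # duplicate wells are averaged on the Cq scale
  dup <- quantify_qpcr(
    tibble::tibble(sample_id = "s3", cq = c(19.5, 20.5), template_ul = 1,
                   elution_ul = 100, tissue_g = 0.1), sc)
  expect_equal(dup$cq, 20)
  expect_equal(dup$copies_per_ul, q$copies_per_ul)
})

test_that("qPCR plate round trip: exact at zero noise, <10% median error with noise", {
  truth <- 1.64e10
  plate <- simulate_qpcr(truth, efficiency = 1, cq_noise_sd = 0, seed = 1)
  curve <- fit_standard_curve(
    dplyr::select(dplyr::filter(plate, is_standard),
                  copies = standard_copies_per_ul, cq))
  q <- quantify_qpcr(dplyr::filter(plate, !is_standard), curve)
  expect_equal(q$copies_per_g, truth, tolerance = 1e-9)

  errs <- vapply(1:20, function(s) {
    plate <- simulate_qpcr(truth, efficiency = 0.95, cq_noise_sd = 0.15,
                           seed = 100 + s)
    curve <- fit_standard_curve(
      dplyr::select(dplyr::filter(plate, is_standard),
                    copies = standard_copies_per_ul, cq))
    q <- quantify_qpcr(dplyr::filter(plate, !is_standard), curve)
    abs(q$copies_per_g - truth) / truth
  }, numeric(1))
  expect_lt(median(errs), 0.10)
})

test_that("cell-specific rates are a unit conversion conserving the bulk rate", {
  expect_equal(cell_specific_rate(10.8, 1.64e10), 0.6585, tolerance = 1e-4)
  expect_equal(cell_specific_rate(0, 1e10), 0)
  expect_equal(cell_specific_rate(1, 1e10, copies_per_cell = 2),
               2 * cell_specific_rate(1, 1e10))

  # conservation: per-cell rate times cell density returns the bulk rate
  rate <- 3.7; copies <- 8.58e10
  cells_per_g <- copies / 1
  expect_equal(cell_specific_rate(rate, copies) * cells_per_g / 1e9, rate)
  expect_error(cell_specific_rate(1, 0),
               class = "nitrosponge_validation_error")
})

test_that("FISH relative abundance averages per-image percentages", {
  even <- tibble::tibble(image_id = 1:5, archaeal = 50, bacterial = 50)
  out <- fish_relative_abundance(even)
  expect_equal(out$mean_percent, 50)
  expect_equal(out$se_percent, 0)

  prop <- tibble::tibble(image_id = 1:2, archaeal = c(10, 20),
                         bacterial = c(30, 60))
  out2 <- fish_relative_abundance(prop)
  expect_equal(out2$mean_percent, 25)
  expect_equal(out2$se_percent, 0)

  expect_warning(
    fish_relative_abundance(
      tibble::tibble(image_id = 1:2, archaeal = c(10, 0),
                     bacterial = c(30, 0))), "zero counts")
})

test_that("binomial counts with a true 24% fraction are recovered within 3 SE", {
  set.seed(24)
  n_cells <- 400
  arch <- rbinom(10, n_cells, 0.24)
  counts <- tibble::tibble(image_id = 1:10, archaeal = arch,
                           bacterial = n_cells - arch)
  out <- fish_relative_abundance(counts)
  expect_lt(abs(out$mean_percent - 24), 3 * max(out$se_percent, 0.5))
})
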