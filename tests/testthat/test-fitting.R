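# Parameter estimation: noiseless round trips, design errors, scale
# equivariance, and the derived scalar quantities.

test_that("Hill fit recovers generating parameters from clean data", {
  cases <- list(
    list(vmax = 1361, k = 8.5, n = 1.1, unit = "per_s"),
    list(vmax = 279, k = 0.3, n = 1.0, unit = "umol_min_mg"),
    list(vmax = 959, k = 0.3, n = 1.8, unit = "per_s"))
  for (cs in cases) {
    p <- hill_params(cs$vmax, cs$k, cs$n, unit = cs$unit)
    ds <- gen_saturation(p, conc_series = span_levels(cs$k,
                           c(0.2, 0.5, 1, 2, 5, 10)))
    f <- fit_hill(ds)
    expect_true(f$converged)
    expect_equal(f$estimates[["vmax"]], cs$vmax, tolerance = 1e-3)
    expect_equal(f$estimates[["k_half"]], cs$k, tolerance = 1e-3)
    expect_equal(f$estimates[["n"]], cs$n, tolerance = 1e-3)
    expect_identical(f$unit, cs$unit)
  }
})

test_that("a Michaelis-Menten curve fits with Hill number near 1", {
  p <- hill_params(100, 2, n = 1)
  ds <- gen_saturation(p, conc_series = c(0.25, 0.5, 1, 2, 4, 8, 16),
                       noise = noise_model("multiplicative", 0.02,
                                           seed = 3, replicates = 3))
  f <- fit_hill(ds)
  ci <- confint_kin_fit(f)
  expect_gt(1, ci["n", "lower"])
  expect_lt(1, ci["n", "upper"])
})

test_that("under-determined saturation designs are rejected", {
  p <- hill_params(100, 2, 1)
  ds <- gen_saturation(p, conc_series = c(1, 2, 4))
  expect_error(fit_hill(ds), "under-determined")
})

test_that("global bisubstrate fit recovers both published truths", {
  refs <- vcpk_reference_params()$bisubstrate
  for (enz in names(refs)) {
    r <- refs[[enz]]
    p <- bisubstrate_params(r$vmax, r$ka, r$kb)
    ds <- gen_bisubstrate_grid(p, metal = r$metal)
    f <- fit_bisubstrate_global(ds)
    expect_true(f$converged)
    expect_equal(f$estimates[["vmax"]], r$vmax, tolerance = 1e-3)
    expect_equal(f$estimates[["ka"]], r$ka, tolerance = 1e-3)
    expect_equal(f$estimates[["kb"]], r$kb, tolerance = 1e-3)
  }
})

test_that("a saturating co-substrate reduces to a single-substrate fit", {
  p <- bisubstrate_params(476, 0.3, 0.5)
  ds <- gen_bisubstrate_grid(p,
                             a_levels = span_levels(0.3, c(0.2, 0.5, 1, 2, 5)),
                             b_levels = c(200, 500))
  f2 <- fit_bisubstrate_global(ds)
  mm <- fit_hill(gen_saturation(hill_params(476, 0.3, 1),
                                conc_series = span_levels(0.3, c(0.2, 0.5, 1, 2, 5))))
  expect_equal(f2$estimates[["ka"]], mm$estimates[["k_half"]],
               tolerance = 0.01)
})

test_that("degenerate bisubstrate designs raise rank errors", {
  p <- bisubstrate_params(476, 0.3, 0.5)
  ds <- suppressWarnings(
    gen_bisubstrate_grid(p, a_levels = c(0.1, 0.3, 0.6, 1.2, 2, 4),
                         b_levels = 0.5))
  expect_error(fit_bisubstrate_global(ds), "rank-deficient")
})

test_that("global inhibition fit recovers Ki in the inhibitor's unit", {
  p <- inhibition_params(476, 0.3, 7.8, mode = "C", ki_unit = "uM")
  ds <- gen_inhibition_grid(p, s_levels = span_levels(0.3, c(0.25, 0.5, 1, 2, 4, 8)),
                            i_levels = c(0, 10, 20, 30))
  f <- fit_inhibition_global(ds, "C")
  expect_equal(f$estimates[["ki"]], 7.8, tolerance = 1e-3)
  expect_identical(f$extra$ki_unit, "uM")
  # nesting: the mixed model on noncompetitive data returns alpha ~ 1
  pnc <- inhibition_params(300, 1.1, 1.3, mode = "NC")
  dnc <- gen_inhibition_grid(pnc, s_levels = span_levels(1.1),
                             i_levels = c(0, 0.65, 1.3, 2.6))
  fmt <- fit_inhibition_global(dnc, "MT")
  expect_equal(fmt$estimates[["alpha"]], 1, tolerance = 1e-3)
  # missing zero-inhibitor series warns but fits
  dwz <- gen_inhibition_grid(p, s_levels = span_levels(0.3),
                             i_levels = c(5, 10, 20)) |>
    suppressWarnings()
  expect_warning(fit_inhibition_global(dwz, "C"), "zero-inhibitor")
})

test_that("fitted K's scale with concentration units, Vmax does not", {
  p <- hill_params(500, 1.2, 2.1)
  conc <- span_levels(1.2, c(0.2, 0.5, 1, 2, 5, 10))
  f1 <- fit_hill(gen_saturation(p, conc))
  ds2 <- gen_saturation(p, conc)
  ds2$conc_K <- ds2$conc_K * 1000       # mM -> uM relabel
  # refit on the rescaled axis
  f2 <- fit_hill(ds2)
  expect_equal(f2$estimates[["k_half"]] / f1$estimates[["k_half"]],
               1000, tolerance = 1e-6)
  expect_equal(f2$estimates[["vmax"]], f1$estimates[["vmax"]],
               tolerance = 1e-6)
})

test_that("turnover conversion matches the published tetramer values", {
  expect_equal(kcat_from_vmax(476, 53138, 4), 1684, tolerance = 0.01)
  expect_equal(kcat_from_vmax(147, 54914, 4), 541, tolerance = 0.01)
  expect_equal(kcat_from_vmax(60, 60000, 1), 60)
  # inverse round trip
  for (v in c(12, 147, 476))
    expect_equal(vmax_from_kcat(kcat_from_vmax(v, 53138, 4), 53138, 4),
                 v, tolerance = 1e-12)
})

test_that("log catalytic efficiencies match the published table", {
  expect_equal(catalytic_efficiency(1684, 0.3), 6.76, tolerance = 0.01)
  expect_equal(catalytic_efficiency(541, 0.06), 6.95, tolerance = 0.01)
  expect_equal(catalytic_efficiency(1000, 1.0), 6.00)
})

test_that("activation folds and fractions come out as published", {
  a1 <- relative_activation(9, 279)
  expect_equal(a1$fold, 31)
  a2 <- relative_activation(1.5, 300)
  expect_equal(a2$fold, 200)
  expect_equal(a2$percent_of_activated, 0.5)
  a3 <- relative_activation(5, 5)
  expect_equal(a3$fold, 1)
  expect_equal(a3$percent_of_activated, 100)
  expect_warning(z <- relative_activation(0, 10), "undefined")
  expect_true(is.na(z$fold))
})
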