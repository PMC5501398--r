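# Pattern classification and mechanism inference.

test_that("reciprocal lines reproduce the algebraic slopes/intercepts", {
  p <- bisubstrate_params(476, 0.3, 0.5)
  ds <- gen_bisubstrate_grid(p, metal = "Mg")
  fam <- reciprocal_lines(ds)
  for (k in seq_len(nrow(fam))) {
    b <- fam$fixed_level[k]
    expect_equal(fam$slope[k], p$ka * (1 + p$kb / b) / p$vmax,
                 tolerance = 1e-9)
    expect_equal(fam$intercept[k], (1 + p$kb / b) / p$vmax,
                 tolerance = 1e-9)
  }
  # single fixed level is not a family
  one <- suppressWarnings(
    gen_bisubstrate_grid(p, a_levels = c(0.1, 0.3, 0.9),
                         b_levels = 0.5))
  expect_error(reciprocal_lines(one), ">= 2 fixed-species levels")
  # a zero-velocity row is dropped with a warning
  df <- as.data.frame(ds)
  df$velocity[1] <- 0
  ds0 <- velocity_dataset(df, varied_species = "pep3")
  expect_warning(fam0 <- reciprocal_lines(ds0), "excluded")
  expect_identical(attr(fam0, "n_dropped"), 1L)
})

test_that("random-order families intersect on the 1/S axis at -1/Ka", {
  set.seed(5)
  for (k in 1:10) {
    p <- bisubstrate_params(10^runif(1, 1, 3), 10^runif(1, -1.5, 0.5),
                            10^runif(1, -1.5, 0.5))
    ds <- gen_bisubstrate_grid(p,
                               a_levels = span_levels(p$ka, c(0.2, 0.5, 1, 2, 5)),
                               b_levels = span_levels(p$kb, c(0.3, 0.8, 1.5, 3, 10)))
    call <- classify_initial_velocity(reciprocal_lines(ds))
    expect_identical(call$category, "intersecting_on_1S_axis")
    expect_equal(call$intersection[["x"]], -1 / p$ka,
                 tolerance = 1e-6)
    expect_lt(abs(call$intersection[["y"]]), 1e-9 / p$vmax)
  }
})

test_that("parallel and degenerate families are recognized", {
  fam <- structure(data.frame(fixed_level = c(1, 2, 3),
                              slope = c(0.5, 0.5, 0.5),
                              intercept = c(0.1, 0.2, 0.3),
                              n_points = 5),
                   class = c("reciprocal_family", "data.frame"))
  expect_identical(classify_initial_velocity(fam)$category, "parallel")
  fam2 <- fam
  fam2$slope <- c(0.5, 0.5, 0.9)
  fam2$intercept <- c(0.1, 0.1, 0.3)
  expect_error(classify_initial_velocity(fam2), "identical lines")
})

test_that("inhibition classification round-trips every mode", {
  vmax <- 476; km <- 0.3
  s_levels <- span_levels(km, c(0.25, 0.5, 1, 2, 4, 8))
  mk <- function(mode, alpha = NULL)
    gen_inhibition_grid(inhibition_params(vmax, km, 7.8, mode,
                                          alpha = alpha, ki_unit = "uM"),
                        s_levels = s_levels, i_levels = c(0, 5, 15, 30))
  expect_identical(classify_inhibition(mk("C"))$inhibition_mode, "C")
  expect_identical(classify_inhibition(mk("NC"))$inhibition_mode, "NC")
  expect_identical(classify_inhibition(mk("MT", alpha = 0.5))$inhibition_mode,
                   "MT_alpha_lt_1")
  expect_identical(classify_inhibition(mk("MT", alpha = 2.2))$inhibition_mode,
                   "MT_alpha_gt_1")
})

test_that("classification ignores row order and velocity rescaling", {
  p <- inhibition_params(300, 1.1, 1.3, mode = "MT", alpha = 0.4)
  ds <- gen_inhibition_grid(p, s_levels = span_levels(1.1),
                            i_levels = c(0, 0.65, 1.3, 2.6),
                            noise = noise_model("multiplicative", 0.03,
                                                seed = 9, replicates = 2))
  base <- classify_inhibition(ds)$inhibition_mode
  shuf <- as.data.frame(ds)[sample(nrow(ds)), ]
  ds_shuf <- velocity_dataset(shuf, varied_species = "pep3",
                              inhibitor_unit = "mM")
  expect_identical(classify_inhibition(ds_shuf)$inhibition_mode, base)
  sc <- as.data.frame(ds)
  sc$velocity <- sc$velocity * 37.5
  ds_sc <- velocity_dataset(sc, varied_species = "pep3",
                            inhibitor_unit = "mM")
  expect_identical(classify_inhibition(ds_sc)$inhibition_mode, base)
})

test_that("mechanism inference applies the dead-end rule table", {
  # published pattern rows for the two isozymes
  ev1 <- list(initial_velocity = "intersecting_on_1S_axis",
              oxalate_vs_A = "C", oxalate_vs_B = "MT_alpha_lt_1",
              adpcr_vs_A = "NC", adpcr_vs_B = "C")
  expect_identical(infer_mechanism(ev1)$label,
                   "rapid_equilibrium_random")
  ev2 <- modifyList(ev1, list(adpcr_vs_A = "MT_alpha_gt_1"))
  expect_identical(infer_mechanism(ev2)$label,
                   "rapid_equilibrium_random")
  # an analog competitive against both substrates means ordered binding
  ev3 <- list(initial_velocity = "intersecting_on_1S_axis",
              oxalate_vs_A = "C", oxalate_vs_B = "C")
  expect_identical(infer_mechanism(ev3)$label, "ordered_A_first")
  ev4 <- list(initial_velocity = "intersecting_on_1S_axis",
              adpcr_vs_A = "C", adpcr_vs_B = "C")
  expect_identical(infer_mechanism(ev4)$label, "ordered_B_first")
  # initial-velocity evidence alone cannot fix the mechanism
  ev5 <- list(initial_velocity = "intersecting_on_1S_axis")
  expect_identical(infer_mechanism(ev5)$label, "indeterminate")
  # contradictory evidence is surfaced, not silently resolved
  ev6 <- modifyList(ev1, list(oxalate_vs_A = "NC"))
  out <- infer_mechanism(ev6)
  expect_identical(out$label, "indeterminate")
  expect_true(any(grepl("not competitive", out$notes)))
  expect_error(infer_mechanism(list(oxalate_vs_A = "C")),
               "initial-velocity")
})

test_that("the full noiseless pipeline identifies random-order binding", {
  set.seed(21)
  for (k in 1:5) {
    call <- pipeline_mechanism_call(
      vmax = runif(1, 100, 1000),
      ka = 10^runif(1, -1.5, 0.5), kb = 10^runif(1, -1.5, 0.5),
      ki_ox = 10^runif(1, -2, 0), ki_cr = 10^runif(1, -1, 1),
      alpha_mt = runif(1, 0.2, 0.8))
    expect_identical(call$label, "rapid_equilibrium_random")
  }
})
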