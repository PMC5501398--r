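# Assay-mix speciation: ionization, metal-ADP complexation, ionic
# strength bookkeeping, and the inverse (targets -> totals) path.

test_that("PEP ionization follows Henderson-Hasselbalch", {
  # half-ionization at pH = pK, for any total
  expect_equal(ionize_pep(10, ph = 6.3, pk = 6.3)$pep3, 5.0)
  # closed form at the assay pH
  expect_equal(ionize_pep(40, ph = 7.0, pk = 6.3)$pep3,
               40 / (1 + 10^(-0.7)), tolerance = 1e-12)
  expect_equal(ionize_pep(0, ph = 7.0)$pep3, 0)
  # the two fractions always rebuild the total
  for (tot in c(0.5, 5, 40))
    expect_equal(sum(unlist(ionize_pep(tot, 7.0))), tot,
                 tolerance = 1e-9)
  expect_error(ionize_pep(-1, 7.0), "non-negative")
})

test_that("PEP ionization is linear in total and monotone in pH", {
  f <- function(tot, ph) ionize_pep(tot, ph)$pep3
  expect_equal(f(8, 7.0), 4 * f(2, 7.0), tolerance = 1e-12)
  phs <- seq(5.5, 8.5, by = 0.25)
  expect_true(all(diff(vapply(phs, f, 0, tot = 10)) > 0))
})

test_that("ADP-metal complexation solves the mass-action quadratic", {
  out <- complex_metal_adp(7, 9, 0.38)
  expect_equal(out$complex, oracle_complex_scan(7, 9, 0.38),
               tolerance = 1e-6)
  # quantitative binding in the tight-Kd limit
  expect_equal(complex_metal_adp(7, 9, 1e-9)$complex, 7,
               tolerance = 1e-6)
  expect_equal(complex_metal_adp(9, 7, 1e-9)$complex, 7,
               tolerance = 1e-6)
  z <- complex_metal_adp(0, 5, 0.38)
  expect_equal(z$complex, 0)
  expect_equal(z$metal_free, 5)
  expect_error(complex_metal_adp(1, 1, 0), "positive")
})

test_that("complexation matches the brute-force scan on random mixes", {
  set.seed(11)
  for (k in 1:50) {
    a0 <- runif(1, 0, 20); m0 <- runif(1, 0, 20)
    kd <- 10^runif(1, -2, 1)
    out <- complex_metal_adp(a0, m0, kd)
    expect_lt(abs(out$complex - oracle_complex_scan(a0, m0, kd)),
              1e-6)
    # mass balance and mass-action residual
    expect_equal(out$complex + out$adp_free, a0, tolerance = 1e-9)
    expect_equal(out$complex + out$metal_free, m0, tolerance = 1e-9)
    if (out$complex > 0)
      expect_lt(abs(out$adp_free * out$metal_free -
                      kd * out$complex) / kd, 1e-6)
  }
})

test_that("target free species invert to pipettable totals", {
  tot <- compose_for_targets(6.5, 2.0, 0.38)
  expect_equal(tot$adp_total, 6.5 + 0.38 * 6.5 / 2.0, tolerance = 1e-12)
  expect_equal(tot$metal_total, 8.5)
  z <- compose_for_targets(0, 3, 0.38)
  expect_equal(z$adp_total, 0)
  expect_equal(z$metal_total, 3)
  expect_error(compose_for_targets(1, 0, 0.38), "infeasible")
  # round-trip identity on random targets
  set.seed(7)
  for (k in 1:25) {
    cx <- runif(1, 0, 10); mf <- runif(1, 0.01, 10)
    kd <- 10^runif(1, -2, 1)
    tt <- compose_for_targets(cx, mf, kd)
    back <- complex_metal_adp(tt$adp_total, tt$metal_total, kd)
    expect_equal(back$complex, cx, tolerance = 1e-9)
    expect_equal(back$metal_free, mf, tolerance = 1e-9)
  }
})

test_that("ionic strength sums charged species and balances with TMACl", {
  expect_equal(ionic_strength(c(K = 150, Cl = 150)), 150)
  expect_equal(ionic_strength(c(Mg = 2, Cl = 4)), 6)
  expect_equal(ionic_strength(c(K = 90, Cl = 94, Mg = 2)), 96)
  expect_error(ionic_strength(c(K = 1, Xx = 2)), "Xx")
  expect_equal(balance_ionic_strength(210, 300), 90)
  expect_equal(balance_ionic_strength(300, 300), 0)
  expect_error(balance_ionic_strength(310, 300), "exceeds")
})

test_that("full speciation keeps every mass balance", {
  comp <- assay_composition(pep_total = 40, adp_total = 9.7,
                            metal_identity = "Mg", metal_total = 39,
                            monovalent = c(K = 90), tmacl = 50)
  st <- speciate(comp)
  expect_equal(st$pep3 + st$pep_protonated, 40, tolerance = 1e-9)
  expect_equal(st$adp_metal_complex + st$adp_free, 9.7,
               tolerance = 1e-9)
  expect_equal(st$adp_metal_complex + st$metal_free, 39,
               tolerance = 1e-9)
  expect_true(all(unlist(st) >= 0))
  kd <- speciation_constants()$kd_adp_mg
  expect_lt(abs(st$adp_free * st$metal_free -
                  kd * st$adp_metal_complex) / kd, 1e-6)
  # the Mn table uses its own dissociation constant
  comp_mn <- assay_composition(adp_total = 3.2, metal_identity = "Mn",
                               metal_total = 3.5)
  st_mn <- speciate(comp_mn)
  expect_equal(st_mn$adp_metal_complex,
               oracle_complex_scan(3.2, 3.5, 0.10), tolerance = 1e-6)
})

test_that("composition invariants reject bad input", {
  expect_error(assay_composition(pep_total = -1), "non-negative")
  expect_error(assay_composition(ph = 4.5), "ph")
  expect_error(assay_composition(metal_identity = "Ca"))
})
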