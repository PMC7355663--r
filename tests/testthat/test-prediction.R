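test_that("mass-balance solver agrees with an independent root finder", {
  set.seed(7)
  for (i in 1:15) {
    p <- sips_parameters(kd = 10^stats::runif(1, 0, 3),
                         bmax = 10^stats::runif(1, 0.5, 3),
                         n = stats::runif(1, 0.3, 1.2))
    m <- 10^stats::runif(1, -1, 2)
    total <- 10^stats::runif(1, -1, 1)
    fu <- fraction_unbound_sips(p, m, total)
    oracle <- stats::uniroot(
      function(L) L + m * sips_bound(L, p) - total,
      c(1e-15, total), tol = 1e-14)$root / total * 100
    expect_equal(fu, oracle, tolerance = 1e-6)
  }
})

test_that("unbound fraction falls with melanin and is 100% without it", {
  p <- chloroquine_sips()
  expect_identical(fraction_unbound_sips(p, 0, 1), 100)
  fu <- vapply(c(0.1, 1, 5, 34.8), fraction_unbound_sips, numeric(1),
               params = p, total_conc = 1)
  expect_true(all(diff(fu) < 0))
  # published spot check: chloroquine, 1 mg/mL, 1 uM total
  expect_equal(fraction_unbound_sips(p, 1, 1), 0.41, tolerance = 0.01)
})

test_that("dilution scaling matches the mass balance in the linear limit", {
  # n = 1 and total << Kd: binding is linear, so the closed-form dilution
  # rescaling and the numerical mass balance must coincide
  p <- sips_parameters(kd = 500, bmax = 40, n = 1)
  total <- 1e-4
  fu1 <- fraction_unbound_sips(p, 1, total)
  fu2 <- fraction_unbound_sips(p, 34.8, total)
  expect_equal(dilution_scale(fu1, 34.8), fu2, tolerance = 1e-4)
})

test_that("dilution scaling round-trips and fixes its edge cases", {
  expect_equal(dilution_scale(9.2, 34.8), 0.29, tolerance = 0.005)
  expect_equal(dilution_scale(100, 7), 100)
  expect_equal(dilution_scale(42, 1), 42)
  for (fu in c(0.05, 3, 42, 99))
    expect_equal(dilution_scale(dilution_scale(fu, 34.8), 1 / 34.8), fu)
  expect_error(dilution_scale(0, 2), "percent")
})

test_that("cassette correction rescales competitive-assay fractions", {
  expect_equal(cassette_correction(21), 10)
  expect_equal(cassette_correction(19.3), 9.19, tolerance = 0.005)
  expect_equal(cassette_correction(37, factor = 1), 37)
  expect_error(cassette_correction(-1), "positive")
})

test_that("Kd classes use half-open bins favouring the weaker class", {
  expect_identical(classify_kd(c(0.8, 29, 214, 912)),
                   c("extreme", "high", "intermediate", "low"))
  # boundary values fall into the weaker-binding class
  expect_identical(classify_kd(c(6.5, 65, 650)),
                   c("high", "intermediate", "low"))
  expect_identical(classify_kd(c(6.499, 64.99, 649.9)),
                   c("extreme", "high", "intermediate"))
  expect_error(classify_kd(0), "positive")
})

test_that("unbound-fraction classes mirror the Kd tiers", {
  expect_identical(classify_fu(c(0.0012, 0.33, 5.7, 54)),
                   c("extreme", "high", "intermediate", "low"))
  expect_identical(classify_fu(c(0.1, 1, 10)),
                   c("high", "intermediate", "low"))
  expect_true(is.na(classify_fu(NA)))
  expect_error(classify_fu(101), "percent")
})

test_that("predict_unbound assembles a coherent prediction row", {
  row <- predict_unbound(chloroquine_sips(), compound = "Chloroquine")
  expect_identical(row$binding_class, "extreme")
  expect_lt(row$fu_vivo_pct, row$fu_vitro_pct)
  expect_identical(row$method, "sips_mass_balance")
})
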