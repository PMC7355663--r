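test_that("bound amount follows the supernatant mass balance", {
  expect_equal(bound_amount(100, 30, 1), 70)
  expect_equal(bound_amount(50, 50, 2), 0)
  # negative values are retained, not truncated
  expect_equal(bound_amount(10, 12, 1), -2)
  expect_error(bound_amount(1, 1, 0), "melanin")
})

test_that("generated bound amounts match the isotherm they came from", {
  cfg <- synth_config(true_kd = 76, true_bmax = 380, true_n = 0.605,
                      noise_cv = 0, seed = 101,
                      conc_series = 500 / 2^(0:10))
  out <- generate_equilibrium_dataset(cfg, melanin_conc = 1,
                                      n_replicates = 1)
  expect_equal(out$data$bound, sips_bound(out$data$free, chloroquine_sips()),
               tolerance = 1e-9)
})

test_that("noise-free equilibrium data invert to the exact Sips parameters", {
  cfg <- synth_config(true_kd = 66, true_bmax = 66, true_n = 0.715,
                      noise_cv = 0, seed = 102,
                      conc_series = papaverine_design)
  sf <- fit_sips(generate_equilibrium_dataset(cfg, melanin_conc = 1)$data)
  expect_identical(sf$verdict, "fitted")
  expect_lt(abs(sf$params$kd - 66) / 66, 1e-3)
  expect_lt(abs(sf$params$bmax - 66) / 66, 1e-3)
  expect_lt(abs(sf$params$n - 0.715) / 0.715, 1e-3)
})

test_that("Langmuir-generated data fit back with n within 1 SE of 1", {
  cfg <- synth_config(true_kd = 50, true_bmax = 80, true_n = 1,
                      noise_cv = 0.03, seed = 103,
                      conc_series = papaverine_design)
  sf <- fit_sips(generate_equilibrium_dataset(cfg, melanin_conc = 1)$data)
  expect_lt(abs(sf$params$n - 1), sf$params$se_n)
})

test_that("fitted Kd lies within 2 SE of truth in most noisy replicates", {
  # papaverine truth, 0.25-250 uM design, 1 mg/mL melanin, 5% noise
  ok <- vapply(1:200, function(i) {
    cfg <- synth_config(true_kd = 66, true_bmax = 66, true_n = 0.715,
                        noise_cv = 0.05, seed = 40000 + i,
                        conc_series = papaverine_design)
    sf <- fit_sips(generate_equilibrium_dataset(cfg, melanin_conc = 1)$data)
    !is.null(sf$params) && abs(sf$params$kd - 66) <= 2 * sf$params$se_kd
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("non-binding data produce a no-binding verdict, not an error", {
  cfg <- synth_config(true_kd = 1e5, true_bmax = 0.01, true_n = 1,
                      noise_cv = 0.03, seed = 104,
                      conc_series = papaverine_design)
  out <- generate_equilibrium_dataset(cfg, melanin_conc = 1)
  # free ~ total everywhere: about half the bound amounts go negative
  sf <- suppressWarnings(fit_sips(out$data))
  expect_s3_class(sf, "sips_fit")
  expect_true(sf$verdict == "no_binding" ||
                (sf$n_negative_bound > 0 && !is.null(sf$params) &&
                   sf$params$se_kd > sf$params$kd))
})

test_that("target capacity converts Bmax to a molar assay concentration", {
  expect_equal(sips_target_capacity(sips_parameters(46, 112, 0.64), 0.5), 56)
  expect_equal(sips_target_capacity(chloroquine_sips(), 0.5), 190)
  # linear in the melanin concentration
  p <- papaverine_sips()
  expect_equal(sips_target_capacity(p, 2), 4 * sips_target_capacity(p, 0.5))
  expect_equal(sips_target_capacity(p, 0), 0)
})

test_that("equilibrium CSV round trip preserves the dataset", {
  cfg <- synth_config(true_kd = 66, true_bmax = 66, true_n = 0.715,
                      noise_cv = 0.05, seed = 105,
                      conc_series = papaverine_design)
  out <- generate_equilibrium_dataset(cfg, melanin_conc = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_equilibrium_csv(out$data, path)
  back <- read_equilibrium_csv(path, melanin_conc = 1)
  expect_equal(back$bound, out$data$bound, tolerance = 1e-8)
  expect_equal(attr(back, "melanin_conc"), 1)
})
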