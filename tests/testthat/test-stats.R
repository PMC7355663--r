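test_that("capacity ratios put both assays on one binding-strength scale", {
  expect_equal(capacity_ratio_mst(12.5), 1)
  expect_equal(capacity_ratio_mst(0.8), 15.625)
  expect_equal(capacity_ratio_mst(260), 12.5 / 260)
  # Sips: capacity / Kd^n, terazosin and chloroquine from published values
  expect_equal(capacity_ratio_sips(sips_parameters(46, 112, 0.64)),
               56 / 46^0.64, tolerance = 1e-12)
  expect_equal(capacity_ratio_sips(chloroquine_sips()), 190 / 76^0.605)
  # n = 1 and capacity equal to Kd gives exactly 1
  expect_equal(capacity_ratio_sips(sips_parameters(60, 120, 1)), 1)
})

test_that("Spearman correlation behaves as a rank statistic", {
  x <- c(3, 1, 4, 1.5, 9, 2.6)
  expect_equal(spearman_rho(x, x), 1)
  expect_equal(spearman_rho(x, -x), -1)
  # invariance under strictly monotone transforms
  y <- c(2, 7, 1, 8, 2.8, 18)
  expect_equal(spearman_rho(exp(x), y^3), spearman_rho(x, y))
  expect_error(spearman_rho(x, rep(1, 6)), "constant")
})

test_that("exact permutation p-value matches the reference implementation", {
  set.seed(9)
  x <- stats::rnorm(7)
  y <- x + stats::rnorm(7, sd = 0.8)
  ours <- spearman_test(x, y)
  ref <- stats::cor.test(x, y, method = "spearman", exact = TRUE)
  expect_identical(ours$method, "exact permutation")
  expect_equal(ours$rho, unname(ref$estimate))
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
  # large-n branch uses the t approximation
  x2 <- stats::rnorm(20); y2 <- x2 + stats::rnorm(20)
  expect_identical(spearman_test(x2, y2)$method, "t approximation")
})

test_that("through-origin regression is the Sxy/Sxx slope", {
  expect_equal(origin_regression(2, 10)$slope, 5)
  x <- c(1, 2, 5); y <- 3 * x
  expect_equal(origin_regression(x, y)$slope, 3)
  # closed form and scale equivariance
  set.seed(3)
  x <- stats::runif(8); y <- stats::rnorm(8)
  expect_equal(origin_regression(x, y)$slope, sum(x * y) / sum(x^2))
  expect_equal(origin_regression(x, 7 * y)$slope,
               7 * origin_regression(x, y)$slope)
  expect_error(origin_regression(c(0, 0), c(1, 2)), "zero")
})

test_that("class limits are the slope mapped through the fu breaks", {
  expect_equal(derive_class_limits(65), c(650, 65, 6.5))
  expect_equal(derive_class_limits(1), c(10, 1, 0.1))
  expect_equal(derive_class_limits(65, 54), 3510)
})

test_that("cross-method comparison finds strong rank agreement", {
  cmp <- compare_methods(binding_parameters())
  expect_equal(cmp$n, 7)  # compounds with both parameter sets
  expect_equal(cmp$rho, 0.89, tolerance = 0.005)
  expect_lt(cmp$p_value, 0.05)
  expect_setequal(
    cmp$ratios$compound,
    c("Terazosin", "Chloroquine", "Levofloxacin", "Papaverine",
      "Propranolol", "Nadolol", "Timolol"))
})
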