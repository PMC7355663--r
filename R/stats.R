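#' Target-capacity to Kd ratio for the MST assay
#'
#' MST sees melanin as a single-site target, so its target capacity is the
#' molar melanin concentration in the assay (12.5 uM at 0.5 mg/mL); the
#' capacity/Kd ratio puts compounds with very different affinities and
#' capacities on one binding-strength scale.
#'
#' @param kd MST dissociation constant(s), uM (> 0).
#' @param melanin_target_conc Molar melanin concentration, uM.
#' @return Dimensionless ratio(s) `melanin_target_conc / kd`.
#' @export
#' @examples
#' capacity_ratio_mst(0.8)  # chloroquine: 15.625
capacity_ratio_mst <- function(kd, melanin_target_conc = 12.5) {
  if (any(kd <= 0, na.rm = TRUE)) stop("`kd` must be positive (uM)")
  melanin_target_conc / kd
}

#' Target-capacity to Kd^n ratio for the Sips isotherm
#'
#' The Sips analogue of [capacity_ratio_mst()]: the ligand-specific target
#' capacity `Bmax * melanin_conc` divided by `Kd^n` (the heterogeneous
#' half-saturation constant on the `L^n` scale), evaluated at the melanin
#' concentration of the MST assay so the two methods are comparable.
#'
#' @param params A [sips_parameters()] object.
#' @param melanin_conc Melanin concentration, mg/mL (default: 0.5, the MST
#'   assay level).
#' @return Dimensionless ratio.
#' @export
capacity_ratio_sips <- function(params, melanin_conc = 0.5) {
  stopifnot(inherits(params, "sips_parameters"))
  sips_target_capacity(params, melanin_conc) / params$kd^params$n
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties; invariant under strictly
#' monotone transforms of either input.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return The correlation of the rank vectors.
#' @export
#' @examples
#' spearman_rho(1:5, c(2, 4, 8, 16, 32))  # 1
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("Spearman correlation is undefined for a constant vector")
  stats::cor(rank(x), rank(y))
}

#' Spearman correlation test
#'
#' Two-sided p-value for the rank correlation: an exact permutation test
#' (all `n!` rearrangements) for `n <= 9`, and the usual t approximation
#' `t = rho * sqrt((n-2)/(1-rho^2))` on `n - 2` degrees of freedom above
#' that.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return A list with `rho`, `p_value`, `n`, and `method`.
#' @export
spearman_test <- function(x, y) {
  rho <- spearman_rho(x, y)
  n <- length(x)
  if (n <= 9L) {
    rx <- rank(x)
    ry <- rank(y)
    perms <- permutations(n)
    rhos <- apply(perms, 1L, function(p) stats::cor(rx, ry[p]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tval), df = n - 2)
    method <- "t approximation"
  }
  list(rho = rho, p_value = p, n = n, method = method)
}

# all permutations of 1..n as an n! x n matrix (recursive construction)
permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, matrix(c(seq_len(n)[-i])[sub], nrow(sub), n - 1L))
  }))
}

#' Through-origin least-squares regression
#'
#' Slope of `y` on `x` with the intercept fixed at the origin,
#' `sum(x*y) / sum(x^2)`, computed via [stats::lm()] so a standard error
#' comes with it.
#'
#' @param x,y Numeric vectors of equal length >= 2; `x` not all zero.
#' @return A list with `slope`, `se`, and `n`.
#' @export
#' @examples
#' origin_regression(c(2), c(10))$slope  # 5
origin_regression <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 1L)
  if (all(x == 0)) stop("`x` must not be all zero")
  fit <- stats::lm(y ~ 0 + x)
  slope <- unname(stats::coef(fit)[1])
  se <- if (length(x) >= 2L)
    sqrt(sum(stats::residuals(fit)^2) / (length(x) - 1L) / sum(x^2))
  else NA_real_
  list(slope = slope, se = se, n = length(x))
}

#' Kd classification limits from the fu-Kd regression slope
#'
#' The through-origin slope of MST Kd on predicted in vivo unbound
#' fraction maps unbound-fraction class breaks (10, 1, 0.1%) onto the Kd
#' scale: `Kd_limit = slope * fu_break`, giving 650/65/6.5 uM for a slope
#' of 65.
#'
#' @param slope Regression slope, uM per percent (> 0).
#' @param fu_breaks Unbound-fraction breaks, percent.
#' @return Kd limits, uM, in the order of `fu_breaks`.
#' @export
#' @examples
#' derive_class_limits(65)  # 650 65 6.5
derive_class_limits <- function(slope, fu_breaks = c(10, 1, 0.1)) {
  if (slope <= 0) stop("`slope` must be positive")
  slope * fu_breaks
}

#' Cross-method comparison of melanin-binding strength
#'
#' Computes the MST and Sips target-capacity ratios for the compounds with
#' both parameter sets and their Spearman correlation -- the comparison
#' behind the two-assay concordance claim.
#'
#' @param params_table A data frame shaped like [binding_parameters()]:
#'   columns `compound`, `kd_mst_uM`, `kd_sips_uM`, `bmax_nmol_mg`,
#'   `n_sips`.
#' @param mst_target_conc Molar melanin concentration of the MST assay, uM.
#' @param sips_melanin_conc Melanin concentration used to translate Sips
#'   capacities to the MST assay, mg/mL.
#'
#' @return An object of class `method_comparison`: a list with `ratios`
#'   (per-compound tibble), `rho`, `p_value`, and `n`.
#' @export
#' @examples
#' compare_methods(binding_parameters())
compare_methods <- function(params_table, mst_target_conc = 12.5,
                            sips_melanin_conc = 0.5) {
  tb <- params_table
  ok <- is.finite(tb$kd_mst_uM) & is.finite(tb$kd_sips_uM) &
    is.finite(tb$bmax_nmol_mg) & is.finite(tb$n_sips)
  tb <- tb[ok, ]
  if (nrow(tb) < 3L)
    stop("need at least 3 compounds with both parameter sets")
  mst_ratio <- capacity_ratio_mst(tb$kd_mst_uM, mst_target_conc)
  sips_ratio <- vapply(seq_len(nrow(tb)), function(i) {
    capacity_ratio_sips(
      sips_parameters(tb$kd_sips_uM[i], tb$bmax_nmol_mg[i], tb$n_sips[i]),
      sips_melanin_conc)
  }, numeric(1))
  ts <- spearman_test(mst_ratio, sips_ratio)
  structure(
    list(ratios = tibble::tibble(compound = tb$compound,
                                 mst_ratio = mst_ratio,
                                 sips_ratio = sips_ratio),
         rho = ts$rho, p_value = ts$p_value, n = ts$n,
         p_method = ts$method),
    class = "method_comparison"
  )
}

#' @export
print.method_comparison <- function(x, ...) {
  cat("Cross-method comparison of capacity/Kd ratios\n")
  cat(sprintf("  Spearman rho = %.3f (p = %.4g, %s, n = %d)\n",
              x$rho, x$p_value, x$p_method, x$n))
  print(x$ratios)
  invisible(x)
}

#' Scatter plot of the two methods' capacity ratios
#'
#' Log-log scatter of MST vs Sips capacity ratios with the line of
#' identity.
#'
#' @param x A `method_comparison` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.method_comparison <- function(x, ...) {
  r <- x$ratios
  graphics::plot(r$sips_ratio, r$mst_ratio, log = "xy",
                 xlab = "target capacity / Kd^n (Sips)",
                 ylab = "target capacity / Kd (MST)", ...)
  graphics::abline(0, 1, untf = TRUE, lty = 2)
  graphics::text(r$sips_ratio, r$mst_ratio, r$compound, pos = 3, cex = 0.7)
  invisible(x)
}

#' Regress MST Kd on predicted in vivo unbound fraction
#'
#' Through-origin regression of the MST dissociation constant on the
#' predicted RPE-choroid unbound fraction across compounds, plus the Kd
#' class limits the slope implies ([derive_class_limits()]).
#'
#' @param kd_mst MST Kd values, uM.
#' @param fu_in_vivo Predicted in vivo unbound fractions, percent.
#' @param fu_breaks Unbound-fraction class breaks, percent.
#' @return A list with `slope`, `se`, `n`, and `kd_limits`.
#' @export
kd_fu_regression <- function(kd_mst, fu_in_vivo, fu_breaks = c(10, 1, 0.1)) {
  ok <- is.finite(kd_mst) & is.finite(fu_in_vivo)
  reg <- origin_regression(fu_in_vivo[ok], kd_mst[ok])
  c(reg, list(kd_limits = derive_class_limits(reg$slope, fu_breaks)))
}
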