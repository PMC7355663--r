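#' Parameters of the quadratic ligand-depletion binding model
#'
#' The depletion model describes a single class of binding site on a target
#' present at a concentration (`target_conc`) comparable to the ligand
#' concentrations, so free-ligand depletion cannot be neglected.  The
#' observable interpolates between `unbound_signal` (target alone) and
#' `bound_signal` (saturated complex) according to the fraction of target
#' occupied.
#'
#' @param unbound_signal Signal of the free target (normalized fluorescence
#'   or raw counts, arbitrary units).
#' @param bound_signal Signal of the saturated target-ligand complex, same
#'   units as `unbound_signal`.
#' @param kd Dissociation constant, uM.  Must be positive.
#' @param target_conc Total target concentration in the assay, uM.  Must be
#'   positive.  For melanin nanoparticles at 0.5 mg/mL and 40 kDa this is
#'   12.5 uM (see [melanin_molar_conc()]).
#'
#' @return An object of class `depletion_params`.
#' @seealso [depletion_fraction_bound()], [depletion_occupancy()]
#' @export
#' @examples
#' depletion_params(1, 0.8, kd = 30, target_conc = 12.5)
depletion_params <- function(unbound_signal, bound_signal, kd, target_conc) {
  stopifnot(is.numeric(unbound_signal), length(unbound_signal) == 1L,
            is.numeric(bound_signal), length(bound_signal) == 1L,
            is.numeric(kd), length(kd) == 1L,
            is.numeric(target_conc), length(target_conc) == 1L)
  if (!is.finite(kd) || kd <= 0)
    stop("`kd` must be a positive, finite concentration (uM)")
  if (!is.finite(target_conc) || target_conc <= 0)
    stop("`target_conc` must be a positive, finite concentration (uM)")
  if (unbound_signal == bound_signal)
    warning("unbound_signal equals bound_signal: the model is uninformative")
  structure(
    list(unbound_signal = unbound_signal, bound_signal = bound_signal,
         kd = kd, target_conc = target_conc),
    class = "depletion_params"
  )
}

#' Fraction of target occupied under ligand depletion
#'
#' Solves the single-site mass-action equilibrium for the bound-target
#' fraction without the free-ligand approximation.  With `s = c + ct + Kd`
#' the occupied fraction is `(s - sqrt(s^2 - 4 c ct)) / (2 ct)`, evaluated
#' in the rationalized form `2 c / (s + sqrt(s^2 - 4 c ct))`, which is
#' algebraically identical but avoids catastrophic cancellation when
#' `c >> ct`.
#'
#' @param ligand_conc Total ligand concentration(s), uM.  Nonnegative.
#' @param kd Dissociation constant, uM (> 0).
#' @param target_conc Total target concentration, uM (> 0).
#'
#' @return Occupied fraction(s) in `[0, 1]`, same length as `ligand_conc`.
#' @export
#' @examples
#' depletion_occupancy(12.5, kd = 30, target_conc = 12.5)
depletion_occupancy <- function(ligand_conc, kd, target_conc) {
  if (any(!is.finite(ligand_conc)) || any(ligand_conc < 0))
    stop("`ligand_conc` must be finite and nonnegative (uM)")
  if (!is.finite(kd) || kd <= 0) stop("`kd` must be positive (uM)")
  if (!is.finite(target_conc) || target_conc <= 0)
    stop("`target_conc` must be positive (uM)")
  s <- ligand_conc + target_conc + kd
  disc <- s^2 - 4 * ligand_conc * target_conc
  if (any(disc < 0)) {
    # analytically impossible; only reachable through rounding
    warning("negative discriminant clamped to zero")
    disc <- pmax(disc, 0)
  }
  2 * ligand_conc / (s + sqrt(disc))
}

#' Depletion-model binding signal
#'
#' Expected observable for a capillary at a given total ligand
#' concentration: the unbound-target signal plus the bound-minus-unbound
#' amplitude scaled by the occupied-target fraction from
#' [depletion_occupancy()].  This is the dose-response curve fitted to MST
#' data (normalized fluorescence in MST mode, raw pre-heating counts in
#' initial-fluorescence mode).
#'
#' @param ligand_conc Total ligand concentration(s), uM.  Nonnegative.
#' @param params A [depletion_params()] object.
#'
#' @return Predicted signal(s), between `unbound_signal` and `bound_signal`
#'   inclusive, monotone in `ligand_conc`.
#' @export
#' @examples
#' p <- depletion_params(1, 0.8, kd = 30, target_conc = 12.5)
#' depletion_fraction_bound(c(0, 30, 3000), p)
depletion_fraction_bound <- function(ligand_conc, params) {
  stopifnot(inherits(params, "depletion_params"))
  fb <- depletion_occupancy(ligand_conc, params$kd, params$target_conc)
  params$unbound_signal + (params$bound_signal - params$unbound_signal) * fb
}

#' Sips (Langmuir-Freundlich) isotherm parameters
#'
#' The Sips isotherm `B = Bmax L^n / (Kd^n + L^n)` describes nonspecific
#' surface binding with a distribution of binding energies; the
#' heterogeneity index `n` equals 1 for a homogeneous (Langmuir) surface
#' and falls below 1 as the spread of site energies grows.
#'
#' @param kd Dissociation constant, uM (> 0).
#' @param bmax Maximum binding capacity, nmol per mg melanin (> 0).
#' @param n Heterogeneity index, dimensionless, in `(0, 1.5]`.
#' @param se_kd,se_bmax,se_n Optional standard errors (same units).
#'
#' @return An object of class `sips_parameters`.
#' @seealso [sips_bound()], [fit_sips()]
#' @export
#' @examples
#' sips_parameters(kd = 76, bmax = 380, n = 0.605)  # chloroquine
sips_parameters <- function(kd, bmax, n, se_kd = NA_real_, se_bmax = NA_real_,
                            se_n = NA_real_) {
  stopifnot(is.numeric(kd), is.numeric(bmax), is.numeric(n))
  if (!is.finite(kd) || kd <= 0) stop("`kd` must be positive (uM)")
  if (!is.finite(bmax) || bmax <= 0) stop("`bmax` must be positive (nmol/mg)")
  if (!is.finite(n) || n <= 0 || n > 1.5)
    stop("heterogeneity index `n` must lie in (0, 1.5]")
  structure(
    list(kd = kd, bmax = bmax, n = n,
         se_kd = as.numeric(se_kd), se_bmax = as.numeric(se_bmax),
         se_n = as.numeric(se_n)),
    class = "sips_parameters"
  )
}

#' @export
print.sips_parameters <- function(x, ...) {
  fmt <- function(v, se) {
    if (is.na(se)) sprintf("%.4g", v) else sprintf("%.4g ± %.2g", v, se)
  }
  cat("Sips isotherm parameters\n")
  cat("  Kd  :", fmt(x$kd, x$se_kd), "uM\n")
  cat("  Bmax:", fmt(x$bmax, x$se_bmax), "nmol/mg\n")
  cat("  n   :", fmt(x$n, x$se_n), "\n")
  invisible(x)
}

#' Bound amount from the Sips isotherm
#'
#' @param free_conc Free ligand concentration(s) `L`, uM.  Nonnegative.
#' @param params A [sips_parameters()] object.
#'
#' @return Bound amount(s) `Bmax L^n / (Kd^n + L^n)` in nmol/mg; exactly 0
#'   at `L = 0` (special-cased so `0^n` never arises), strictly increasing
#'   in `L`, and bounded above by `Bmax`.
#' @export
#' @examples
#' chq <- sips_parameters(kd = 76, bmax = 380, n = 0.605)
#' sips_bound(76, chq)  # half saturation: Bmax / 2
sips_bound <- function(free_conc, params) {
  stopifnot(inherits(params, "sips_parameters"))
  if (any(!is.finite(free_conc)) || any(free_conc < 0))
    stop("`free_conc` must be finite and nonnegative (uM)")
  b <- numeric(length(free_conc))
  pos <- free_conc > 0
  if (any(pos)) {
    ln <- free_conc[pos]^params$n
    b[pos] <- params$bmax * ln / (params$kd^params$n + ln)
  }
  b
}

#' Convert a melanin mass concentration to a molar concentration
#'
#' Melanin has no defined molecular formula; molar concentrations refer to
#' particles of an assumed average molecular weight (40 kDa for the
#' synthetic nanoparticles used in MST assays, giving 12.5 uM at
#' 0.5 mg/mL).
#'
#' @param mass_conc Mass concentration(s), mg/mL.  Nonnegative.
#' @param mw Particle molecular weight, kDa.  Positive; default 40.
#'
#' @return Molar concentration(s), uM: `mass_conc / mw * 1000`.
#' @export
#' @examples
#' melanin_molar_conc(0.5)        # 12.5 uM
melanin_molar_conc <- function(mass_conc, mw = 40) {
  if (any(!is.finite(mass_conc)) || any(mass_conc < 0))
    stop("`mass_conc` must be finite and nonnegative (mg/mL)")
  if (!is.finite(mw) || mw <= 0) stop("`mw` must be positive (kDa)")
  mass_conc / mw * 1000
}
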