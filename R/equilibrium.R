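#' An equilibrium (supernatant-depletion) binding dataset
#'
#' Paired control and melanin-incubated supernatant concentrations per
#' nominal ligand concentration.  The control supernatant measures the
#' total concentration actually delivered; the melanin supernatant
#' measures the free concentration at equilibrium.
#'
#' @param total_conc Control-supernatant (total) concentrations, uM.
#' @param free_conc Melanin-supernatant (free) concentrations, uM,
#'   nonnegative, same length.
#' @param melanin_conc Melanin concentration in the incubation, mg/mL
#'   (> 0; 1 mg/mL in the standard design).
#' @param replicate Optional replicate identifiers, same length.
#'
#' @return An object of class `equilibrium_dataset`: a data frame with
#'   columns `total`, `free`, `bound` (nmol/mg, via [bound_amount()]) and
#'   `replicate`, with the melanin concentration as attribute
#'   `melanin_conc`.
#' @export
equilibrium_dataset <- function(total_conc, free_conc, melanin_conc,
                                replicate = NULL) {
  stopifnot(length(total_conc) == length(free_conc))
  if (!is.finite(melanin_conc) || melanin_conc <= 0)
    stop("`melanin_conc` must be positive (mg/mL)")
  if (any(free_conc < 0)) stop("`free_conc` must be nonnegative (uM)")
  if (is.null(replicate)) replicate <- rep(1L, length(total_conc))
  df <- data.frame(
    total = as.numeric(total_conc),
    free = as.numeric(free_conc),
    bound = bound_amount(total_conc, free_conc, melanin_conc),
    replicate = replicate
  )
  structure(df, melanin_conc = as.numeric(melanin_conc),
            class = c("equilibrium_dataset", "data.frame"))
}

#' Bound amount per mg melanin from supernatant depletion
#'
#' Mass balance of the incubation: ligand missing from the
#' melanin-incubated supernatant relative to the melanin-free control is
#' bound, so `B = (total - free) / melanin_conc`, with uM * mL/mg =
#' nmol/mg.  Negative values (measurement noise at weak binding) are
#' retained rather than truncated -- truncation at zero biases the fitted
#' capacity upward -- and can be located with `which(b < 0)` downstream.
#'
#' @param total Total (control) concentration(s), uM.
#' @param free Free (melanin-incubated) concentration(s), uM.
#' @param melanin_conc Melanin concentration, mg/mL (> 0).
#'
#' @return Bound amount(s), nmol/mg.
#' @export
#' @examples
#' bound_amount(100, 30, 1)  # 70 nmol/mg
bound_amount <- function(total, free, melanin_conc) {
  if (!is.finite(melanin_conc) || melanin_conc <= 0)
    stop("`melanin_conc` must be positive (mg/mL)")
  (total - free) / melanin_conc
}

#' Fit the Sips isotherm to an equilibrium dataset
#'
#' Nonlinear least squares of `B = Bmax L^n / (Kd^n + L^n)` against the
#' free-concentration/bound-amount pairs, with the heterogeneity index
#' constrained to `(0, 1.5]`.  Free concentrations are treated as exact
#' (conventional for depletion assays).
#'
#' Because the bound amount is a difference of two measured supernatant
#' concentrations whose errors are CV-dominated, its standard deviation
#' scales with `sqrt(total^2 + free^2)` rather than with the bound amount
#' itself; the default `"measurement"` weighting uses the inverse of that
#' (delta-method) variance, which keeps the parameter standard errors
#' honest across the concentration range.  `"none"` gives the
#' conventional unweighted fit, `"replicate"` weights by inverse
#' within-replicate variance, and a log-domain fit is a further option.
#'
#' A no-binding verdict (`verdict = "no_binding"`, parameters `NA`) is
#' returned -- never an error -- when the optimizer fails or drives `Bmax`
#' into its upper bound, the behaviour weakly bound compounds such as
#' diclofenac produce.
#'
#' @param data An [equilibrium_dataset()], or any data frame with `free`
#'   and `bound` columns (`total` is needed for `"measurement"` weighting,
#'   `replicate` for `"replicate"` weighting).
#' @param weighting `"measurement"` (default; falls back to `"none"` with
#'   a message when no `total` column is present), `"none"`, or
#'   `"replicate"`.
#' @param log_domain Fit `log(B)` instead of `B` (drops nonpositive bound
#'   amounts).
#' @param n_bounds Constraint on the heterogeneity index.
#'
#' @return An object of class `sips_fit`: `params`
#'   ([sips_parameters()] with standard errors) or `NULL`, `verdict`
#'   (`"fitted"` or `"no_binding"`), `n_negative_bound`, and the `nls`
#'   object in `fit`.
#' @export
#' @examples
#' pap <- sips_parameters(kd = 66, bmax = 66, n = 0.715)
#' L <- 250 / 2^(0:10)
#' d <- data.frame(free = L, bound = sips_bound(L, pap))
#' fit_sips(d)
fit_sips <- function(data, weighting = c("measurement", "none", "replicate"),
                     log_domain = FALSE, n_bounds = c(1e-3, 1.5)) {
  weighting <- match.arg(weighting)
  df <- as.data.frame(data)
  df <- df[, intersect(c("total", "free", "bound", "replicate"), names(df))]
  stopifnot(all(c("free", "bound") %in% names(df)))
  df <- df[is.finite(df$free) & is.finite(df$bound), ]
  if (length(unique(df$free)) < 6L ||
      diff(log10(range(df$free[df$free > 0]))) < 2)
    warning("fewer than 6 free concentrations spanning < 2 orders of ",
            "magnitude; Sips parameters may be poorly constrained")
  n_neg <- sum(df$bound < 0)

  if (weighting == "measurement" && !"total" %in% names(df)) {
    message("no `total` column: falling back to unweighted fit")
    weighting <- "none"
  }
  w <- switch(weighting,
    none = rep(1, nrow(df)),
    measurement = 1 / (df$total^2 + df$free^2),
    replicate = {
      grp <- factor(signif(df$free, 3))
      v <- tapply(df$bound, grp, stats::var)
      v[!is.finite(v) | v <= 0] <- min(v[is.finite(v) & v > 0],
                                       na.rm = TRUE)
      as.numeric(1 / v[as.character(grp)])
    })
  w <- w / mean(w)

  b_scale <- max(abs(df$bound))
  bmax_hi <- 100 * b_scale
  start <- list(kd = stats::median(df$free[df$free > 0]),
                bmax = 1.2 * max(df$bound, b_scale * 0.01),
                n = 1)
  fit_df <- df
  if (log_domain) {
    fit_df <- df[df$bound > 0 & df$free > 0, ]
    w <- w[df$bound > 0 & df$free > 0]
  }

  form <- if (log_domain)
    log(bound) ~ log(bmax * free^n / (kd^n + free^n))
  else
    bound ~ bmax * ifelse(free > 0, free^n / (kd^n + free^n), 0)

  fit <- tryCatch(
    minpack.lm::nlsLM(
      form, data = fit_df, start = start, weights = w,
      lower = c(kd = 1e-6, bmax = 1e-9, n = n_bounds[1]),
      upper = c(kd = 1e9, bmax = bmax_hi, n = n_bounds[2]),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    ),
    error = function(e) e
  )

  if (inherits(fit, "error"))
    return(new_sips_fit(NULL, "no_binding", n_neg,
                        diagnostics = conditionMessage(fit)))

  est <- stats::coef(fit)
  if (est[["bmax"]] >= bmax_hi * (1 - 1e-6))
    return(new_sips_fit(NULL, "no_binding", n_neg,
                        diagnostics = "Bmax at upper bound", fit = fit))

  se <- tryCatch(sqrt(diag(stats::vcov(fit))),
                 error = function(e) stats::setNames(rep(NA_real_, 3),
                                                     names(est)))
  params <- sips_parameters(kd = est[["kd"]], bmax = est[["bmax"]],
                            n = est[["n"]], se_kd = se[["kd"]],
                            se_bmax = se[["bmax"]], se_n = se[["n"]])
  new_sips_fit(params, "fitted", n_neg, fit = fit)
}

new_sips_fit <- function(params, verdict, n_negative_bound,
                         diagnostics = NULL, fit = NULL) {
  structure(
    list(params = params, verdict = verdict,
         n_negative_bound = n_negative_bound,
         diagnostics = diagnostics, fit = fit),
    class = "sips_fit"
  )
}

#' @export
print.sips_fit <- function(x, ...) {
  cat("Sips isotherm fit:", x$verdict, "\n")
  if (!is.null(x$params)) print(x$params)
  if (x$n_negative_bound > 0)
    cat("  (", x$n_negative_bound, "negative bound amounts retained )\n")
  if (!is.null(x$diagnostics)) cat(" ", x$diagnostics, "\n")
  invisible(x)
}

#' @export
as.data.frame.sips_fit <- function(x, ...) {
  p <- x$params
  data.frame(
    kd_uM = if (is.null(p)) NA_real_ else p$kd,
    se_kd = if (is.null(p)) NA_real_ else p$se_kd,
    bmax_nmol_mg = if (is.null(p)) NA_real_ else p$bmax,
    se_bmax = if (is.null(p)) NA_real_ else p$se_bmax,
    n = if (is.null(p)) NA_real_ else p$n,
    se_n = if (is.null(p)) NA_real_ else p$se_n,
    verdict = x$verdict,
    n_negative_bound = x$n_negative_bound
  )
}

#' Target capacity of melanin for a ligand
#'
#' The maximal binding capacity expressed as a molar concentration in an
#' assay: `Bmax` (nmol/mg) times the melanin mass concentration (mg/mL)
#' gives nmol/mL = uM.
#'
#' @param params A [sips_parameters()] object.
#' @param melanin_conc Melanin concentration, mg/mL.
#'
#' @return Target capacity, uM.
#' @export
#' @examples
#' sips_target_capacity(sips_parameters(46, 112, 0.64), 0.5)  # 56 uM
sips_target_capacity <- function(params, melanin_conc) {
  stopifnot(inherits(params, "sips_parameters"))
  if (any(melanin_conc < 0)) stop("`melanin_conc` must be nonnegative")
  params$bmax * melanin_conc
}

#' Read an equilibrium-assay CSV
#'
#' Columns `nominal_conc_uM`, `control_supernatant_uM`,
#' `melanin_supernatant_uM`, and optionally `replicate`.
#'
#' @param path CSV path.
#' @param melanin_conc Melanin concentration in the incubation, mg/mL.
#' @return An [equilibrium_dataset()].
#' @export
read_equilibrium_csv <- function(path, melanin_conc) {
  df <- utils::read.csv(path)
  need <- c("nominal_conc_uM", "control_supernatant_uM",
            "melanin_supernatant_uM")
  if (!all(need %in% names(df)))
    stop("expected columns: ", paste(need, collapse = ", "))
  equilibrium_dataset(
    total_conc = df$control_supernatant_uM,
    free_conc = df$melanin_supernatant_uM,
    melanin_conc = melanin_conc,
    replicate = if ("replicate" %in% names(df)) df$replicate else NULL
  )
}
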