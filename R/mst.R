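#' A single MST capillary trace
#'
#' Time-resolved fluorescence of one capillary at one ligand concentration.
#' The infrared laser switches on at `laser_on_time`; fluorescence before
#' that instant is the "cold" (initial) signal, fluorescence after it
#' reflects thermophoretic depletion in the heated spot.
#'
#' @param times Acquisition times, seconds, strictly increasing (typically
#'   a 30 s span).
#' @param fluorescence Fluorescence counts, same length as `times`,
#'   nonnegative.
#' @param ligand_conc Total ligand concentration in the capillary, uM
#'   (0 for the melanin-only reference).
#' @param laser_on_time Laser-on instant, seconds, within the time span.
#'
#' @return An object of class `mst_trace`.
#' @export
mst_trace <- function(times, fluorescence, ligand_conc, laser_on_time) {
  stopifnot(is.numeric(times), is.numeric(fluorescence),
            length(times) == length(fluorescence), length(times) >= 2L)
  if (any(diff(times) <= 0)) stop("`times` must be strictly increasing")
  if (any(fluorescence < 0)) stop("`fluorescence` must be nonnegative")
  if (ligand_conc < 0) stop("`ligand_conc` must be nonnegative (uM)")
  if (laser_on_time < min(times) || laser_on_time > max(times))
    stop("`laser_on_time` must lie within the acquisition span")
  structure(
    list(times = as.numeric(times), fluorescence = as.numeric(fluorescence),
         ligand_conc = as.numeric(ligand_conc),
         laser_on_time = as.numeric(laser_on_time)),
    class = "mst_trace"
  )
}

#' An MST dilution series
#'
#' A set of capillary traces sharing one melanin target concentration: the
#' unit of Kd fitting.  Repeated ligand concentrations are treated as
#' replicate capillaries and pooled in the fit.
#'
#' @param traces List of [mst_trace()] objects with positive ligand
#'   concentrations.
#' @param target_conc Molar melanin concentration in every capillary, uM
#'   (12.5 uM at 0.5 mg/mL nanoparticles).
#' @param reference_trace Optional melanin-only trace (`ligand_conc = 0`).
#'
#' @return An object of class `mst_series`.
#' @export
mst_series <- function(traces, target_conc, reference_trace = NULL) {
  stopifnot(is.list(traces), length(traces) >= 2L,
            all(vapply(traces, inherits, logical(1), "mst_trace")))
  concs <- vapply(traces, `[[`, numeric(1), "ligand_conc")
  if (any(concs <= 0))
    stop("all series traces need positive ligand concentrations; ",
         "pass the melanin-only capillary as `reference_trace`")
  if (!is.finite(target_conc) || target_conc <= 0)
    stop("`target_conc` must be positive (uM)")
  if (!is.null(reference_trace)) {
    stopifnot(inherits(reference_trace, "mst_trace"))
    if (reference_trace$ligand_conc != 0)
      stop("`reference_trace` must have ligand_conc = 0")
  }
  structure(
    list(traces = traces, target_conc = as.numeric(target_conc),
         reference_trace = reference_trace),
    class = "mst_series"
  )
}

all_traces <- function(series) {
  c(series$traces, if (!is.null(series$reference_trace))
    list(series$reference_trace))
}

region_mean <- function(trace, region) {
  sel <- trace$times >= region[1] & trace$times <= region[2]
  if (!any(sel)) stop("region [", region[1], ", ", region[2],
                      "] s contains no samples")
  mean(trace$fluorescence[sel])
}

#' Default cold region of a trace
#'
#' The second immediately preceding laser-on (clipped to the start of the
#' acquisition), matching the instrument convention of referencing
#' thermophoresis to the late pre-heating signal.
#'
#' @param trace An [mst_trace()].
#' @param width Window width, seconds.
#' @return `c(start, end)` in seconds.
#' @export
default_cold_region <- function(trace, width = 1) {
  c(max(min(trace$times), trace$laser_on_time - width), trace$laser_on_time)
}

#' Normalized fluorescence of a trace
#'
#' Fnorm is the mean fluorescence in a post-heating ("hot") window divided
#' by the mean in a pre-heating ("cold") window.  A flat trace gives
#' exactly 1; thermophoretic depletion of the fluorescent target pushes it
#' below 1.
#'
#' @param trace An [mst_trace()].
#' @param cold,hot Regions `c(start, end)` in seconds; the cold region must
#'   end at or before laser-on and the hot region start at or after it.
#'
#' @return The dimensionless ratio mean(hot)/mean(cold).
#' @export
#' @examples
#' tr <- mst_trace(0:29, c(rep(1000, 5), rep(950, 25)), 10, laser_on_time = 5)
#' compute_fnorm(tr, cold = c(0, 5), hot = c(20, 25))  # 0.95
compute_fnorm <- function(trace, cold, hot) {
  stopifnot(inherits(trace, "mst_trace"),
            length(cold) == 2L, length(hot) == 2L)
  if (cold[2] > trace$laser_on_time)
    stop("cold region must lie entirely before laser-on")
  if (hot[1] < trace$laser_on_time)
    stop("hot region must lie entirely after laser-on")
  cold_mean <- region_mean(trace, cold)
  if (cold_mean <= 0)
    stop("degenerate trace: nonpositive cold-region fluorescence")
  region_mean(trace, hot) / cold_mean
}

# Fnorm of every trace in a series for one hot window, plus a noise scale:
# the mean within-concentration sd of Fnorm when replicate capillaries
# exist, otherwise the mean detrended-residual standard error propagated
# through the ratio.
series_fnorm <- function(series, cold, hot) {
  traces <- all_traces(series)
  fn <- vapply(traces, compute_fnorm, numeric(1), cold = cold, hot = hot)
  conc <- vapply(traces, `[[`, numeric(1), "ligand_conc")
  list(conc = conc, fnorm = fn)
}

window_noise <- function(traces, fn, conc, cold, hot) {
  reps <- split(fn, conc)
  n_rep <- vapply(reps, length, integer(1))
  if (any(n_rep >= 2L)) {
    sds <- vapply(reps[n_rep >= 2L], stats::sd, numeric(1))
    return(mean(sds))
  }
  # no replicates: detrended-residual standard error of the window means,
  # hot and cold contributions combined, per trace
  win_se <- function(tr, region) {
    sel <- tr$times >= region[1] & tr$times <= region[2]
    f <- tr$fluorescence[sel]
    t <- tr$times[sel]
    if (length(f) < 3L) return(NA_real_)
    stats::sd(stats::residuals(stats::lm(f ~ t))) / sqrt(length(f))
  }
  per_trace <- vapply(traces, function(tr) {
    cm <- region_mean(tr, cold)
    sqrt(win_se(tr, hot)^2 + win_se(tr, cold)^2) / cm
  }, numeric(1))
  mean(per_trace, na.rm = TRUE)
}

#' Select the hot region of an MST series
#'
#' Scans sliding post-laser windows (`width` s wide, stepped by `step` s)
#' and scores each by signal-to-noise ratio: the concentration-trend span
#' of Fnorm (mean response at the highest concentrations minus the mean at
#' the lowest, which tracks the thermophoretic amplitude while being
#' nearly insensitive to individual noise realizations) divided by the
#' Fnorm noise (within-replicate sd when replicate capillaries exist,
#' detrended residual error otherwise).  The window with the highest ratio
#' is returned; if even that falls short of `min_snr` it is flagged
#' `below_threshold`.
#'
#' @param series An [mst_series()].
#' @param min_snr Minimum acceptable signal-to-noise ratio (default 5).
#' @param width,step Window width and step, seconds.
#' @param cold Cold region; defaults to the second before laser-on.
#'
#' @return A list with `hot` (the window, seconds), `cold`, `snr`, and
#'   `below_threshold`.
#' @export
select_hot_region <- function(series, min_snr = 5, width = 1, step = 0.5,
                              cold = NULL) {
  stopifnot(inherits(series, "mst_series"))
  traces <- all_traces(series)
  if (length(unique(vapply(series$traces, `[[`, numeric(1),
                           "ligand_conc"))) < 2L)
    stop("need at least 2 distinct ligand concentrations")
  t0 <- traces[[1]]$laser_on_time
  t_end <- min(vapply(traces, function(tr) max(tr$times), numeric(1)))
  if (t_end <= t0) stop("no post-laser samples")
  starts <- seq(t0, t_end - width, by = step)
  if (!length(starts)) starts <- t0
  if (is.null(cold)) cold <- default_cold_region(traces[[1]])

  best <- NULL
  for (s in starts) {
    hot <- c(s, min(s + width, t_end))
    sf <- series_fnorm(series, cold, hot)
    mu <- tapply(sf$fnorm, sf$conc, mean)
    mu <- mu[order(as.numeric(names(mu)))]
    k <- max(1L, min(3L, length(mu) %/% 2L))
    span <- abs(mean(utils::tail(mu, k)) - mean(utils::head(mu, k)))
    noise <- window_noise(traces, sf$fnorm, sf$conc, cold, hot)
    snr <- if (!is.finite(noise) || noise <= 0) {
      if (span > 0) Inf else 0
    } else span / noise
    if (is.null(best) || snr > best$snr)
      best <- list(hot = hot, cold = cold, snr = snr,
                   below_threshold = snr < min_snr)
  }
  best
}

#' Detect the analysis mode of an MST series
#'
#' Some ligands change the raw pre-heating fluorescence of melanin in a
#' concentration-dependent way; for those, the dose-response is read from
#' the cold-region counts ("initial-fluorescence mode") rather than from
#' thermophoresis.  The trend test is deliberately conservative: the mode
#' switches only when the Spearman correlation between cold counts and log
#' concentration exceeds `rho_threshold` in absolute value *and* the
#' relative span of the cold counts exceeds `span_threshold`, so random
#' jitter or slow drift does not flip the mode.
#'
#' @param series An [mst_series()].
#' @param rho_threshold Absolute Spearman correlation required (default 0.7).
#' @param span_threshold Minimum relative span (max-min)/mean of cold
#'   counts (default 0.1).
#' @param cold Cold region; defaults to the second before laser-on.
#'
#' @return `"initial_fluorescence"` or `"mst"`.
#' @export
detect_mode <- function(series, rho_threshold = 0.7, span_threshold = 0.1,
                        cold = NULL) {
  stopifnot(inherits(series, "mst_series"))
  if (is.null(cold)) cold <- default_cold_region(series$traces[[1]])
  conc <- vapply(series$traces, `[[`, numeric(1), "ligand_conc")
  counts <- vapply(series$traces, region_mean, numeric(1), region = cold)
  mu <- tapply(counts, conc, mean)
  lc <- log10(as.numeric(names(mu)))
  if (length(mu) < 3L) return("mst")
  if (stats::sd(mu) == 0) return("mst")   # perfectly constant cold counts
  rho <- spearman_rho(lc, as.numeric(mu))
  span <- (max(mu) - min(mu)) / mean(mu)
  if (is.finite(rho) && abs(rho) > rho_threshold && span > span_threshold)
    "initial_fluorescence" else "mst"
}

#' Fit a dissociation constant to extracted dose-response points
#'
#' Core nonlinear least-squares fit of the ligand-depletion model
#' ([depletion_fraction_bound()]) with free parameters `unbound`, `bound`
#' and `kd` and the target concentration fixed.  `kd` is box-constrained to
#' `kd_bounds` and initialized at the geometric mean of the tested
#' concentrations; the signals are initialized from the low- and
#' high-concentration ends of the response.  The 68% confidence half-width
#' is the asymptotic standard error of `kd` from the least-squares
#' covariance (1 sigma).
#'
#' @param conc Total ligand concentrations, uM (replicate points allowed;
#'   a 0 uM reference point is allowed and pins the unbound signal).
#' @param response Measured responses (Fnorm or raw counts), same length.
#' @param target_conc Fixed target concentration, uM.
#' @param kd_bounds Box constraint on `kd`, uM.
#'
#' @return An object of class `mst_fit` (see [fit_kd()]); on
#'   non-convergence a fit-failure result with `converged = FALSE` and the
#'   condition message in `diagnostics`, never an error.
#' @export
fit_kd_points <- function(conc, response, target_conc,
                          kd_bounds = c(1e-3, 1e6)) {
  stopifnot(length(conc) == length(response), all(conc >= 0))
  pos <- conc > 0
  if (length(unique(conc[pos])) < 3L)
    stop("need at least 3 distinct positive ligand concentrations")
  if (length(unique(conc[pos])) < 6L ||
      diff(log10(range(conc[pos]))) < 2)
    warning("fewer than 6 concentrations spanning < 2 orders of magnitude; ",
            "the Kd estimate may be poorly constrained")
  kd0 <- exp(mean(log(conc[pos])))
  # low-concentration end estimates the unbound signal
  ord <- order(conc)
  k <- max(2L, ceiling(length(conc) / 4))
  u0 <- mean(response[ord][seq_len(k)])
  b0 <- mean(response[rev(ord)][seq_len(k)])
  if (u0 == b0) b0 <- u0 * (1 + 1e-3) + 1e-12
  scale <- max(abs(response))
  df <- data.frame(conc = conc, response = response)

  fit <- tryCatch(
    minpack.lm::nlsLM(
      response ~ unbound + (bound - unbound) *
        depletion_occupancy(conc, kd, target_conc),
      data = df,
      start = list(unbound = u0, bound = b0, kd = kd0),
      lower = c(unbound = -Inf, bound = -Inf, kd = kd_bounds[1]),
      upper = c(unbound = Inf, bound = Inf, kd = kd_bounds[2]),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    ),
    error = function(e) e
  )

  if (inherits(fit, "error")) {
    return(new_mst_fit(kd = NA_real_, ci68 = NA_real_,
                       unbound = NA_real_, bound = NA_real_,
                       converged = FALSE, flags = "fit_failed",
                       diagnostics = conditionMessage(fit),
                       data = df, target_conc = target_conc))
  }

  est <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))),
                 error = function(e) rep(NA_real_, 3))
  names(se) <- names(est)
  amp <- est[["bound"]] - est[["unbound"]]
  v <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  se_amp <- if (!is.null(v))
    sqrt(v["bound", "bound"] + v["unbound", "unbound"] -
           2 * v["bound", "unbound"]) else NA_real_

  flags <- character(0)
  resid_sd <- stats::sd(stats::residuals(fit))
  # flat response: amplitude indistinguishable from zero -> no binding
  if ((is.finite(se_amp) && abs(amp) < 2 * se_amp) ||
      abs(amp) < 1e-8 * scale)
    flags <- c(flags, "no_binding")
  kd_hat <- est[["kd"]]
  ci68 <- se[["kd"]]
  if (is.finite(ci68) && ci68 > kd_hat) flags <- c(flags, "wide_ci")
  if (kd_hat <= kd_bounds[1] * (1 + 1e-6) ||
      kd_hat >= kd_bounds[2] * (1 - 1e-6))
    flags <- c(flags, "kd_at_bound")

  new_mst_fit(kd = kd_hat, ci68 = ci68,
              unbound = est[["unbound"]], bound = est[["bound"]],
              converged = TRUE, flags = flags, diagnostics = NULL,
              data = df, target_conc = target_conc, fit = fit)
}

new_mst_fit <- function(kd, ci68, unbound, bound, converged, flags,
                        diagnostics, data, target_conc, fit = NULL,
                        mode = NA_character_, hot_region = c(NA, NA),
                        cold_region = c(NA, NA), snr = NA_real_) {
  structure(
    list(kd = kd, ci68 = ci68, unbound = unbound, bound = bound,
         mode = mode, hot_region = hot_region, cold_region = cold_region,
         snr = snr, converged = converged, flags = flags,
         diagnostics = diagnostics, data = data,
         target_conc = target_conc, fit = fit),
    class = "mst_fit"
  )
}

#' Fit a dissociation constant to an MST dilution series
#'
#' Full trace workflow: pick the analysis mode (thermophoresis vs
#' initial fluorescence, [detect_mode()]), select the hot region by
#' signal-to-noise ([select_hot_region()]), reduce every capillary to one
#' dose-response point (Fnorm in MST mode, cold-region raw counts in
#' initial-fluorescence mode), and fit the ligand-depletion model with
#' [fit_kd_points()].  Replicate capillaries are fitted jointly (pooled
#' residuals), preserving the error structure behind the 68% confidence
#' interval.
#'
#' @param series An [mst_series()].
#' @param mode `"auto"` (default), `"mst"`, or `"initial_fluorescence"`.
#' @param min_snr Signal-to-noise threshold for hot-region selection.
#' @param kd_bounds Box constraint on `kd`, uM.
#' @param ... Passed to [select_hot_region()].
#'
#' @return An object of class `mst_fit`: `kd` and `ci68` (uM), the fitted
#'   `unbound`/`bound` signals, `mode`, `hot_region`/`cold_region`
#'   (seconds), `snr`, a `converged` flag, and `flags` among
#'   `"no_binding"`, `"wide_ci"`, `"kd_at_bound"`, `"low_snr"`,
#'   `"fit_failed"`.
#' @export
#' @examples
#' cfg <- synth_config(true_kd = 30, noise_cv = 0, seed = 1)
#' fit_kd(generate_mst_series(cfg)$series)
fit_kd <- function(series, mode = c("auto", "mst", "initial_fluorescence"),
                   min_snr = 5, kd_bounds = c(1e-3, 1e6), ...) {
  stopifnot(inherits(series, "mst_series"))
  mode <- match.arg(mode)
  if (mode == "auto") mode <- detect_mode(series)
  cold <- default_cold_region(series$traces[[1]])
  traces <- all_traces(series)
  conc <- vapply(traces, `[[`, numeric(1), "ligand_conc")

  if (mode == "mst") {
    sel <- select_hot_region(series, min_snr = min_snr, cold = cold, ...)
    response <- vapply(traces, compute_fnorm, numeric(1),
                       cold = sel$cold, hot = sel$hot)
    hot <- sel$hot
    snr <- sel$snr
    low_snr <- sel$below_threshold
  } else {
    response <- vapply(traces, region_mean, numeric(1), region = cold)
    hot <- c(NA_real_, NA_real_)
    snr <- NA_real_
    low_snr <- FALSE
  }

  out <- fit_kd_points(conc, response, series$target_conc,
                       kd_bounds = kd_bounds)
  out$mode <- mode
  out$hot_region <- hot
  out$cold_region <- cold
  out$snr <- snr
  if (isTRUE(low_snr)) out$flags <- c(out$flags, "low_snr")
  out
}

#' @export
print.mst_fit <- function(x, ...) {
  cat("MST Kd fit (ligand-depletion model)\n")
  cat("  mode      :", x$mode, "\n")
  if (!x$converged) {
    cat("  fit failed:", x$diagnostics, "\n")
    return(invisible(x))
  }
  cat(sprintf("  Kd        : %.4g ± %.2g uM (68%% CI)\n", x$kd, x$ci68))
  cat(sprintf("  signals   : unbound %.4g, bound %.4g\n",
              x$unbound, x$bound))
  if (!is.na(x$snr)) cat(sprintf("  SNR       : %.3g\n", x$snr))
  if (length(x$flags)) cat("  flags     :", paste(x$flags, collapse = ", "),
                           "\n")
  invisible(x)
}

#' @export
as.data.frame.mst_fit <- function(x, ...) {
  data.frame(kd_uM = x$kd, ci68_uM = x$ci68, mode = x$mode,
             unbound = x$unbound, bound = x$bound,
             hot_start_s = x$hot_region[1], hot_end_s = x$hot_region[2],
             cold_start_s = x$cold_region[1], cold_end_s = x$cold_region[2],
             snr = x$snr, converged = x$converged,
             flags = paste(x$flags, collapse = ";"))
}

#' Read an MST trace file into a series
#'
#' Long-format CSV with columns `capillary_id`, `ligand_conc_uM`, `time_s`,
#' `fluorescence`, one row per sample.  The capillary with
#' `ligand_conc_uM = 0` (if present) becomes the reference trace.
#'
#' @param path CSV path.
#' @param target_conc Molar melanin concentration, uM.
#' @param laser_on_time Laser-on instant, seconds.
#'
#' @return An [mst_series()].
#' @export
read_mst_csv <- function(path, target_conc, laser_on_time) {
  df <- utils::read.csv(path)
  need <- c("capillary_id", "ligand_conc_uM", "time_s", "fluorescence")
  if (!all(need %in% names(df)))
    stop("expected columns: ", paste(need, collapse = ", "))
  traces <- lapply(split(df, df$capillary_id), function(d) {
    d <- d[order(d$time_s), ]
    mst_trace(d$time_s, d$fluorescence, d$ligand_conc_uM[1], laser_on_time)
  })
  conc <- vapply(traces, `[[`, numeric(1), "ligand_conc")
  ref <- if (any(conc == 0)) traces[[which(conc == 0)[1]]]
  mst_series(traces[conc > 0], target_conc, reference_trace = ref)
}

#' Read pre-extracted dose-response points
#'
#' CSV with columns `ligand_conc_uM`, `response`, and optionally
#' `replicate`; the direct input to [fit_kd_points()].
#'
#' @param path CSV path.
#' @return A data frame with columns `conc`, `response`, `replicate`.
#' @export
read_dose_response_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("ligand_conc_uM", "response")
  if (!all(need %in% names(df)))
    stop("expected columns: ", paste(need, collapse = ", "))
  data.frame(conc = df$ligand_conc_uM, response = df$response,
             replicate = if ("replicate" %in% names(df)) df$replicate else 1L)
}
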