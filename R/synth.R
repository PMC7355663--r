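#' Configuration for the synthetic-assay generator
#'
#' Bundles the ground-truth binding parameters and instrument settings the
#' generator uses to emulate both assays.  Defaults mirror the standard
#' screening design: a 16-step twofold dilution from 500 uM, 12.5 uM molar
#' melanin (0.5 mg/mL at 40 kDa) in the MST capillaries, 30 s acquisition
#' with the laser on at 5 s, and 3% multiplicative measurement noise.
#'
#' @param true_kd Ground-truth dissociation constant, uM.
#' @param true_bmax Ground-truth capacity, nmol/mg (Sips route).
#' @param true_n Ground-truth heterogeneity index.
#' @param target_conc Molar melanin concentration in MST capillaries, uM.
#' @param conc_series Ligand dilution series, uM, sorted descending.
#' @param noise_cv Coefficient of variation of the measurement noise.
#' @param baseline Cold-region fluorescence of the melanin target, counts.
#' @param amplitude Fractional thermophoretic depletion at full occupancy.
#' @param tau Thermophoresis time constant, seconds.
#' @param laser_on Laser-on instant, seconds.
#' @param duration Acquisition span, seconds.
#' @param dt Sampling interval, seconds.
#' @param cold_amplitude Fractional change of the *initial* fluorescence at
#'   full occupancy; nonzero values emulate ligands detected in
#'   initial-fluorescence mode.
#' @param noise_model `"lognormal"` (multiplicative, the default: counts
#'   and LC-measured concentrations are positive and CV-dominated) or
#'   `"additive"`.
#' @param seed Integer seed; mandatory, every draw flows from it.
#'
#' @return An object of class `synth_config`.
#' @export
#' @examples
#' synth_config(true_kd = 30, seed = 1)
synth_config <- function(true_kd = 30, true_bmax = 100, true_n = 0.7,
                         target_conc = 12.5,
                         conc_series = 500 / 2^(0:15),
                         noise_cv = 0.03, baseline = 1000,
                         amplitude = 0.3, tau = 2.5, laser_on = 5,
                         duration = 30, dt = 0.25, cold_amplitude = 0,
                         noise_model = c("lognormal", "additive"),
                         seed) {
  if (missing(seed)) stop("`seed` is mandatory for reproducibility")
  noise_model <- match.arg(noise_model)
  stopifnot(true_kd > 0, true_bmax > 0, true_n > 0, target_conc > 0,
            all(conc_series > 0), noise_cv >= 0, baseline > 0,
            amplitude > 0, tau > 0, laser_on > 0, duration > laser_on,
            dt > 0)
  if (is.unsorted(rev(conc_series)))
    stop("`conc_series` must be sorted descending")
  structure(
    list(true_kd = true_kd, true_bmax = true_bmax, true_n = true_n,
         target_conc = target_conc, conc_series = conc_series,
         noise_cv = noise_cv, baseline = baseline, amplitude = amplitude,
         tau = tau, laser_on = laser_on, duration = duration, dt = dt,
         cold_amplitude = cold_amplitude, noise_model = noise_model,
         seed = as.integer(seed)),
    class = "synth_config"
  )
}

noise_factor <- function(n, cv, model) {
  if (cv == 0) return(rep(1, n))
  if (model == "lognormal") {
    sdlog <- sqrt(log(1 + cv^2))
    exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))   # mean exactly 1
  } else {
    1 + stats::rnorm(n, 0, cv)
  }
}

#' Generate a synthetic MST dilution series
#'
#' For each ligand concentration the occupied-target fraction `fb` comes
#' from the depletion model at the configured truth; the trace is a flat
#' baseline until laser-on, then a single-exponential thermophoretic decay
#' `baseline * (1 - amplitude * fb * (1 - exp(-(t - t_on)/tau)))`, with
#' multiplicative noise on every sample.  A nonzero `cold_amplitude`
#' additionally scales the pre-heating baseline by `(1 - cold_amplitude *
#' fb)`, producing the ligand-induced initial-fluorescence signature.  A
#' melanin-only reference capillary is always included.
#'
#' @param cfg A [synth_config()].
#' @param n_replicates Replicate capillaries per concentration.
#'
#' @return A list with `series` (an [mst_series()]) and `truth` (the
#'   configured parameters plus the per-concentration occupancy `fb` and
#'   the noise-free Fnorm amplitude).
#' @export
#' @examples
#' out <- generate_mst_series(synth_config(true_kd = 30, seed = 7))
#' fit_kd(out$series)
generate_mst_series <- function(cfg, n_replicates = 1) {
  stopifnot(inherits(cfg, "synth_config"), n_replicates >= 1)
  withr::with_seed(cfg$seed, {
    times <- seq(0, cfg$duration, by = cfg$dt)
    post <- pmax(times - cfg$laser_on, 0)
    decay <- (1 - exp(-post / cfg$tau)) * (times >= cfg$laser_on)
    make_trace <- function(conc) {
      fb <- if (conc > 0)
        depletion_occupancy(conc, cfg$true_kd, cfg$target_conc) else 0
      base <- cfg$baseline * (1 - cfg$cold_amplitude * fb)
      clean <- base * (1 - cfg$amplitude * fb * decay)
      noisy <- clean * noise_factor(length(clean), cfg$noise_cv,
                                    cfg$noise_model)
      mst_trace(times, pmax(noisy, 0), conc, cfg$laser_on)
    }
    traces <- lapply(rep(cfg$conc_series, each = n_replicates), make_trace)
    ref <- make_trace(0)
    fb <- depletion_occupancy(cfg$conc_series, cfg$true_kd, cfg$target_conc)
    list(
      series = mst_series(traces, cfg$target_conc, reference_trace = ref),
      truth = list(true_kd = cfg$true_kd, target_conc = cfg$target_conc,
                   conc = cfg$conc_series, fb = fb,
                   fnorm_amplitude = cfg$amplitude,
                   cold_amplitude = cfg$cold_amplitude,
                   noise_cv = cfg$noise_cv, seed = cfg$seed)
    )
  })
}

#' Generate a synthetic equilibrium-binding dataset
#'
#' For each total concentration in the series the true free concentration
#' is obtained from the same mass balance the prediction module solves
#' ([fraction_unbound_sips()]) at the configured Sips truth; control and
#' melanin supernatant measurements are then emitted with multiplicative
#' noise.  With `melanin_conc = 0` the free concentrations equal the
#' totals and a plain data frame (no bound amounts) is returned.
#'
#' @param cfg A [synth_config()]; `true_kd`, `true_bmax`, `true_n` define
#'   the isotherm.
#' @param melanin_conc Melanin concentration in the incubation, mg/mL.
#' @param n_replicates Replicates per concentration (3 in the standard
#'   design).
#' @param conc_series Total-concentration series, uM; defaults to
#'   `cfg$conc_series`.
#'
#' @return A list with `data` (an [equilibrium_dataset()]) and `truth`
#'   (the Sips parameters and noise-free free concentrations).
#' @export
#' @examples
#' cfg <- synth_config(true_kd = 66, true_bmax = 66, true_n = 0.715,
#'                     noise_cv = 0, seed = 3)
#' fit_sips(generate_equilibrium_dataset(cfg)$data)
generate_equilibrium_dataset <- function(cfg, melanin_conc = 1,
                                         n_replicates = 3,
                                         conc_series = NULL) {
  stopifnot(inherits(cfg, "synth_config"), melanin_conc >= 0)
  if (is.null(conc_series)) conc_series <- cfg$conc_series
  params <- sips_parameters(cfg$true_kd, cfg$true_bmax, cfg$true_n)
  free_true <- vapply(conc_series, function(total) {
    if (melanin_conc == 0) return(total)
    fraction_unbound_sips(params, melanin_conc, total) / 100 * total
  }, numeric(1))

  withr::with_seed(cfg$seed, {
    total <- rep(conc_series, each = n_replicates)
    free <- rep(free_true, each = n_replicates)
    replicate <- rep(seq_len(n_replicates), times = length(conc_series))
    control_meas <- total * noise_factor(length(total), cfg$noise_cv,
                                         cfg$noise_model)
    free_meas <- free * noise_factor(length(free), cfg$noise_cv,
                                     cfg$noise_model)
    data <- if (melanin_conc == 0) {
      data.frame(total = control_meas, free = free_meas,
                 replicate = replicate)
    } else {
      equilibrium_dataset(control_meas, free_meas, melanin_conc,
                          replicate = replicate)
    }
    list(data = data,
         truth = list(params = params, total = conc_series,
                      free = free_true, melanin_conc = melanin_conc,
                      noise_cv = cfg$noise_cv, seed = cfg$seed))
  })
}

#' Write a synthetic MST series to the package's CSV dialect
#'
#' Emits the long format [read_mst_csv()] reads; if `jsonlite` is
#' installed and `truth` is supplied, a `<path>.truth.json` sidecar with
#' the ground truth is written alongside.
#'
#' @param series An [mst_series()].
#' @param path Output CSV path.
#' @param truth Optional ground-truth list (from [generate_mst_series()]).
#' @return `path`, invisibly.
#' @export
write_mst_csv <- function(series, path, truth = NULL) {
  traces <- all_traces(series)
  rows <- lapply(seq_along(traces), function(i) {
    tr <- traces[[i]]
    data.frame(capillary_id = i, ligand_conc_uM = tr$ligand_conc,
               time_s = tr$times, fluorescence = tr$fluorescence)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  if (!is.null(truth) && requireNamespace("jsonlite", quietly = TRUE))
    jsonlite::write_json(truth, paste0(path, ".truth.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a synthetic equilibrium dataset to the package's CSV dialect
#'
#' Emits the columns [read_equilibrium_csv()] reads, with an optional
#' ground-truth JSON sidecar as in [write_mst_csv()].
#'
#' @param data An [equilibrium_dataset()].
#' @param path Output CSV path.
#' @param truth Optional ground-truth list.
#' @return `path`, invisibly.
#' @export
write_equilibrium_csv <- function(data, path, truth = NULL) {
  df <- data.frame(nominal_conc_uM = data$total,
                   control_supernatant_uM = data$total,
                   melanin_supernatant_uM = data$free,
                   replicate = data$replicate)
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(truth) && requireNamespace("jsonlite", quietly = TRUE))
    jsonlite::write_json(truth, paste0(path, ".truth.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(path)
}
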