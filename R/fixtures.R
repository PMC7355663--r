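#' Published melanin-binding parameters of the 13-compound screening set
#'
#' MST dissociation constants (with 68% confidence half-widths and the
#' analysis mode used) and Sips isotherm parameters (with standard errors)
#' for the model compounds of the melanin-binding screening study, as
#' packaged reference data.  `sips_status` distinguishes compounds with a
#' fitted isotherm from those not studied in the traditional assay and
#' those without measurable binding; diclofenac's MST Kd could not be
#' determined and is `NA`.
#'
#' @return A [tibble::tibble()] with one row per compound and columns
#'   `compound`, `kd_mst_uM`, `kd_mst_ci68_uM`, `mst_mode`, `kd_sips_uM`,
#'   `se_kd_sips`, `bmax_nmol_mg`, `se_bmax`, `n_sips`, `se_n`,
#'   `sips_status`.
#' @export
#' @examples
#' binding_parameters()
binding_parameters <- function() {
  path <- system.file("extdata", "binding_parameters.csv",
                      package = "melbind", mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path, check.names = TRUE))
}

#' Published unbound fractions and binding classes of the screening set
#'
#' The reference classification table of the screening study: per
#' compound, the binding class from each method, the unbound fraction at
#' 1 mg/mL melanin in vitro, the predicted unbound fraction in the human
#' RPE-choroid (34.8 mg/mL), and the calculation route
#' (`sips_mass_balance` at 1 uM total ligand, or `dilution_equation` from
#' literature fractions at ~0.3 uM).  For the dilution-route compounds the
#' `fu_vitro_pct` column doubles as the input to the extrapolation;
#' quinidine and penicillin G carry the 2.1-fold cassette correction.
#'
#' @return A [tibble::tibble()] with columns `compound`,
#'   `class_traditional`, `class_mst`, `fu_vitro_pct`, `fu_vivo_pct`,
#'   `method`.
#' @export
#' @examples
#' reference_predictions()
reference_predictions <- function() {
  path <- system.file("extdata", "unbound_reference.csv",
                      package = "melbind", mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path, check.names = TRUE))
}
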