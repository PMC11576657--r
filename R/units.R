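#' @useDynLib adcsim, .registration = TRUE
#' @importFrom stats approx coef cor lm median qnorm quantile resid rexp rlnorm
#'   rnorm runif sd setNames complete.cases pt
#' @importFrom utils modifyList head tail
NULL

#' Avogadro constant (molecules per mol)
#' @keywords internal
AVOGADRO <- 6.02214076e23

# molecules per nmol
.NMOL <- AVOGADRO * 1e-9

.assert_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0 (got %g)", name, x), call. = FALSE)
  if (nonneg && x < 0)
    stop(sprintf("'%s' must be >= 0 (got %g)", name, x), call. = FALSE)
  invisible(x)
}

#' Convert a body-weight based IV dose to a central-compartment concentration
#'
#' Converts a dose in mg/kg to the nM concentration increment it produces in
#' the central compartment when given as an instantaneous IV bolus.
#'
#' @param dose_mg_per_kg dose level (mg drug per kg body weight), >= 0
#' @param body_weight_kg body weight in kg, > 0
#' @param mw molecular weight of the dosed species (g/mol), > 0
#' @param v_central_l central compartment volume (L), > 0
#' @return concentration increment in nM
#' @examples
#' dose_to_central_conc(3.6, 70, 150000, 3) # 560 nM
#' @export
dose_to_central_conc <- function(dose_mg_per_kg, body_weight_kg, mw, v_central_l) {
  .assert_scalar(dose_mg_per_kg, "dose_mg_per_kg", nonneg = TRUE)
  .assert_scalar(body_weight_kg, "body_weight_kg", positive = TRUE)
  .assert_scalar(mw, "mw", positive = TRUE)
  .assert_scalar(v_central_l, "v_central_l", positive = TRUE)
  # mg -> nmol: mg * 1e6 / (g/mol); nmol / L = nM
  dose_mg_per_kg * body_weight_kg * 1e6 / mw / v_central_l
}

#' Convert a dose in mg/kg to an amount in nmol
#' @inheritParams dose_to_central_conc
#' @return amount in nmol
#' @export
dose_to_nmol <- function(dose_mg_per_kg, body_weight_kg, mw) {
  .assert_scalar(dose_mg_per_kg, "dose_mg_per_kg", nonneg = TRUE)
  .assert_scalar(body_weight_kg, "body_weight_kg", positive = TRUE)
  .assert_scalar(mw, "mw", positive = TRUE)
  dose_mg_per_kg * body_weight_kg * 1e6 / mw
}

#' Convert a receptor count per cell to a concentration
#'
#' Expresses `r_per_cell * n_cells` receptors distributed in a volume `v_l`
#' as a molar concentration in nM.
#'
#' @param r_per_cell receptors per cell, >= 0
#' @param n_cells number of cells, >= 0
#' @param v_l volume in L, > 0
#' @return concentration in nM
#' @examples
#' receptors_to_conc(1e6, 1e11, 1) # ~166 nM
#' @export
receptors_to_conc <- function(r_per_cell, n_cells, v_l) {
  .assert_scalar(r_per_cell, "r_per_cell", nonneg = TRUE)
  .assert_scalar(n_cells, "n_cells", nonneg = TRUE)
  .assert_scalar(v_l, "v_l", positive = TRUE)
  r_per_cell * n_cells / AVOGADRO * 1e9 / v_l
}

#' Receptor count to amount in nmol
#' @inheritParams receptors_to_conc
#' @return amount in nmol
#' @export
receptors_to_nmol <- function(r_per_cell, n_cells) {
  .assert_scalar(r_per_cell, "r_per_cell", nonneg = TRUE)
  .assert_scalar(n_cells, "n_cells", nonneg = TRUE)
  r_per_cell * n_cells / .NMOL
}

#' First-order rate constant from a half-life
#'
#' @param t_half half-life (any time unit), > 0
#' @return rate constant ln(2)/t_half in the reciprocal unit
#' @examples
#' half_life_to_rate(11.6) # antibody elimination, 1/day
#' @export
half_life_to_rate <- function(t_half) {
  .assert_scalar(t_half, "t_half", positive = TRUE)
  log(2) / t_half
}

#' Half-life from a first-order rate constant
#' @param rate rate constant, > 0
#' @return half-life ln(2)/rate
#' @export
rate_to_half_life <- function(rate) {
  .assert_scalar(rate, "rate", positive = TRUE)
  log(2) / rate
}

#' Equivalent spherical diameter of a tumor volume
#' @param v_mm3 tumor volume in mm^3
#' @return diameter in mm, (6 V / pi)^(1/3)
#' @export
volume_to_diameter <- function(v_mm3) (6 * v_mm3 / pi)^(1 / 3)

#' Tumor volume from an equivalent spherical diameter
#' @param d_mm diameter in mm
#' @return volume in mm^3
#' @export
diameter_to_volume <- function(d_mm) pi / 6 * d_mm^3
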