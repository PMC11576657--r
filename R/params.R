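# Parameter containers.  Canonical unit system: nM, days, L (systemic
# volumes), mm^3 (tumor volume), cm (lengths).  Constructors validate
# invariants once; downstream code assumes validated objects.

.check_rates <- function(x, names) {
  for (nm in names) .assert_scalar(x[[nm]], nm, nonneg = TRUE)
}

#' Molecule (drug-specific) parameters
#'
#' Rate constants and physical properties of one ADC molecule in canonical
#' units (1/day, 1/nM/day, g/mol).
#'
#' @param name molecule label
#' @param linker_type `"cleavable"` or `"non_cleavable"`; a non-cleavable
#'   linker must have `k_cleave = 0` and a cleavable one `k_cleave > 0`
#' @param dar mean drug-to-antibody ratio (> 0)
#' @param k_dec extracellular deconjugation rate (1/day)
#' @param k_on_ab,k_off_ab antibody-receptor association (1/nM/day) and
#'   dissociation (1/day) rates
#' @param k_cleave endo/lysosomal linker cleavage rate (1/day)
#' @param k_in_pl,k_out_pl payload cellular influx/efflux rates (1/day)
#' @param k_on_pl,k_off_pl payload binding rates to its intracellular target
#' @param mw_adc,mw_pl molecular weights of ADC and payload (g/mol)
#' @return object of class `molecule_params`
#' @export
molecule_params <- function(name = "ADC",
                            linker_type = c("non_cleavable", "cleavable"),
                            dar, k_dec, k_on_ab, k_off_ab, k_cleave = 0,
                            k_in_pl, k_out_pl, k_on_pl, k_off_pl,
                            mw_adc, mw_pl) {
  linker_type <- match.arg(linker_type)
  p <- list(name = name, linker_type = linker_type, dar = dar, k_dec = k_dec,
            k_on_ab = k_on_ab, k_off_ab = k_off_ab, k_cleave = k_cleave,
            k_in_pl = k_in_pl, k_out_pl = k_out_pl,
            k_on_pl = k_on_pl, k_off_pl = k_off_pl,
            mw_adc = mw_adc, mw_pl = mw_pl)
  .assert_scalar(dar, "dar", positive = TRUE)
  .check_rates(p, c("k_dec", "k_on_ab", "k_off_ab", "k_cleave",
                    "k_in_pl", "k_out_pl", "k_on_pl", "k_off_pl"))
  .assert_scalar(mw_adc, "mw_adc", positive = TRUE)
  .assert_scalar(mw_pl, "mw_pl", positive = TRUE)
  if (linker_type == "non_cleavable" && k_cleave != 0)
    stop("non-cleavable linker requires k_cleave = 0", call. = FALSE)
  structure(p, class = "molecule_params")
}

#' System (target, physiology, transport) parameters
#'
#' Receptor trafficking rates, compartment volumes, healthy-tissue sink and
#' soluble-target parameters, and tumor transport geometry, in canonical
#' units.
#'
#' @param k_endo_her2,k_endo_her2ab internalization rates of free and
#'   drug-bound receptor (1/day)
#' @param k_rec_her2,k_rec_her2ab recycling rates from the endo/lysosomal
#'   compartment to the surface (1/day)
#' @param k_deg_her2,k_deg_her2ab endo/lysosomal degradation rates (1/day)
#' @param r_total_per_cell receptors per tumor cell
#' @param target_conc intracellular payload target concentration (nM);
#'   tubulin for maytansinoids, TOPO-1 for camptothecin payloads
#' @param k12,k21 antibody inter-compartment distribution rates (1/day)
#' @param k12_pl,k21_pl payload distribution rates (1/day)
#' @param k_elim_ab,k_elim_pl first-order elimination rates (1/day)
#' @param v_central,v_peripheral systemic compartment volumes (L)
#' @param v_tumor_init initial tumor volume (mm^3)
#' @param k_shed membrane receptor shedding rate (1/day)
#' @param t_half_sher2,t_half_sher2ab half-lives of soluble receptor and its
#'   drug complexes (day)
#' @param n_healthy_central,n_healthy_peripheral healthy HER2+ cell counts
#' @param r_healthy_per_cell receptors per healthy cell
#' @param d_ab,d_pl diffusivities of antibody species and payload (cm^2/day)
#' @param p_ab,p_pl vascular permeabilities (cm/day)
#' @param r_cap,r_krogh capillary and Krogh cylinder radii (cm)
#' @param eps_ab,eps_pl tumor void fractions for antibody species and
#'   payload; must satisfy 0 < eps_ab <= eps_pl <= 1
#' @param cell_density tumor cells per mm^3
#' @param v_cell single-cell volume (L)
#' @param body_weight body weight (kg) used for mg/kg dose conversion
#' @param species `"mouse"` or `"human"`
#' @return object of class `system_params`
#' @export
system_params <- function(k_endo_her2, k_endo_her2ab,
                          k_rec_her2, k_rec_her2ab,
                          k_deg_her2, k_deg_her2ab,
                          r_total_per_cell, target_conc,
                          k12, k21, k12_pl, k21_pl,
                          k_elim_ab, k_elim_pl,
                          v_central, v_peripheral, v_tumor_init,
                          k_shed = 0, t_half_sher2 = 1, t_half_sher2ab = 1,
                          n_healthy_central = 0, n_healthy_peripheral = 0,
                          r_healthy_per_cell = 0,
                          d_ab, p_ab, d_pl, p_pl, r_cap, r_krogh,
                          eps_ab, eps_pl, cell_density, v_cell,
                          body_weight, species = c("mouse", "human")) {
  species <- match.arg(species)
  p <- as.list(environment())
  .check_rates(p, c("k_endo_her2", "k_endo_her2ab", "k_rec_her2",
                    "k_rec_her2ab", "k_deg_her2", "k_deg_her2ab",
                    "k12", "k21", "k12_pl", "k21_pl",
                    "k_elim_ab", "k_elim_pl", "k_shed",
                    "r_total_per_cell", "n_healthy_central",
                    "n_healthy_peripheral", "r_healthy_per_cell",
                    "target_conc"))
  for (nm in c("v_central", "v_peripheral", "t_half_sher2", "t_half_sher2ab",
               "d_ab", "p_ab", "d_pl", "p_pl", "r_cap", "r_krogh",
               "cell_density", "v_cell", "body_weight"))
    .assert_scalar(p[[nm]], nm, positive = TRUE)
  .assert_scalar(v_tumor_init, "v_tumor_init", nonneg = TRUE)
  .assert_scalar(eps_ab, "eps_ab")
  .assert_scalar(eps_pl, "eps_pl")
  if (!(eps_ab > 0 && eps_ab <= eps_pl && eps_pl <= 1))
    stop("void fractions must satisfy 0 < eps_ab <= eps_pl <= 1",
         call. = FALSE)
  structure(p, class = "system_params")
}

#' Tumor growth inhibition parameters
#'
#' Parameters of the exponential-to-linear growth model with logistic cap and
#' the transit-compartment killing cascade.
#'
#' @param t_double exponential doubling time (day)
#' @param k_lin linear growth rate (mm^3/day)
#' @param v_tumor_max maximum tumor volume (mm^3)
#' @param psi growth regime switching constant (dimensionless, >= 1;
#'   default 20)
#' @param tau transduction delay: mean residence time of the killing
#'   cascade (day)
#' @param k_kill_max maximal kill rate (1/day)
#' @param kc50 intracellular payload concentration at half-maximal kill (nM)
#' @return object of class `tgi_params`
#' @export
tgi_params <- function(t_double, k_lin, v_tumor_max, psi = 20, tau,
                       k_kill_max, kc50) {
  p <- as.list(environment())
  for (nm in c("t_double", "k_lin", "v_tumor_max", "tau", "k_kill_max",
               "kc50"))
    .assert_scalar(p[[nm]], nm, positive = TRUE)
  .assert_scalar(psi, "psi")
  if (psi < 1) stop("psi must be >= 1", call. = FALSE)
  structure(p, class = "tgi_params")
}

#' IV dosing regimen
#'
#' @param dose_mg_per_kg dose level (mg/kg) of each administration
#' @param interval days between doses (> 0 if `n_doses > 1`)
#' @param n_doses number of doses (>= 1)
#' @param analyte which species is dosed: `"adc"`, `"antibody"` or
#'   `"payload"`
#' @param route `"bolus"` (default) or `"infusion"`
#' @param duration infusion duration (day), required for infusion
#' @return object of class `regimen`
#' @export
regimen <- function(dose_mg_per_kg, interval = 21, n_doses = 1,
                    analyte = c("adc", "antibody", "payload"),
                    route = c("bolus", "infusion"), duration = NULL) {
  analyte <- match.arg(analyte)
  route <- match.arg(route)
  .assert_scalar(dose_mg_per_kg, "dose_mg_per_kg", nonneg = TRUE)
  if (n_doses < 1) stop("n_doses must be >= 1", call. = FALSE)
  if (n_doses > 1) .assert_scalar(interval, "interval", positive = TRUE)
  if (route == "infusion") {
    if (is.null(duration))
      stop("infusion route requires a duration", call. = FALSE)
    .assert_scalar(duration, "duration", positive = TRUE)
  }
  structure(list(dose_mg_per_kg = dose_mg_per_kg, interval = interval,
                 n_doses = as.integer(n_doses), analyte = analyte,
                 route = route, duration = duration),
            class = "regimen")
}

#' @export
print.molecule_params <- function(x, ...) {
  cat(sprintf("<molecule_params> %s (%s linker), DAR %.3g\n",
              x$name, x$linker_type, x$dar))
  invisible(x)
}

#' @export
print.system_params <- function(x, ...) {
  cat(sprintf("<system_params> %s: %.3g receptors/cell, Vc %.3g L\n",
              x$species, x$r_total_per_cell, x$v_central))
  invisible(x)
}

#' @export
print.tgi_params <- function(x, ...) {
  cat(sprintf(
    "<tgi_params> t_double %.3g d, k_lin %.3g mm^3/d, k_kill_max %.3g /d, kc50 %.3g nM\n",
    x$t_double, x$k_lin, x$k_kill_max, x$kc50))
  invisible(x)
}

#' @export
print.regimen <- function(x, ...) {
  cat(sprintf("<regimen> %g mg/kg %s x%d q%gd\n", x$dose_mg_per_kg,
              x$analyte, x$n_doses, x$interval))
  invisible(x)
}
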