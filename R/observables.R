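# Derived analytes, matching ligand-binding-assay conventions:
# "adc" counts conjugated antibody regardless of binding state (free +
# soluble-complexed), "total_ab" additionally counts the naked antibody,
# "payload" is the free released payload.

#' Plasma analyte concentrations from an in vivo trajectory
#'
#' @param traj an `adc_trajectory` from [simulate_regimen()]
#' @param compartment `"central"` or `"peripheral"`
#' @return data frame with `time`, `adc`, `total_ab`, `payload`
#'   concentrations (nM)
#' @export
plasma_concentrations <- function(traj, compartment = c("central",
                                                        "peripheral")) {
  compartment <- match.arg(compartment)
  model <- attr(traj, "model")
  stopifnot(model$kind == "invivo")
  sfx <- if (compartment == "central") "_c" else "_p"
  v <- if (compartment == "central") model$sys$v_central
       else model$sys$v_peripheral
  g <- function(nm) traj[[paste0(nm, sfx)]]
  data.frame(
    time = traj$time,
    adc = (g("adc") + g("sher2adc")) / v,
    total_ab = (g("adc") + g("ab") + g("sher2adc") + g("sher2ab")) / v,
    payload = g("pl") / v)
}

#' Tumor observables from a coupled trajectory
#'
#' @param traj an `adc_trajectory` from a tumor-coupled model
#' @return data frame with tumor volume (mm^3), equivalent spherical
#'   diameter (mm), kill-driving intracellular unconjugated payload
#'   concentration (nM), total intracellular unconjugated payload (nM),
#'   total tumor payload (conjugated + unconjugated, nM over tumor volume),
#'   tumor extracellular ADC concentration (nM, accessible volume) and
#'   surface receptor occupancy
#' @export
tumor_observables <- function(traj) {
  model <- attr(traj, "model")
  stopifnot(model$kind == "invivo", isTRUE(model$opts$tumor_on))
  sys <- model$sys
  vt <- traj$n1 + traj$n2 + traj$n3 + traj$n4           # mm^3
  vt_safe <- pmax(vt, 1e-9)
  vt_l <- vt_safe * 1e-6
  v_intra <- sys$v_cell * sys$cell_density * vt_safe    # L
  kill_free_only <- isTRUE(model$opts$kill_free_only)
  cyto <- traj$t_pl_cyto_free + if (kill_free_only) 0 else traj$t_pl_cyto_bound
  dar <- model$mol$dar
  occ_den <- traj$t_her2_surf + traj$t_her2adc_surf + traj$t_her2ab_surf
  data.frame(
    time = traj$time,
    tumor_volume = vt,
    tumor_diameter = volume_to_diameter(vt),
    payload_intra_conc = cyto / v_intra,
    payload_intra_total_conc =
      (traj$t_pl_endo + traj$t_pl_cyto_free + traj$t_pl_cyto_bound) / v_intra,
    payload_tumor_total_conc =
      (traj$t_pl_endo + traj$t_pl_cyto_free + traj$t_pl_cyto_bound +
         traj$pl_t +
         dar * (traj$adc_t + traj$t_her2adc_surf + traj$t_her2adc_endo)) /
        vt_l,
    adc_tumor_conc = traj$adc_t / vt_l / sys$eps_ab,
    receptor_occupancy =
      (traj$t_her2adc_surf + traj$t_her2ab_surf) / pmax(occ_den, 1e-300))
}

#' Media and intracellular concentrations from an in vitro trajectory
#'
#' @param traj an `adc_trajectory` from [simulate_cellular()]
#' @return data frame with media ADC/antibody/payload concentrations and
#'   intracellular unconjugated payload concentration (nM)
#' @export
cellular_concentrations <- function(traj) {
  model <- attr(traj, "model")
  stopifnot(model$kind == "cellular")
  data.frame(
    time = traj$time,
    adc_media = traj$adc_media / model$v_media,
    ab_media = traj$ab_media / model$v_media,
    payload_media = traj$pl_media / model$v_media,
    payload_intracellular =
      (traj$pl_endo + traj$pl_cyto_free + traj$pl_cyto_bound) / model$v_cyt)
}

#' Long (tidy) form of a trajectory
#'
#' @param traj an `adc_trajectory`
#' @return data frame with columns `time`, `species`, `amount` (nmol)
#' @export
trajectory_long <- function(traj) {
  df <- as.data.frame(traj)
  species <- setdiff(names(df), "time")
  out <- data.frame(
    time = rep(df$time, times = length(species)),
    species = rep(species, each = nrow(df)),
    amount = unlist(df[species], use.names = FALSE))
  rownames(out) <- NULL
  out
}

#' Trapezoidal area under a curve
#' @param t time points (increasing)
#' @param y values
#' @return AUC by the trapezoid rule
#' @export
auc_trapz <- function(t, y) {
  stopifnot(length(t) == length(y), length(t) >= 2)
  sum(diff(t) * (head(y, -1) + tail(y, -1)) / 2)
}

#' Terminal half-life from a concentration-time profile
#'
#' Log-linear regression over the terminal portion of the profile.
#'
#' @param t time points
#' @param conc concentrations (> 0 over the fitted window)
#' @param tail_frac fraction of the profile (by time, from the end) used
#'   for the regression; default the final half
#' @return half-life in the unit of `t`
#' @export
terminal_half_life <- function(t, conc, tail_frac = 0.5) {
  keep <- t >= max(t) - tail_frac * (max(t) - min(t)) & conc > 0
  if (sum(keep) < 3) stop("not enough points in the terminal window",
                          call. = FALSE)
  slope <- coef(lm(log(conc[keep]) ~ t[keep]))[[2]]
  if (slope >= 0) stop("terminal profile is not declining", call. = FALSE)
  log(2) / -slope
}
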