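# Model assembly and simulation on top of the compiled right-hand sides.
# Orderings of .CELL_PARMS / .VIVO_PARMS and the state vectors must match
# the enums in src/models.c.

.CELL_PARMS <- c("dar", "k_dec", "k_on_ab", "k_off_ab", "k_cleave",
                 "k_in_pl", "k_out_pl", "k_on_pl", "k_off_pl",
                 "k_endo_her2", "k_endo_her2ab", "k_rec_her2", "k_rec_her2ab",
                 "k_deg_her2", "k_deg_her2ab", "v_media", "v_cyt",
                 "target_conc")

.CELL_STATES <- c("adc_media", "ab_media", "pl_media",
                  "her2_surf", "her2adc_surf", "her2ab_surf",
                  "her2_endo", "her2adc_endo", "her2ab_endo",
                  "pl_endo", "pl_cyto_free", "pl_cyto_bound")

.VIVO_PARMS <- c("dar", "k_dec", "k_on_ab", "k_off_ab", "k_cleave",
                 "k_in_pl", "k_out_pl", "k_on_pl", "k_off_pl",
                 "k_endo", "k_endob", "k_rec", "k_recb", "k_deg", "k_degb",
                 "k12", "k21", "k_elim_ab", "k12_pl", "k21_pl", "k_elim_pl",
                 "v_central", "v_peripheral",
                 "k_shed", "k_elim_s", "k_elim_sb",
                 "target_conc", "r_dens", "f_cell", "eps_ab", "eps_pl",
                 "d_ab", "p_ab", "d_pl", "p_pl", "r_cap", "r_krogh",
                 "ex_mode",
                 "k_exp", "k_lin", "v_max", "psi", "k_kill_max", "kc50",
                 "k_tau",
                 "growth_on", "kill_free_only", "f_tumor", "f_surf",
                 "inf_rate", "inf_target")

.VIVO_STATES <- c("adc_c", "adc_p", "ab_c", "ab_p", "pl_c", "pl_p",
                  "sher2_c", "sher2adc_c", "sher2ab_c",
                  "sher2_p", "sher2adc_p", "sher2ab_p",
                  "hc_her2_surf", "hc_her2adc_surf", "hc_her2ab_surf",
                  "hc_her2_endo", "hc_her2adc_endo", "hc_her2ab_endo",
                  "hp_her2_surf", "hp_her2adc_surf", "hp_her2ab_surf",
                  "hp_her2_endo", "hp_her2adc_endo", "hp_her2ab_endo",
                  "adc_t", "ab_t", "pl_t",
                  "t_her2_surf", "t_her2adc_surf", "t_her2ab_surf",
                  "t_her2_endo", "t_her2adc_endo", "t_her2ab_endo",
                  "t_pl_endo", "t_pl_cyto_free", "t_pl_cyto_bound",
                  "n1", "n2", "n3", "n4")

.default_solver <- function(solver = list()) {
  modifyList(list(method = "lsoda", rtol = 1e-8, atol = 1e-10,
                  maxsteps = 50000), solver)
}

#' Drug-free steady-state split of receptor between surface and endosome
#'
#' With receptor synthesis balancing degradation (total receptor constant),
#' the drug-free surface/endosome split is
#' `endo/surface = k_endo / (k_rec + k_deg)`.
#'
#' @param sys a `system_params` object
#' @return list with `frac_surface` and `frac_endo` (summing to 1)
#' @export
receptor_steady_state <- function(sys) {
  ke <- sys$k_endo_her2; kr <- sys$k_rec_her2; kd <- sys$k_deg_her2
  if (ke == 0 && kr + kd == 0)
    stop("degenerate receptor trafficking: all rates are zero",
         call. = FALSE)
  if (ke == 0) return(list(frac_surface = 1, frac_endo = 0))
  if (kr + kd == 0) return(list(frac_surface = 0, frac_endo = 1))
  ratio <- ke / (kr + kd)           # endo : surface
  fs <- 1 / (1 + ratio)
  list(frac_surface = fs, frac_endo = 1 - fs)
}

#' Build the in vitro cellular disposition model
#'
#' Assembles the ODE system for one cell line incubated with an ADC: media
#' deconjugation, monovalent reversible receptor binding of ADC and naked
#' antibody, internalization/recycling/degradation, payload release by
#' degradation (non-cleavable) and linker cleavage (cleavable), transfer to
#' the cytosol, intracellular target binding, and passive payload
#' efflux/re-entry.  Receptors start at their drug-free steady-state split
#' and total receptor is conserved.
#'
#' @param mol a `molecule_params`
#' @param sys a `system_params`
#' @param n_cells number of cells in the incubation
#' @param v_media media volume (L)
#' @return object of class `adc_model`
#' @export
build_cellular_model <- function(mol, sys, n_cells, v_media) {
  stopifnot(inherits(mol, "molecule_params"), inherits(sys, "system_params"))
  .assert_scalar(n_cells, "n_cells", positive = TRUE)
  .assert_scalar(v_media, "v_media", positive = TRUE)
  v_cyt <- sys$v_cell * n_cells
  p <- c(mol$dar, mol$k_dec, mol$k_on_ab, mol$k_off_ab, mol$k_cleave,
         mol$k_in_pl, mol$k_out_pl, mol$k_on_pl, mol$k_off_pl,
         sys$k_endo_her2, sys$k_endo_her2ab, sys$k_rec_her2,
         sys$k_rec_her2ab, sys$k_deg_her2, sys$k_deg_her2ab,
         v_media, v_cyt, sys$target_conc)
  names(p) <- .CELL_PARMS
  ss <- receptor_steady_state(sys)
  rtot <- receptors_to_nmol(sys$r_total_per_cell, n_cells)
  y0 <- setNames(numeric(length(.CELL_STATES)), .CELL_STATES)
  y0["her2_surf"] <- rtot * ss$frac_surface
  y0["her2_endo"] <- rtot * ss$frac_endo
  structure(list(kind = "cellular", parms = p, y0 = y0,
                 mol = mol, sys = sys, n_cells = n_cells,
                 v_media = v_media, v_cyt = v_cyt),
            class = "adc_model")
}

.assemble_vivo_parms <- function(mol, sys, tgi, opts) {
  k_elim_s <- half_life_to_rate(sys$t_half_sher2)
  k_elim_sb <- half_life_to_rate(sys$t_half_sher2ab)
  r_dens <- sys$r_total_per_cell * sys$cell_density / (AVOGADRO * 1e-9)
  f_cell <- sys$v_cell * sys$cell_density     # L cytosol per mm^3 tumor
  ss <- receptor_steady_state(sys)
  if (is.null(tgi)) {
    tg <- c(k_exp = 0, k_lin = 1, v_max = 1, psi = 20, k_kill_max = 0,
            kc50 = 1, k_tau = 1, growth_on = 0)
  } else {
    tg <- c(k_exp = log(2) / tgi$t_double, k_lin = tgi$k_lin,
            v_max = tgi$v_tumor_max, psi = tgi$psi,
            k_kill_max = tgi$k_kill_max, kc50 = tgi$kc50,
            k_tau = if (isTRUE(opts$single_transit)) 1 / tgi$tau
                    else 3 / tgi$tau,
            growth_on = as.numeric(isTRUE(opts$growth_on)))
  }
  p <- c(mol$dar, mol$k_dec, mol$k_on_ab, mol$k_off_ab, mol$k_cleave,
         mol$k_in_pl, mol$k_out_pl, mol$k_on_pl, mol$k_off_pl,
         sys$k_endo_her2, sys$k_endo_her2ab, sys$k_rec_her2,
         sys$k_rec_her2ab, sys$k_deg_her2, sys$k_deg_her2ab,
         sys$k12, sys$k21, sys$k_elim_ab, sys$k12_pl, sys$k21_pl,
         sys$k_elim_pl,
         sys$v_central, sys$v_peripheral,
         sys$k_shed, k_elim_s, k_elim_sb,
         sys$target_conc, r_dens, f_cell, sys$eps_ab, sys$eps_pl,
         sys$d_ab, sys$p_ab, sys$d_pl, sys$p_pl, sys$r_cap, sys$r_krogh,
         as.numeric(identical(opts$exchange_mode, "switch")),
         tg[["k_exp"]], tg[["k_lin"]], tg[["v_max"]], tg[["psi"]],
         tg[["k_kill_max"]], tg[["kc50"]], tg[["k_tau"]],
         tg[["growth_on"]], as.numeric(isTRUE(opts$kill_free_only)),
         as.numeric(isTRUE(opts$tumor_on)), ss$frac_surface,
         0, 0)
  names(p) <- .VIVO_PARMS
  p
}

.assemble_vivo_init <- function(mol, sys, opts) {
  y0 <- setNames(numeric(length(.VIVO_STATES)), .VIVO_STATES)
  ss <- receptor_steady_state(sys)
  rh_c <- receptors_to_nmol(sys$r_healthy_per_cell, sys$n_healthy_central)
  rh_p <- receptors_to_nmol(sys$r_healthy_per_cell, sys$n_healthy_peripheral)
  y0["hc_her2_surf"] <- rh_c * ss$frac_surface
  y0["hc_her2_endo"] <- rh_c * ss$frac_endo
  y0["hp_her2_surf"] <- rh_p * ss$frac_surface
  y0["hp_her2_endo"] <- rh_p * ss$frac_endo
  if (isTRUE(opts$tumor_on)) {
    v0 <- sys$v_tumor_init
    rt <- sys$r_total_per_cell * sys$cell_density * v0 / (AVOGADRO * 1e-9)
    y0["t_her2_surf"] <- rt * ss$frac_surface
    y0["t_her2_endo"] <- rt * ss$frac_endo
    y0["n1"] <- v0
  }
  # drug-free steady state of the free soluble receptor pools
  if (sys$k_shed > 0) {
    kels <- half_life_to_rate(sys$t_half_sher2)
    a_c <- sys$k_shed * (y0[["hc_her2_surf"]] +
                           if (isTRUE(opts$tumor_on)) y0[["t_her2_surf"]]
                           else 0)
    a_p <- sys$k_shed * y0[["hp_her2_surf"]]
    a_mat <- matrix(c(kels + sys$k12, -sys$k21,
                      -sys$k12, kels + sys$k21), 2, 2, byrow = TRUE)
    s <- solve(a_mat, c(a_c, a_p))
    y0["sher2_c"] <- s[1]
    y0["sher2_p"] <- s[2]
  }
  y0
}

.new_vivo_model <- function(mol, sys, tgi, opts) {
  opts <- modifyList(list(tumor_on = FALSE, growth_on = FALSE,
                          exchange_mode = "sum", kill_free_only = FALSE,
                          single_transit = FALSE), opts)
  structure(list(kind = "invivo", mol = mol, sys = sys, tgi = tgi,
                 opts = opts,
                 parms = .assemble_vivo_parms(mol, sys, tgi, opts),
                 y0 = .assemble_vivo_init(mol, sys, opts)),
            class = "adc_model")
}

#' Build the mouse plasma PK model
#'
#' Two-compartment kinetics of ADC, naked antibody and released payload with
#' deconjugation in every compartment.  The mouse carries no target sinks:
#' receptor shedding and healthy-cell expression are forced to zero
#' (trastuzumab does not cross-react with rodent Her2).  Couple a tumor with
#' [couple_tumor()].
#'
#' @param mol a `molecule_params`
#' @param sys a `system_params`
#' @return an `adc_model`
#' @export
build_mouse_pk <- function(mol, sys) {
  stopifnot(inherits(mol, "molecule_params"), inherits(sys, "system_params"))
  sys$k_shed <- 0
  sys$n_healthy_central <- 0
  sys$n_healthy_peripheral <- 0
  .new_vivo_model(mol, sys, NULL, list())
}

#' Build the human plasma PK model
#'
#' The mouse structure plus soluble HER2 shedding (from tumor and
#' healthy-cell membranes), reversible binding of ADC/antibody to the
#' soluble receptor, first-order elimination of soluble species, and
#' healthy-cell membrane receptor sinks in the central and peripheral
#' compartments.
#'
#' @inheritParams build_mouse_pk
#' @return an `adc_model`
#' @export
build_human_pk <- function(mol, sys) {
  stopifnot(inherits(mol, "molecule_params"), inherits(sys, "system_params"))
  if (sys$k_shed > 0 &&
      (is.null(sys$t_half_sher2) || is.null(sys$t_half_sher2ab)))
    stop("soluble-target parameters required for the human model",
         call. = FALSE)
  .new_vivo_model(mol, sys, NULL, list())
}

#' Couple a tumor compartment to a systemic PK model
#'
#' Adds tumor extracellular ADC/antibody/payload pools behind void
#' fractions, the full cellular sub-model on the tumor cells (receptor
#' amounts scaling with live cell mass), and size-dependent plasma-tumor
#' exchange (surface + Krogh vascular terms recomputed from the current
#' tumor volume at every evaluation).  Supplying `tgi` switches on tumor
#' growth and payload-driven killing.
#'
#' @param model an `adc_model` from [build_mouse_pk()] or [build_human_pk()]
#' @param tgi optional `tgi_params`; when omitted the tumor is static
#' @param exchange_mode `"sum"` (default; surface and vascular terms added)
#'   or `"switch"` (dominant term only)
#' @param kill_free_only if `TRUE` only free cytosolic payload drives the
#'   kill rate; default uses free + target-bound cytosolic payload
#' @param single_transit if `TRUE` transit steps leave at rate `1/tau`
#'   instead of the default `3/tau` (Erlang-3, mean delay `tau`)
#' @return an `adc_model` with an active tumor compartment
#' @export
couple_tumor <- function(model, tgi = NULL, exchange_mode = c("sum", "switch"),
                         kill_free_only = FALSE, single_transit = FALSE) {
  stopifnot(inherits(model, "adc_model"), model$kind == "invivo")
  exchange_mode <- match.arg(exchange_mode)
  if (!is.null(tgi) && !inherits(tgi, "tgi_params"))
    stop("'tgi' must be a tgi_params object", call. = FALSE)
  if (is.null(model$sys$v_tumor_init))
    stop("system parameters carry no tumor geometry", call. = FALSE)
  opts <- modifyList(model$opts,
                     list(tumor_on = TRUE, growth_on = !is.null(tgi),
                          exchange_mode = exchange_mode,
                          kill_free_only = kill_free_only,
                          single_transit = single_transit))
  .new_vivo_model(model$mol, model$sys, tgi, opts)
}

#' @export
print.adc_model <- function(x, ...) {
  if (x$kind == "cellular")
    cat(sprintf("<adc_model> in vitro cellular: %s, %.3g cells in %.3g mL\n",
                x$mol$name, x$n_cells, x$v_media * 1e3))
  else
    cat(sprintf("<adc_model> in vivo %s: %s%s%s\n", x$sys$species,
                x$mol$name,
                if (isTRUE(x$opts$tumor_on)) " + tumor" else "",
                if (isTRUE(x$opts$growth_on)) " + TGI" else ""))
  invisible(x)
}

.integrate <- function(model, y0, times, events = NULL, solver = list(),
                       parms = NULL) {
  sv <- .default_solver(solver)
  if (is.null(parms)) parms <- model$parms
  fn <- if (model$kind == "cellular") c("cell_derivs", "cell_init")
        else c("vivo_derivs", "vivo_init")
  out <- deSolve::ode(y = y0, times = times, func = fn[1], parms = parms,
                      dllname = "adcsim", initfunc = fn[2],
                      method = sv$method, rtol = sv$rtol, atol = sv$atol,
                      maxsteps = sv$maxsteps,
                      events = if (is.null(events)) NULL
                               else list(data = events))
  if (attr(out, "istate")[1] < 0)
    stop(sprintf(
      "ODE integration failed (istate %d) at t ~ %.4g; last state recorded",
      attr(out, "istate")[1], max(out[, 1])), call. = FALSE)
  out
}

.new_trajectory <- function(out, model, regimen = NULL) {
  df <- as.data.frame(out)
  names(df)[1] <- "time"
  structure(df, class = c("adc_trajectory", "data.frame"),
            model = model, regimen = regimen)
}

#' Simulate the in vitro cellular model
#'
#' @param model an `adc_model` from [build_cellular_model()]
#' @param t_grid increasing vector of output times (day)
#' @param dose_conc initial ADC concentration in the media (nM); ignored
#'   when `initial` is given
#' @param initial optional named vector of initial state amounts (nmol)
#'   overriding the default (receptors at steady state, ADC per `dose_conc`)
#' @param solver list of solver options (`method`, `rtol`, `atol`,
#'   `maxsteps`)
#' @return an `adc_trajectory` data frame of state amounts (nmol) over time;
#'   use [cellular_concentrations()] for concentrations
#' @export
simulate_cellular <- function(model, t_grid, dose_conc = 0, initial = NULL,
                              solver = list()) {
  stopifnot(inherits(model, "adc_model"), model$kind == "cellular")
  if (is.unsorted(t_grid, strictly = TRUE))
    stop("t_grid must be strictly increasing", call. = FALSE)
  y0 <- model$y0
  if (!is.null(initial)) {
    bad <- setdiff(names(initial), .CELL_STATES)
    if (length(bad))
      stop("unknown state(s): ", paste(bad, collapse = ", "), call. = FALSE)
    y0[names(initial)] <- initial
  } else {
    y0["adc_media"] <- dose_conc * model$v_media
  }
  if (any(y0 < 0)) stop("initial state must be non-negative", call. = FALSE)
  .new_trajectory(.integrate(model, y0, t_grid, solver = solver), model)
}

#' Simulate a dosing regimen on an in vivo model
#'
#' Applies the regimen as exact bolus state increments (or zero-order
#' infusions) and integrates the coupled system over `t_grid`.
#'
#' @param model an `adc_model` from [build_mouse_pk()], [build_human_pk()]
#'   or [couple_tumor()]
#' @param reg a `regimen`
#' @param t_grid increasing vector of output times (day); must span the
#'   dosing events
#' @param solver solver options, see [simulate_cellular()]
#' @param initial optional named vector overriding initial state amounts
#'   (nmol)
#' @return an `adc_trajectory`; use [plasma_concentrations()] and
#'   [tumor_observables()] for derived analytes
#' @export
simulate_regimen <- function(model, reg, t_grid, solver = list(),
                             initial = NULL) {
  stopifnot(inherits(model, "adc_model"), model$kind == "invivo",
            inherits(reg, "regimen"))
  if (is.unsorted(t_grid, strictly = TRUE))
    stop("t_grid must be strictly increasing", call. = FALSE)
  dose_times <- t_grid[1] + (seq_len(reg$n_doses) - 1) * reg$interval
  if (max(dose_times) > max(t_grid))
    stop("dosing events fall outside the simulation time grid",
         call. = FALSE)
  y0 <- model$y0
  if (!is.null(initial)) {
    bad <- setdiff(names(initial), .VIVO_STATES)
    if (length(bad))
      stop("unknown state(s): ", paste(bad, collapse = ", "), call. = FALSE)
    y0[names(initial)] <- initial
  }
  mw <- if (reg$analyte == "payload") model$mol$mw_pl else model$mol$mw_adc
  target <- switch(reg$analyte, adc = "adc_c", antibody = "ab_c",
                   payload = "pl_c")
  amt <- dose_to_nmol(reg$dose_mg_per_kg, model$sys$body_weight, mw)

  if (reg$route == "bolus") {
    times <- sort(unique(c(t_grid, dose_times)))
    ev <- data.frame(var = target, time = dose_times, value = amt,
                     method = "add")
    out <- .integrate(model, y0, times, events = ev, solver = solver)
    out <- out[out[, 1] %in% t_grid, , drop = FALSE]
    return(.new_trajectory(out, model, reg))
  }

  # zero-order infusion: piecewise integration with the infusion rate
  # switched on during each administration window
  idx <- match(target, .VIVO_STATES)
  p_on <- model$parms
  p_on["inf_rate"] <- amt / reg$duration
  p_on["inf_target"] <- idx
  bounds <- sort(unique(c(t_grid[1], dose_times, dose_times + reg$duration,
                          max(t_grid))))
  y <- y0
  rows <- list()
  for (i in seq_len(length(bounds) - 1)) {
    t0 <- bounds[i]; t1 <- bounds[i + 1]
    on <- any(t0 >= dose_times - 1e-12 &
                t1 <= dose_times + reg$duration + 1e-12)
    seg_times <- sort(unique(c(t0, t_grid[t_grid > t0 & t_grid < t1], t1)))
    out <- .integrate(model, y, seg_times, solver = solver,
                      parms = if (on) p_on else model$parms)
    y <- out[nrow(out), -1]
    rows[[i]] <- if (i < length(bounds) - 1) out[-nrow(out), , drop = FALSE]
                 else out
  }
  all <- do.call(rbind, rows)
  all <- all[all[, 1] %in% t_grid, , drop = FALSE]
  colnames(all) <- c("time", .VIVO_STATES)
  .new_trajectory(all, model, reg)
}

#' Simulate tumor growth inhibition under a dosing regimen
#'
#' Convenience wrapper: simulates the coupled PK + tumor disposition + TGI
#' model and returns the tumor volume/diameter trajectory together with the
#' payload observables that drive killing.
#'
#' @inheritParams simulate_regimen
#' @return a data frame with `time`, `tumor_volume` (mm^3),
#'   `tumor_diameter` (mm), `payload_intra_conc` (nM, kill-driving
#'   intracellular unconjugated payload) and `payload_tumor_total_conc`
#'   (nM, total payload per tumor volume)
#' @export
simulate_tgi <- function(model, reg, t_grid, solver = list()) {
  if (!isTRUE(model$opts$tumor_on))
    stop("model has no tumor compartment; call couple_tumor() first",
         call. = FALSE)
  traj <- simulate_regimen(model, reg, t_grid, solver = solver)
  tumor_observables(traj)
}
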