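# Small parameter sets and generators shared across test files.  All
# fixtures are built in code; randomized cases always run under a fixed
# seed.

quick_mol <- function(...) {
  args <- modifyList(list(
    name = "test-ADC", linker_type = "non_cleavable", dar = 4,
    k_dec = 0.1, k_on_ab = 50, k_off_ab = 25, k_cleave = 0,
    k_in_pl = 2, k_out_pl = 1, k_on_pl = 5, k_off_pl = 10,
    mw_adc = 150000, mw_pl = 750), list(...))
  do.call(molecule_params, args)
}

quick_sys <- function(...) {
  args <- modifyList(list(
    k_endo_her2 = 5, k_endo_her2ab = 5, k_rec_her2 = 8, k_rec_her2ab = 8,
    k_deg_her2 = 3, k_deg_her2ab = 3, r_total_per_cell = 1e6,
    target_conc = 65, k12 = 0.3, k21 = 0.45, k12_pl = 15, k21_pl = 21,
    k_elim_ab = log(2) / 11.6, k_elim_pl = 4.75, v_central = 1e-3,
    v_peripheral = 2.6e-3, v_tumor_init = 200, k_shed = 0,
    t_half_sher2 = 0.5, t_half_sher2ab = 2, n_healthy_central = 0,
    n_healthy_peripheral = 0, r_healthy_per_cell = 0, d_ab = 0.022,
    p_ab = 0.0334, d_pl = 0.25, p_pl = 5, r_cap = 8e-4, r_krogh = 75e-4,
    eps_ab = 0.24, eps_pl = 0.44, cell_density = 5e5, v_cell = 1e-12,
    body_weight = 0.02, species = "mouse"), list(...))
  do.call(system_params, args)
}

quick_tgi <- function(...) {
  args <- modifyList(list(
    t_double = 9, k_lin = 25, v_tumor_max = 3000, psi = 20, tau = 3,
    k_kill_max = 0.2, kc50 = 4000), list(...))
  do.call(tgi_params, args)
}

# lognormally jittered system/molecule pair for conservation sweeps
random_closed_pair <- function(seed) {
  set.seed(seed)
  j <- function(x, sd = 0.5) x * exp(rnorm(1, 0, sd))
  mol <- quick_mol(dar = runif(1, 1, 8),
                   k_dec = j(0.1), k_on_ab = j(50), k_off_ab = j(25),
                   k_in_pl = j(2), k_out_pl = j(1), k_on_pl = j(5),
                   k_off_pl = j(10))
  sys <- quick_sys(k_endo_her2 = j(5), k_endo_her2ab = j(5),
                   k_rec_her2 = j(8), k_rec_her2ab = j(8),
                   k_deg_her2 = j(3), k_deg_her2ab = 0,   # keep Ab closed
                   k12 = j(0.3), k21 = j(0.45),
                   k12_pl = j(15), k21_pl = j(21),
                   k_elim_ab = 0, k_elim_pl = 0,
                   r_total_per_cell = j(5e5),
                   n_healthy_central = 1e8, n_healthy_peripheral = 1e9,
                   r_healthy_per_cell = 1e4)
  list(mol = mol, sys = sys)
}

# bookkeeping helpers over in vivo trajectories ---------------------------

vivo_payload_equivalents <- function(traj, dar) {
  adc_like <- c("adc_c", "adc_p", "adc_t", "sher2adc_c", "sher2adc_p",
                "hc_her2adc_surf", "hc_her2adc_endo",
                "hp_her2adc_surf", "hp_her2adc_endo",
                "t_her2adc_surf", "t_her2adc_endo")
  pl <- c("pl_c", "pl_p", "pl_t", "t_pl_endo", "t_pl_cyto_free",
          "t_pl_cyto_bound")
  dar * rowSums(traj[, adc_like]) + rowSums(traj[, pl])
}

vivo_antibody_equivalents <- function(traj) {
  ab_like <- c("adc_c", "adc_p", "adc_t", "ab_c", "ab_p", "ab_t",
               "sher2adc_c", "sher2adc_p", "sher2ab_c", "sher2ab_p",
               "hc_her2adc_surf", "hc_her2adc_endo", "hc_her2ab_surf",
               "hc_her2ab_endo", "hp_her2adc_surf", "hp_her2adc_endo",
               "hp_her2ab_surf", "hp_her2ab_endo",
               "t_her2adc_surf", "t_her2adc_endo", "t_her2ab_surf",
               "t_her2ab_endo")
  rowSums(traj[, ab_like])
}

cell_receptor_total <- function(traj) {
  rowSums(traj[, c("her2_surf", "her2adc_surf", "her2ab_surf",
                   "her2_endo", "her2adc_endo", "her2ab_endo")])
}

cell_payload_equivalents <- function(traj, dar) {
  dar * rowSums(traj[, c("adc_media", "her2adc_surf", "her2adc_endo")]) +
    rowSums(traj[, c("pl_media", "pl_endo", "pl_cyto_free",
                     "pl_cyto_bound")])
}

rel_drift <- function(x) max(abs(x - x[1])) / abs(x[1])

# the PK / TGI parameter-recovery harnesses used by the calibration and
# acceptance tests; one replicate per seed
pk_recovery_once <- function(seed) {
  cfg <- set_params(default_config("tdm1_mouse"),
                    list("molecule.k_dec" = 0, "system.k12" = 1.0,
                         "system.k21" = 0.25))
  truth <- c("system.k_elim_ab" = cfg$system$k_elim_ab,
             "system.k12" = 1.0, "system.k21" = 0.25)
  times <- c(0.042, 0.167, 0.5, 1, 1.5, 2.5, 4, 6, 8, 11, 15, 21)
  ds <- generate_fixture(fixture_spec(cfg, "pk", times, dose_groups = 3,
                                      analytes = "adc", cv = 0.1,
                                      seed = seed))
  set.seed(seed)
  init <- truth * exp(runif(3, -0.5, 0.5))
  res <- fit(fit_problem(cfg, ds, reg = regimen(3, n_doses = 1)),
             list(fit_param("system.k_elim_ab", init[[1]]),
                  fit_param("system.k12", init[[2]]),
                  fit_param("system.k21", init[[3]])))
  abs(res$estimates - truth) / truth
}

tgi_recovery_once <- function(seed) {
  cfg <- default_config("tdm1_mouse")
  reg0 <- regimen(3, interval = 7, n_doses = 3)
  cfg$regimen <- reg0
  truth <- c("tgi.k_kill_max" = cfg$tgi$k_kill_max,
             "tgi.kc50" = cfg$tgi$kc50, "tgi.t_double" = cfg$tgi$t_double)
  doses <- c(0, 1, 3, 10, 30)
  ds <- generate_fixture(fixture_spec(cfg, "tgi",
                                      times = seq(3, 63, by = 3),
                                      dose_groups = doses, cv = 0.12,
                                      seed = seed))
  probs <- lapply(doses, function(d) {
    reg <- reg0
    reg$dose_mg_per_kg <- d
    fit_problem(cfg, observed_dataset(ds[ds$dose_group == d, ]),
                reg = reg, tumor = TRUE)
  })
  set.seed(seed + 1000)
  init <- truth * exp(runif(3, -0.4, 0.4))
  res <- fit(probs, list(fit_param("tgi.k_kill_max", init[[1]]),
                         fit_param("tgi.kc50", init[[2]]),
                         fit_param("tgi.t_double", init[[3]])))
  abs(res$estimates - truth) / truth
}
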