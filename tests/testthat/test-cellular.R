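test_that("receptor steady state matches closed form and long integration", {
  expect_equal(receptor_steady_state(quick_sys(k_endo_her2 = 0))$frac_surface,
               1)
  s <- receptor_steady_state(quick_sys(k_endo_her2 = 4, k_rec_her2 = 4,
                                       k_deg_her2 = 0))
  expect_equal(s$frac_surface, 0.5)
  expect_error(receptor_steady_state(quick_sys(k_endo_her2 = 0,
                                               k_rec_her2 = 0,
                                               k_deg_her2 = 0)),
               "degenerate")

  # generic rates: drug-free integration from an off-equilibrium split
  # relaxes to the analytic split
  sys <- quick_sys(k_endo_her2 = 3.3, k_rec_her2 = 4.7, k_deg_her2 = 1.9)
  m <- build_cellular_model(quick_mol(), sys, 1e6, 1e-3)
  rtot <- receptors_to_nmol(sys$r_total_per_cell, 1e6)
  tr <- simulate_cellular(m, seq(0, 50, by = 1),
                          initial = c(her2_surf = rtot, her2_endo = 0))
  fs <- tail(tr$her2_surf, 1) / rtot
  expect_equal(fs, receptor_steady_state(sys)$frac_surface,
               tolerance = 1e-6)
})

test_that("zero initial drug stays identically zero", {
  m <- build_cellular_model(quick_mol(), quick_sys(), 1e6, 1e-3)
  tr <- simulate_cellular(m, seq(0, 5, by = 0.5), dose_conc = 0)
  drug <- c("adc_media", "ab_media", "pl_media", "her2adc_surf",
            "her2ab_surf", "her2adc_endo", "her2ab_endo", "pl_endo",
            "pl_cyto_free", "pl_cyto_bound")
  expect_true(all(abs(as.matrix(tr[, drug])) < 1e-12))
})

test_that("equilibrium bound fraction matches the monovalent quadratic", {
  # freeze trafficking and deconjugation so only binding remains
  sys <- quick_sys(k_endo_her2 = 0, k_endo_her2ab = 0, k_deg_her2 = 0,
                   k_deg_her2ab = 0)
  mol <- quick_mol(k_dec = 0)
  n_cells <- 1e6; v_media <- 1e-3; L0 <- 2
  m <- build_cellular_model(mol, sys, n_cells, v_media)
  tr <- simulate_cellular(m, seq(0, 40, by = 1), dose_conc = L0)
  kd <- mol$k_off_ab / mol$k_on_ab
  rtot <- receptors_to_conc(sys$r_total_per_cell, n_cells, v_media)
  b <- L0 + rtot + kd
  bound_expected <- (b - sqrt(b^2 - 4 * L0 * rtot)) / 2
  bound_sim <- tail(tr$her2adc_surf, 1) / v_media
  expect_equal(bound_sim, bound_expected, tolerance = 1e-6)
})

test_that("receptor and payload totals are conserved in vitro", {
  mol <- quick_mol(linker_type = "cleavable", k_cleave = 1.5)
  m <- build_cellular_model(mol, quick_sys(), 1e6, 1e-3)
  tr <- simulate_cellular(m, seq(0, 10, by = 0.25), dose_conc = 20)
  expect_lt(rel_drift(cell_receptor_total(tr)), 1e-8)
  expect_lt(rel_drift(cell_payload_equivalents(tr, mol$dar)), 1e-6)
})

test_that("a cleavable linker with zero cleavage equals non-cleavable", {
  sys <- quick_sys()
  m1 <- build_cellular_model(quick_mol(), sys, 1e6, 1e-3)
  m2 <- build_cellular_model(quick_mol(linker_type = "cleavable",
                                       k_cleave = 0), sys, 1e6, 1e-3)
  t1 <- simulate_cellular(m1, seq(0, 7, by = 0.5), dose_conc = 10)
  t2 <- simulate_cellular(m2, seq(0, 7, by = 0.5), dose_conc = 10)
  expect_equal(as.matrix(t1), as.matrix(t2), tolerance = 1e-12)
})

test_that("faster cleavage never lowers cytosolic payload exposure", {
  sys <- quick_sys()
  aucs <- vapply(c(0.1, 1, 5), function(kc) {
    m <- build_cellular_model(quick_mol(linker_type = "cleavable",
                                        k_cleave = kc), sys, 1e6, 1e-3)
    tr <- simulate_cellular(m, seq(0, 7, by = 0.1), dose_conc = 10)
    auc_trapz(tr$time, tr$pl_cyto_free + tr$pl_cyto_bound)
  }, 0)
  expect_true(all(diff(aucs) >= 0))
})

test_that("strong target binding and slow efflux concentrate payload in cells", {
  cfg <- default_config("tdm1_invitro")
  m <- build_cellular_model(cfg$molecule, cfg$system, cfg$invitro$n_cells,
                            cfg$invitro$v_media)
  tr <- simulate_cellular(m, seq(0, cfg$invitro$duration, by = 0.1),
                          dose_conc = cfg$invitro$dose_conc)
  cc <- cellular_concentrations(tr)
  late <- cc[cc$time > 2, ]
  expect_true(all(late$payload_intracellular > late$payload_media))
})
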