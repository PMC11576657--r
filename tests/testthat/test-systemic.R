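test_that("isolated central compartment decays mono-exponentially", {
  sys <- quick_sys(k12 = 0, k21 = 0)
  mol <- quick_mol(k_dec = 0)
  m <- build_mouse_pk(mol, sys)
  tt <- seq(0, 40, by = 1)
  tr <- simulate_regimen(m, regimen(3, n_doses = 1), tt)
  dose <- dose_to_nmol(3, sys$body_weight, mol$mw_adc)
  expected <- dose * exp(-sys$k_elim_ab * tt)
  expect_equal(tr$adc_c[-1], expected[-1], tolerance = 1e-7)
  expect_equal(terminal_half_life(tr$time[-1], tr$adc_c[-1]), 11.6,
               tolerance = 1e-4)
})

test_that("full linear mouse system matches the matrix-exponential solution", {
  mol <- quick_mol(); sys <- quick_sys()
  m <- build_mouse_pk(mol, sys)
  tt <- seq(0, 21, by = 0.5)
  tr <- simulate_regimen(m, regimen(3, n_doses = 1), tt)
  a <- matrix(0, 6, 6)   # adc_c adc_p ab_c ab_p pl_c pl_p
  k12 <- sys$k12; k21 <- sys$k21; ke <- sys$k_elim_ab; kd <- mol$k_dec
  k12p <- sys$k12_pl; k21p <- sys$k21_pl; kep <- sys$k_elim_pl
  a[1, 1] <- -(k12 + ke + kd); a[1, 2] <- k21
  a[2, 1] <- k12; a[2, 2] <- -(k21 + ke + kd)
  a[3, 1] <- kd; a[3, 3] <- -(k12 + ke); a[3, 4] <- k21
  a[4, 2] <- kd; a[4, 3] <- k12; a[4, 4] <- -(k21 + ke)
  a[5, 1] <- mol$dar * kd; a[5, 5] <- -(k12p + kep); a[5, 6] <- k21p
  a[6, 2] <- mol$dar * kd; a[6, 5] <- k12p; a[6, 6] <- -(k21p + kep)
  y0 <- c(dose_to_nmol(3, sys$body_weight, mol$mw_adc), 0, 0, 0, 0, 0)
  oracle <- t(sapply(tt, function(t)
    as.numeric(Matrix::expm(a * t) %*% y0)))
  sim <- as.matrix(tr[, c("adc_c", "adc_p", "ab_c", "ab_p", "pl_c",
                          "pl_p")])
  for (j in 1:6)   # scaled per state; t = 0 row is pre-dose by convention
    expect_lt(max(abs(sim[-1, j] - oracle[-1, j])) / max(abs(oracle[, j])),
              1e-6)
})

test_that("deconjugation alone conserves payload and antibody equivalents", {
  mol <- quick_mol(k_dec = 0.5)
  sys <- quick_sys(k_elim_ab = 0, k_elim_pl = 0)
  m <- build_mouse_pk(mol, sys)
  tr <- simulate_regimen(m, regimen(3, n_doses = 1), seq(0, 30, by = 1))
  expect_lt(rel_drift(vivo_payload_equivalents(tr[-1, ], mol$dar)), 1e-6)
  expect_lt(rel_drift(vivo_antibody_equivalents(tr[-1, ])), 1e-6)
})

test_that("human model with human-only features zeroed equals mouse model", {
  mol <- quick_mol()
  sys <- quick_sys(species = "human", v_central = 3, v_peripheral = 3.1,
                   body_weight = 70)
  mh <- build_human_pk(mol, sys)
  mm <- build_mouse_pk(mol, sys)
  th <- simulate_regimen(mh, regimen(3.6), seq(0, 21, by = 0.5))
  tm <- simulate_regimen(mm, regimen(3.6), seq(0, 21, by = 0.5))
  expect_identical(as.matrix(th), as.matrix(tm))
})

test_that("healthy-cell sinks lower central ADC exposure", {
  mol <- quick_mol()
  base <- list(species = "human", v_central = 3, v_peripheral = 3.1,
               body_weight = 70, r_healthy_per_cell = 1e4,
               k_shed = 0.1)
  s_lo <- do.call(quick_sys, c(base, list(n_healthy_central = 1e9)))
  s_hi <- do.call(quick_sys, c(base, list(n_healthy_central = 2e11)))
  auc <- vapply(list(s_lo, s_hi), function(s) {
    tr <- simulate_regimen(build_human_pk(mol, s), regimen(0.3),
                           seq(0, 21, by = 0.25))
    pc <- plasma_concentrations(tr)
    auc_trapz(pc$time, pc$adc)
  }, 0)
  expect_lt(auc[2], auc[1])
})

test_that("multi-dose equals concatenated single doses with carry-over", {
  mol <- quick_mol(); sys <- quick_sys()
  m <- build_mouse_pk(mol, sys)
  reg2 <- regimen(3, interval = 7, n_doses = 2)
  tt <- seq(0, 14, by = 0.5)
  two <- simulate_regimen(m, reg2, tt)

  one <- simulate_regimen(m, regimen(3, n_doses = 1), seq(0, 7, by = 0.5))
  carry <- as.numeric(one[nrow(one), -1])
  names(carry) <- names(one)[-1]
  second <- simulate_regimen(m, regimen(3, n_doses = 1),
                             seq(7, 14, by = 0.5), initial = carry)
  expect_equal(as.numeric(two[two$time == 10.5, -1]),
               as.numeric(second[second$time == 10.5, -1]),
               tolerance = 1e-7)
})

test_that("the linear (sink-free) model obeys dose superposition", {
  m <- build_mouse_pk(quick_mol(), quick_sys())
  t1 <- simulate_regimen(m, regimen(1.5), seq(0, 21, by = 0.5))
  t2 <- simulate_regimen(m, regimen(3.0), seq(0, 21, by = 0.5))
  expect_equal(2 * as.matrix(t1[-1, -1]), as.matrix(t2[-1, -1]),
               tolerance = 1e-7)
})

test_that("infusion delivers the same total mass as a bolus", {
  mol <- quick_mol(k_dec = 0)
  sys <- quick_sys(k_elim_ab = 0, k_elim_pl = 0)
  m <- build_mouse_pk(mol, sys)
  tt <- seq(0, 10, by = 0.25)
  inf <- simulate_regimen(m, regimen(3, n_doses = 1, route = "infusion",
                                     duration = 0.5), tt)
  total <- inf$adc_c + inf$adc_p
  expect_equal(tail(total, 1), dose_to_nmol(3, sys$body_weight, mol$mw_adc),
               tolerance = 1e-6)
  # ramp during the infusion window, not a jump
  expect_lt(inf$adc_c[inf$time == 0.25], 0.75 * tail(total, 1))
})

test_that("dosing events outside the grid are rejected", {
  m <- build_mouse_pk(quick_mol(), quick_sys())
  expect_error(simulate_regimen(m, regimen(3, interval = 21, n_doses = 3),
                                seq(0, 30, by = 1)),
               "outside")
})
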