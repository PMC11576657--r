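grow_ode <- function(p, v0, times) {
  deSolve::ode(c(v = v0), times,
               function(t, y, parms) list(growth_rate(y[1], y[1], p)),
               NULL, rtol = 1e-10, atol = 1e-12)
}

test_that("untreated growth doubles every t_double in the exponential regime", {
  p <- quick_tgi(t_double = 9, k_lin = 1e6, v_tumor_max = 1e9)
  out <- grow_ode(p, 1, seq(0, 30, by = 0.01))
  t2 <- approx(out[, "v"], out[, "time"], xout = 2)$y
  expect_equal(t2, 9, tolerance = 0.01)
})

test_that("growth approaches k_lin in the linear regime", {
  p <- quick_tgi(t_double = 9, k_lin = 25, v_tumor_max = 1e6)
  out <- grow_ode(p, 2000, seq(0, 20, by = 0.1))
  slope <- diff(range(out[, "v"])) / 20
  expect_equal(slope, 25, tolerance = 0.05)
})

test_that("growth stops at the maximum tumor volume", {
  p <- quick_tgi()
  expect_equal(growth_rate(p$v_tumor_max, p$v_tumor_max, p), 0)
  expect_warning(g <- growth_rate(3100, 3100, quick_tgi()), "clipped")
  expect_lte(g, 0)
})

test_that("kill rate is Michaelis-Menten with half-max at kc50", {
  p <- quick_tgi(k_kill_max = 0.8, kc50 = 12)
  expect_equal(kill_rate(0, p), 0)
  expect_equal(kill_rate(12, p), 0.4)
  expect_equal(kill_rate(1e9, p), 0.8, tolerance = 1e-6)
  cs <- seq(0, 100, by = 5)
  expect_true(all(diff(kill_rate(cs, p)) > 0))
})

test_that("transit cascade stays empty without kill and has mean delay tau", {
  p <- quick_tgi(tau = 3)
  d <- transit_cascade(c(n1 = 100, n2 = 0, n3 = 0, n4 = 0), kill = 0, p)
  expect_equal(unname(d), c(0, 0, 0, 0))

  # pulse of mass into N2: exit flux is Erlang(3, 3/tau); mean exit time tau
  rhs <- function(t, y, parms) {
    d <- transit_cascade(c(n1 = 0, y), kill = 0, p)
    list(d[-1])
  }
  times <- seq(0, 60, by = 0.02)
  out <- deSolve::ode(c(n2 = 1, n3 = 0, n4 = 0), times, rhs, NULL,
                      rtol = 1e-10, atol = 1e-12)
  exit_flux <- (3 / p$tau) * out[, "n4"]
  mean_exit <- auc_trapz(times, times * exit_flux) /
    auc_trapz(times, exit_flux)
  expect_equal(mean_exit, p$tau, tolerance = 0.01)
})

test_that("constant kill on frozen N1 removes mass at rate kill * N1", {
  p <- quick_tgi(tau = 2)
  k <- 0.05; n1 <- 100
  rhs <- function(t, y, parms) {
    d <- transit_cascade(c(n1 = n1, y), kill = k, p)
    list(d[-1])
  }
  times <- seq(0, 80, by = 0.05)
  out <- deSolve::ode(c(n2 = 0, n3 = 0, n4 = 0), times, rhs, NULL,
                      rtol = 1e-10, atol = 1e-12)
  cum_killed <- auc_trapz(times, (3 / p$tau) * out[, "n4"])
  # linear chain at steady throughput: cumulative exit ~ k*N1*(t - tau)
  expect_equal(cum_killed, k * n1 * (max(times) - p$tau), tolerance = 0.01)
})

test_that("compiled growth matches the reference growth law", {
  cfg <- default_config("tdm1_mouse")
  m <- couple_tumor(build_mouse_pk(cfg$molecule, cfg$system), cfg$tgi)
  tv <- simulate_tgi(m, regimen(0, n_doses = 1), seq(0, 40, by = 0.5))
  out <- grow_ode(cfg$tgi, cfg$system$v_tumor_init, seq(0, 40, by = 0.5))
  expect_equal(tv$tumor_volume, unname(out[, "v"]), tolerance = 1e-6)
})

test_that("vehicle keeps the transit compartments empty", {
  cfg <- default_config("tdm1_mouse")
  m <- couple_tumor(build_mouse_pk(cfg$molecule, cfg$system), cfg$tgi)
  tr <- simulate_regimen(m, regimen(0, n_doses = 1), seq(0, 40, by = 1))
  expect_true(all(abs(as.matrix(tr[, c("n2", "n3", "n4")])) < 1e-10))
})

test_that("higher dose gives no larger tumor burden", {
  cfg <- default_config("tdm1_mouse")
  m <- couple_tumor(build_mouse_pk(cfg$molecule, cfg$system), cfg$tgi)
  grid <- sort(unique(c(seq(0, 42, by = 1), c(0, 7, 14))))
  aucs <- vapply(c(0, 1, 3, 10), function(d) {
    tv <- simulate_tgi(m, regimen(d, interval = 7, n_doses = 3), grid,
                       solver = list(rtol = 1e-6, atol = 1e-9))
    auc_trapz(tv$time, tv$tumor_volume)
  }, 0)
  expect_true(all(diff(aucs) < 0))
})

test_that("tumor volume stays within [0, v_max] and respects the cap", {
  cfg <- default_config("tdm1_mouse")
  cfg <- set_params(cfg, list("system.v_tumor_init" = 2950))
  m <- couple_tumor(build_mouse_pk(cfg$molecule, cfg$system), cfg$tgi)
  tv <- simulate_tgi(m, regimen(0, n_doses = 1), seq(0, 120, by = 1))
  expect_true(all(tv$tumor_volume >= 0))
  expect_true(all(tv$tumor_volume <= cfg$tgi$v_tumor_max * (1 + 1e-6)))
})
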