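# Reference implementations of the tumor growth / kill / transit algebra
# and of the Krogh exchange terms.  The compiled in vivo model implements
# the same formulas; tests cross-check the two.

#' Tumor geometry derived from volume
#'
#' @param v_tumor tumor volume (mm^3)
#' @param sys optional `system_params` supplying `cell_density`
#' @return list with `v_tumor` (mm^3), `r_tumor_cm` (equivalent spherical
#'   radius, cm) and, when `sys` is given, `n_cells`
#' @export
tumor_geometry <- function(v_tumor, sys = NULL) {
  .assert_scalar(v_tumor, "v_tumor", nonneg = TRUE)
  r_mm <- (3 * v_tumor / (4 * pi))^(1 / 3)
  out <- list(v_tumor = v_tumor, r_tumor_cm = r_mm * 0.1)
  if (!is.null(sys)) out$n_cells <- sys$cell_density * v_tumor
  out
}

#' Plasma-tumor exchange rate constants
#'
#' Surface exchange `6 D / R_tumor^2` dominates for small (avascular)
#' tumors; vascular exchange `2 P R_cap / R_krogh^2` (Krogh cylinder)
#' dominates for large vascularized tumors.  The default combination is
#' their sum; `mode = "switch"` takes the dominant term only.
#'
#' @param geom a [tumor_geometry()] result (or list with `r_tumor_cm`)
#' @param d diffusivity (cm^2/day)
#' @param p vascular permeability (cm/day)
#' @param r_cap capillary radius (cm)
#' @param r_krogh Krogh cylinder radius (cm)
#' @param mode `"sum"` or `"switch"`
#' @return list with `k_surface`, `k_vascular`, `k_combined` (1/day)
#' @export
exchange_rate <- function(geom, d, p, r_cap, r_krogh,
                          mode = c("sum", "switch")) {
  mode <- match.arg(mode)
  for (nm in c("d", "p", "r_cap", "r_krogh"))
    .assert_scalar(get(nm), nm, positive = TRUE)
  r <- geom$r_tumor_cm
  if (r <= 0)
    stop("degenerate tumor geometry: R_tumor = 0 (surface term unbounded)",
         call. = FALSE)
  ks <- 6 * d / r^2
  kv <- 2 * p * r_cap / r_krogh^2
  list(k_surface = ks, k_vascular = kv,
       k_combined = if (mode == "sum") ks + kv else max(ks, kv))
}

#' Net growth contribution to the proliferating mass
#'
#' `k_exp N1 / (1 + (k_exp V / k_lin)^psi)^(1/psi) * (1 - V / V_max)` with
#' `k_exp = ln 2 / t_double`: exponential growth of small tumors, linear
#' growth (`k_lin`) of intermediate ones, and a logistic cap at
#' `v_tumor_max`.
#'
#' @param n1 proliferating cell mass (mm^3)
#' @param v_tumor total tumor volume (mm^3)
#' @param p a `tgi_params`
#' @return dN1/dt growth contribution (mm^3/day)
#' @export
growth_rate <- function(n1, v_tumor, p) {
  stopifnot(inherits(p, "tgi_params"), n1 >= 0, v_tumor >= 0)
  if (v_tumor > p$v_tumor_max)
    warning("tumor volume exceeds v_tumor_max; growth clipped at <= 0")
  k_exp <- log(2) / p$t_double
  sw <- (1 + (k_exp * v_tumor / p$k_lin)^p$psi)^(1 / p$psi)
  k_exp * n1 / sw * (1 - v_tumor / p$v_tumor_max)
}

#' Michaelis-Menten kill rate from intracellular payload concentration
#'
#' @param c_pl intracellular unconjugated payload concentration (nM), >= 0
#' @param p a `tgi_params`
#' @return per-unit-mass kill rate (1/day), saturating at `k_kill_max`
#' @export
kill_rate <- function(c_pl, p) {
  stopifnot(inherits(p, "tgi_params"), all(c_pl >= 0))
  p$k_kill_max * c_pl / (p$kc50 + c_pl)
}

#' Transit-cascade derivatives of the four tumor cell states
#'
#' Kill moves proliferating mass N1 into a three-step death cascade
#' N2 -> N3 -> N4 -> (removed), each step at rate `3/tau` so the cascade's
#' mean residence time is `tau` (Erlang-3).  N2-N4 do not proliferate.
#'
#' @param states named list/vector with `n1`, `n2`, `n3`, `n4` (mm^3)
#' @param kill per-unit-mass kill rate (1/day)
#' @param p a `tgi_params`
#' @param single_transit use `1/tau` per step instead of `3/tau`
#' @return named vector of derivatives (growth not included)
#' @export
transit_cascade <- function(states, kill, p, single_transit = FALSE) {
  stopifnot(inherits(p, "tgi_params"))
  if (p$tau <= 0) stop("tau must be > 0", call. = FALSE)
  kt <- if (single_transit) 1 / p$tau else 3 / p$tau
  s <- as.list(states)
  c(n1 = -kill * s$n1,
    n2 = kill * s$n1 - kt * s$n2,
    n3 = kt * (s$n2 - s$n3),
    n4 = kt * (s$n3 - s$n4))
}
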