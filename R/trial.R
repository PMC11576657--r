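# Virtual clinical trials: lognormal virtual populations over the growth
# and kill parameters, per-patient coupled PK-TGI simulation, RECIST
# classification of tumor diameters at scheduled assessments, exponential
# dropout censoring, and the product-limit PFS curve.

#' Virtual population specification
#'
#' @param tgi nominal `tgi_params`
#' @param cv named list/vector of coefficients of variation for any of
#'   `t_double`, `k_lin`, `k_kill_max`, `kc50` (lognormal, median-preserving)
#' @param n_patients number of virtual patients
#' @param her2_receptors_per_cell HER2 stratum (receptors/cell)
#' @return a `population_spec`
#' @export
population_spec <- function(tgi, cv = list(), n_patients,
                            her2_receptors_per_cell = 1e6) {
  stopifnot(inherits(tgi, "tgi_params"), n_patients >= 1)
  cv <- as.list(cv)
  bad <- setdiff(names(cv), c("t_double", "k_lin", "k_kill_max", "kc50"))
  if (length(bad))
    stop("unknown CV name(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if (any(unlist(cv) < 0)) stop("CVs must be >= 0", call. = FALSE)
  structure(list(tgi = tgi, cv = cv, n_patients = as.integer(n_patients),
                 her2_receptors_per_cell = her2_receptors_per_cell),
            class = "population_spec")
}

#' Sample a virtual patient population
#'
#' Independent lognormal draws about the nominal value for each varied
#' parameter.  The lognormal is median-preserving (`meanlog = log(nominal)`)
#' with `sdlog = sqrt(log(1 + CV^2))`, so the sample coefficient of
#' variation matches the specified CV.
#'
#' @param spec a [population_spec()]
#' @return data frame with one row per patient and columns `t_double`,
#'   `k_lin`, `k_kill_max`, `kc50`
#' @export
sample_population <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  n <- spec$n_patients
  out <- data.frame(patient = seq_len(n))
  for (nm in c("t_double", "k_lin", "k_kill_max", "kc50")) {
    nominal <- spec$tgi[[nm]]
    cv <- spec$cv[[nm]]
    if (is.null(cv) || cv == 0) {
      out[[nm]] <- rep(nominal, n)
    } else {
      sdlog <- sqrt(log(1 + cv^2))
      out[[nm]] <- rlnorm(n, meanlog = log(nominal), sdlog = sdlog)
    }
  }
  out
}

#' RECIST-style classification of a tumor diameter against baseline
#'
#' Categories (applied in priority order CR > PD > PR > SD, all relative to
#' baseline): complete response, diameter < 10 mm; progressive disease,
#' > 20% increase from baseline AND absolute increase > 5 mm; partial
#' response, > 30% decrease from baseline; stable disease otherwise.
#'
#' @param baseline_d baseline diameter (mm), > 0
#' @param current_d current diameter (mm), > 0 (vectorized)
#' @return character vector in `c("CR", "PR", "SD", "PD")`
#' @export
recist_classify <- function(baseline_d, current_d) {
  stopifnot(baseline_d > 0, all(current_d > 0))
  change <- (current_d - baseline_d) / baseline_d
  ifelse(current_d < 10, "CR",
         ifelse(change > 0.20 & (current_d - baseline_d) > 5, "PD",
                ifelse(change < -0.30, "PR", "SD")))
}

#' Sample independent exponential dropout (censoring) times
#'
#' @param dropout_rate exponential rate (1/day), >= 0; a rate of 0 returns
#'   infinite times (no censoring)
#' @param n number of patients
#' @param seed optional seed applied before drawing
#' @return vector of censoring times (day)
#' @export
censor_sample <- function(dropout_rate, n, seed = NULL) {
  stopifnot(dropout_rate >= 0, n >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (dropout_rate == 0) return(rep(Inf, n))
  rexp(n, rate = dropout_rate)
}

#' Progression-free survival curve (product-limit estimator)
#'
#' At each event time the interval survival rate is the number of at-risk
#' patients after the events divided by the number at risk during the
#' interval; the running product of interval rates gives the survival
#' probability.  Censored patients leave the risk set without contributing
#' events.  This is the Kaplan-Meier product-limit estimator.
#'
#' @param event_times per-patient progression times (NA when no event)
#' @param censor_times per-patient censoring times (NA or Inf when not
#'   censored); a patient may have an event or a censor time, not both
#' @param trial_end end of the observation window; patients with neither
#'   event nor censoring are censored here
#' @return data frame with `time`, `survival` (percent, starting at 100),
#'   `n_risk`, `n_event`, `n_censored`
#' @export
pfs_curve <- function(event_times, censor_times, trial_end) {
  n <- length(event_times)
  stopifnot(length(censor_times) == n, trial_end > 0)
  censor_times[is.na(censor_times)] <- Inf
  if (any(!is.na(event_times) & is.finite(censor_times)))
    stop("a patient cannot have both an event and a censor time recorded",
         call. = FALSE)
  obs_time <- pmin(ifelse(is.na(event_times), Inf, event_times),
                   censor_times, trial_end)
  status <- !is.na(event_times) & event_times <= pmin(censor_times,
                                                      trial_end)
  if (any(obs_time <= 0)) stop("all times must be > 0", call. = FALSE)

  ev_times <- sort(unique(obs_time[status]))
  surv <- 100
  out <- data.frame(time = 0, survival = 100, n_risk = n, n_event = 0,
                    n_censored = 0)
  for (tt in ev_times) {
    at_risk <- sum(obs_time >= tt)
    d <- sum(obs_time == tt & status)
    cns <- sum(obs_time == tt & !status)
    surv <- surv * (at_risk - d) / at_risk
    out <- rbind(out, data.frame(time = tt, survival = surv,
                                 n_risk = at_risk, n_event = d,
                                 n_censored = cns))
  }
  structure(out, class = c("pfs_curve", "data.frame"))
}

#' Survival percentage at given times from a PFS curve
#' @param curve a [pfs_curve()] result
#' @param times query times
#' @return survival percentages (step function, right-continuous)
#' @export
pfs_at <- function(curve, times) {
  idx <- findInterval(times, curve$time)
  curve$survival[pmax(idx, 1)]
}

#' Run a virtual clinical trial
#'
#' Samples a virtual population, simulates each patient's coupled
#' PK-tumor-TGI trajectory under the configured regimen, classifies RECIST
#' response from the equivalent spherical tumor diameter at each scheduled
#' assessment, records the first progressive disease as the event (at the
#' assessment where it is observed), applies exponential dropout
#' censoring, and computes the PFS curve.
#'
#' @param config an `adc_config` containing `trial`, `tgi` and `regimen`
#'   sections (see e.g. `default_config("trial_tdm1_ph2")`)
#' @param seed RNG seed controlling population sampling and censoring
#' @param her2_receptors_per_cell optional stratum override (receptors/cell)
#' @param solver solver options; trials default to `rtol 1e-6 / atol 1e-9`
#' @param max_fail_frac abort when more than this fraction of patient
#'   simulations fail (default 0.05)
#' @return a `trial_result`: `patients` (draws, baseline/event/censor
#'   data), `diameters` (patients x assessments matrix), `assessments`,
#'   `pfs` curve and `summary`
#' @export
run_trial <- function(config, seed = 1, her2_receptors_per_cell = NULL,
                      solver = list(rtol = 1e-6, atol = 1e-9),
                      max_fail_frac = 0.05) {
  stopifnot(inherits(config, "adc_config"))
  tr <- config$trial
  if (is.null(tr) || is.null(config$tgi) || is.null(config$regimen))
    stop("trial config needs 'trial', 'tgi' and 'regimen' sections",
         call. = FALSE)
  stratum <- if (!is.null(her2_receptors_per_cell)) her2_receptors_per_cell
             else tr$her2_receptors_per_cell
  config <- set_params(config, list("system.r_total_per_cell" = stratum))

  set.seed(seed)
  pop_seed <- sample.int(2^31 - 1, 1)
  censor_seed <- sample.int(2^31 - 1, 1)

  spec <- population_spec(config$tgi, tr$cv, tr$n_patients, stratum)
  set.seed(pop_seed)
  pop <- sample_population(spec)

  assessments <- seq(tr$assessment_interval, tr$duration,
                     by = tr$assessment_interval)
  reg <- config$regimen
  n_doses <- min(reg$n_doses, floor(tr$duration / reg$interval) + 1)
  reg$n_doses <- as.integer(n_doses)
  dose_times <- (seq_len(n_doses) - 1) * reg$interval
  grid <- sort(unique(c(0, dose_times, assessments, tr$duration)))

  baseline_d <- volume_to_diameter(config$system$v_tumor_init)
  diam <- matrix(NA_real_, tr$n_patients, length(assessments))
  failed <- 0L
  for (i in seq_len(tr$n_patients)) {
    cfg_i <- set_params(config, list(
      "tgi.t_double" = pop$t_double[i], "tgi.k_lin" = pop$k_lin[i],
      "tgi.k_kill_max" = pop$k_kill_max[i], "tgi.kc50" = pop$kc50[i]))
    model <- if (cfg_i$system$species == "human")
      build_human_pk(cfg_i$molecule, cfg_i$system)
    else build_mouse_pk(cfg_i$molecule, cfg_i$system)
    model <- couple_tumor(model, cfg_i$tgi)
    tv <- try(suppressWarnings(simulate_tgi(model, reg, grid,
                                            solver = solver)),
              silent = TRUE)
    if (inherits(tv, "try-error")) {
      failed <- failed + 1L
      next
    }
    diam[i, ] <- approx(tv$time, tv$tumor_diameter, xout = assessments)$y
  }
  if (failed > max_fail_frac * tr$n_patients)
    stop(sprintf("%d/%d patient simulations failed", failed,
                 tr$n_patients), call. = FALSE)

  event_time <- rep(NA_real_, tr$n_patients)
  recist <- matrix(NA_character_, tr$n_patients, length(assessments))
  for (i in seq_len(tr$n_patients)) {
    if (any(is.na(diam[i, ]))) next
    recist[i, ] <- recist_classify(baseline_d, diam[i, ])
    pd <- which(recist[i, ] == "PD")
    if (length(pd)) event_time[i] <- assessments[pd[1]]
  }

  dropout <- censor_sample(tr$dropout_rate, tr$n_patients,
                           seed = censor_seed)
  censor_time <- rep(NA_real_, tr$n_patients)
  has_event <- !is.na(event_time) & event_time <= pmin(dropout, tr$duration)
  censor_time[!has_event] <- pmin(dropout[!has_event], tr$duration)
  event_time[!has_event] <- NA_real_

  pfs <- pfs_curve(event_time, censor_time, tr$duration)
  med_idx <- which(pfs$survival <= 50)
  patients <- cbind(pop,
                    data.frame(baseline_diameter = baseline_d,
                               event_time = event_time,
                               censor_time = censor_time,
                               event = !is.na(event_time)))
  structure(list(patients = patients, diameters = diam, recist = recist,
                 assessments = assessments, pfs = pfs,
                 summary = list(
                   n_patients = tr$n_patients,
                   n_events = sum(!is.na(event_time)),
                   n_failed = failed,
                   her2_receptors_per_cell = stratum,
                   median_pfs = if (length(med_idx))
                     pfs$time[med_idx[1]] else NA_real_),
                 seed = seed),
            class = "trial_result")
}

#' @export
print.trial_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<trial_result> %d patients (HER2 %.2g/cell): %d events, median PFS %s d\n",
    s$n_patients, s$her2_receptors_per_cell, s$n_events,
    if (is.na(s$median_pfs)) "not reached" else sprintf("%.0f",
                                                        s$median_pfs)))
  invisible(x)
}

#' Plot a PFS curve
#' @param x a `pfs_curve` or `trial_result`
#' @param ... additional step-function layers are not supported; ignored
#' @return a ggplot object
#' @export
plot_pfs <- function(x, ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_pfs requires ggplot2", call. = FALSE)
  curve <- if (inherits(x, "trial_result")) x$pfs else x
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$time, y = .data$survival)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "time (days)", y = "progression-free survival (%)") +
    ggplot2::ylim(0, 100)
}
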