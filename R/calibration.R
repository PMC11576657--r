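# Weighted least-squares calibration of selected parameters against tidy
# observed time-series, with parameters shared across datasets or local to
# one dataset (e.g. a per-ADC deconjugation rate in a joint fit).

#' Construct/validate a tidy observed dataset
#'
#' @param df data frame with columns `time`, `analyte`, `compartment`,
#'   `value` and optionally `dose_group`, `unit`, `weight`
#' @param source free-text label for provenance
#' @return the validated data frame with class `observed_dataset`
#' @export
observed_dataset <- function(df, source = NULL) {
  need <- c("time", "analyte", "compartment", "value")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("observed dataset lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(df$time < 0)) stop("observation times must be >= 0", call. = FALSE)
  if (any(df$value < 0)) stop("observed values must be >= 0", call. = FALSE)
  if (is.null(df$dose_group)) df$dose_group <- 1
  structure(as.data.frame(df),
            class = c("observed_dataset", "data.frame"), source = source)
}

#' Declare a parameter to estimate
#'
#' @param name `"section.name"` configuration path (canonical units)
#' @param init initial value (> 0; fitting is on the log scale)
#' @param lower,upper box bounds (> 0)
#' @param problems indices of the problems this parameter is local to;
#'   `NULL` (default) shares one value across all problems
#' @return a `fit_param` specification
#' @export
fit_param <- function(name, init, lower = init / 100, upper = init * 100,
                      problems = NULL) {
  stopifnot(init > 0, lower > 0, upper >= lower, init >= lower,
            init <= upper)
  structure(list(name = name, init = init, lower = lower, upper = upper,
                 problems = problems), class = "fit_param")
}

#' Declare one calibration problem
#'
#' @param config an `adc_config` holding the generating model
#' @param data an [observed_dataset()]
#' @param reg a `regimen`; defaults to `config$regimen`
#' @param type `"invivo"` (mouse/human PK, optionally tumor-coupled) or
#'   `"invitro"`
#' @param tumor couple the tumor compartment (`TRUE` automatically when the
#'   data reference the tumor)
#' @return a `fit_problem`
#' @export
fit_problem <- function(config, data, reg = NULL,
                        type = c("invivo", "invitro"), tumor = NULL) {
  type <- match.arg(type)
  stopifnot(inherits(config, "adc_config"),
            inherits(data, "observed_dataset"))
  if (is.null(reg) && type == "invivo") reg <- config$regimen
  if (is.null(tumor))
    tumor <- any(data$compartment %in% c("tumor", "intracellular") |
                   data$analyte == "tumor_volume")
  structure(list(config = config, data = data, reg = reg, type = type,
                 tumor = tumor), class = "fit_problem")
}

.build_problem_model <- function(cfg, prob) {
  if (prob$type == "invitro") {
    iv <- cfg$invitro
    if (is.null(iv)) stop("config has no invitro section", call. = FALSE)
    return(build_cellular_model(cfg$molecule, cfg$system, iv$n_cells,
                                iv$v_media))
  }
  m <- if (cfg$system$species == "human")
    build_human_pk(cfg$molecule, cfg$system)
  else build_mouse_pk(cfg$molecule, cfg$system)
  if (prob$tumor) m <- couple_tumor(m, cfg$tgi)
  m
}

.predict_rows <- function(cfg, prob, rows, solver) {
  t_obs <- sort(unique(rows$time))
  if (prob$type == "invitro") {
    model <- .build_problem_model(cfg, prob)
    grid <- sort(unique(c(0, t_obs)))
    traj <- simulate_cellular(model, grid, dose_conc = cfg$invitro$dose_conc,
                              solver = solver)
    conc <- cellular_concentrations(traj)
    lookup <- function(analyte, compartment) {
      col <- switch(paste(analyte, compartment, sep = "/"),
                    "adc/media" = "adc_media",
                    "total_ab/media" = "ab_media",
                    "payload/media" = "payload_media",
                    "payload/intracellular" = "payload_intracellular",
                    stop(sprintf("unsupported in vitro analyte '%s' in '%s'",
                                 analyte, compartment), call. = FALSE))
      conc[[col]]
    }
    times <- conc$time
  } else {
    model <- .build_problem_model(cfg, prob)
    reg <- prob$reg
    dose_times <- (seq_len(reg$n_doses) - 1) * reg$interval
    grid <- sort(unique(c(0, dose_times, t_obs, max(t_obs, dose_times))))
    traj <- simulate_regimen(model, reg, grid, solver = solver)
    pc <- plasma_concentrations(traj, "central")
    pp <- plasma_concentrations(traj, "peripheral")
    tu <- if (prob$tumor) tumor_observables(traj) else NULL
    lookup <- function(analyte, compartment) {
      if (compartment == "central") return(pc[[analyte]])
      if (compartment == "peripheral") return(pp[[analyte]])
      if (is.null(tu))
        stop("tumor observation on a model without tumor", call. = FALSE)
      switch(paste(analyte, compartment, sep = "/"),
             "payload/tumor" = tu$payload_tumor_total_conc,
             "payload/intracellular" = tu$payload_intra_total_conc,
             "tumor_volume/tumor" = tu$tumor_volume,
             stop(sprintf("unsupported analyte '%s' in '%s'", analyte,
                          compartment), call. = FALSE))
    }
    times <- traj$time
  }
  pred <- numeric(nrow(rows))
  for (key in unique(paste(rows$analyte, rows$compartment))) {
    sel <- paste(rows$analyte, rows$compartment) == key
    a <- rows$analyte[sel][1]; cmp <- rows$compartment[sel][1]
    series <- lookup(a, cmp)
    pred[sel] <- approx(times, series, xout = rows$time[sel],
                        rule = 2)$y
  }
  pred
}

#' Fit model parameters to observed datasets
#'
#' Minimizes the sum of squared residuals (log-scale by default, suited to
#' PK spanning decades) over one or more calibration problems with a
#' Levenberg-Marquardt search on log-transformed, box-bounded parameters.
#' Parameters may be shared across problems or local to specific problems.
#'
#' @param problems list of [fit_problem()] objects (a single problem may be
#'   passed bare)
#' @param params list of [fit_param()] specifications
#' @param residual `"log"` (default), `"proportional"` or `"absolute"`
#' @param solver solver options forwarded to the simulators; calibration
#'   defaults to `rtol 1e-6 / atol 1e-9` for speed
#' @param control passed to [minpack.lm::nls.lm.control()]
#' @return a `fit_result`: estimates, objective, convergence flag,
#'   residual/observed-vs-predicted table, objective trace and bounds
#' @export
fit <- function(problems, params, residual = c("log", "proportional",
                                               "absolute"),
                solver = list(rtol = 1e-6, atol = 1e-9),
                control = list(maxiter = 100, epsfcn = 1e-6)) {
  residual <- match.arg(residual)
  if (inherits(problems, "fit_problem")) problems <- list(problems)
  stopifnot(length(problems) >= 1,
            all(vapply(problems, inherits, TRUE, "fit_problem")),
            length(params) >= 1,
            all(vapply(params, inherits, TRUE, "fit_param")))

  # expand shared/local parameters into one optimization vector
  comp <- list()
  for (p in params) {
    idx <- if (is.null(p$problems)) seq_along(problems) else p$problems
    if (is.null(p$problems))
      comp[[length(comp) + 1]] <- list(name = p$name, problems = idx,
                                       init = p$init, lower = p$lower,
                                       upper = p$upper,
                                       label = p$name)
    else for (i in idx)
      comp[[length(comp) + 1]] <- list(name = p$name, problems = i,
                                       init = p$init, lower = p$lower,
                                       upper = p$upper,
                                       label = sprintf("%s@%d", p$name, i))
  }
  labels <- vapply(comp, `[[`, "", "label")
  n_obs <- sum(vapply(problems, function(pr) nrow(pr$data), 0L))
  if (length(comp) > n_obs)
    warning(sprintf(
      "more parameters (%d) than observations (%d): non-identifiable fit",
      length(comp), n_obs))

  apply_theta <- function(theta) {
    vals <- exp(theta)
    lapply(seq_along(problems), function(i) {
      upd <- list()
      for (j in seq_along(comp))
        if (i %in% comp[[j]]$problems) upd[[comp[[j]]$name]] <- vals[j]
      if (length(upd)) set_params(problems[[i]]$config, upd)
      else problems[[i]]$config
    })
  }

  resid_fun <- function(obs, pred, w) {
    r <- switch(residual,
                log = log(pmax(pred, 1e-12)) - log(pmax(obs, 1e-12)),
                proportional = (pred - obs) / pmax(obs, 1e-12),
                absolute = pred - obs)
    r * sqrt(w)
  }

  trace <- numeric()
  objective <- function(theta) {
    cfgs <- apply_theta(theta)
    r <- unlist(lapply(seq_along(problems), function(i) {
      pr <- problems[[i]]
      w <- if (is.null(pr$data$weight)) rep(1, nrow(pr$data))
           else pr$data$weight
      pred <- .predict_rows(cfgs[[i]], pr, pr$data, solver)
      resid_fun(pr$data$value, pred, w)
    }))
    trace <<- c(trace, sum(r^2))
    r
  }

  th0 <- log(vapply(comp, `[[`, 0, "init"))
  lo <- log(vapply(comp, `[[`, 0, "lower"))
  hi <- log(vapply(comp, `[[`, 0, "upper"))
  res <- minpack.lm::nls.lm(par = th0, lower = lo, upper = hi,
                            fn = objective,
                            control = do.call(minpack.lm::nls.lm.control,
                                              control))
  est <- setNames(exp(res$par), labels)

  cfgs <- apply_theta(res$par)
  ovp <- do.call(rbind, lapply(seq_along(problems), function(i) {
    pr <- problems[[i]]
    data.frame(problem = i, time = pr$data$time, analyte = pr$data$analyte,
               compartment = pr$data$compartment,
               dose_group = pr$data$dose_group, observed = pr$data$value,
               predicted = .predict_rows(cfgs[[i]], pr, pr$data, solver))
  }))

  jac <- res$hessian
  cond <- tryCatch(kappa(jac, exact = TRUE), error = function(e) NA_real_)
  converged <- res$info %in% 1:4
  if (!converged)
    warning("fit did not converge: ", res$message)
  structure(list(estimates = est, objective = res$deviance,
                 converged = converged, info = res$info,
                 message = res$message, residual_type = residual,
                 obs_vs_pred = ovp, trace = trace,
                 rsstrace = res$rsstrace,
                 bounds = data.frame(label = labels, lower = exp(lo),
                                     upper = exp(hi)),
                 condition_number = cond),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> objective %.6g, %sconverged\n", x$objective,
              if (x$converged) "" else "NOT "))
  print(x$estimates)
  invisible(x)
}
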