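# Global sensitivity analysis: Latin hypercube sampling over parameter
# ranges and partial rank correlation coefficients against a scalar
# simulation output (tumor volume AUC by default).

#' Specification of an LHS-PRCC study
#'
#' @param parameters list of entries `list(name, lower, upper, dist)` where
#'   `name` is a `"section.name"` config path and `dist` is `"uniform"`
#'   (default) or `"loguniform"`
#' @param n_samples number of LHS samples (must exceed the number of
#'   parameters by at least 2)
#' @param seed RNG seed for the design
#' @param output scalar output functional; currently
#'   `"tumor_volume_auc"`
#' @param window AUC window length (day)
#' @return a `prcc_spec`
#' @export
prcc_spec <- function(parameters, n_samples = 1000, seed = 1,
                      output = "tumor_volume_auc", window = 84) {
  stopifnot(length(parameters) >= 1)
  parameters <- lapply(parameters, function(p) {
    if (is.null(p$dist)) p$dist <- "uniform"
    stopifnot(!is.null(p$name), p$dist %in% c("uniform", "loguniform"))
    if (!(p$lower < p$upper))
      stop(sprintf("parameter '%s': lower must be < upper", p$name),
           call. = FALSE)
    if (p$dist == "loguniform" && p$lower <= 0)
      stop(sprintf("parameter '%s': loguniform needs lower > 0", p$name),
           call. = FALSE)
    p
  })
  if (n_samples < length(parameters) + 2)
    stop("n_samples must be >= number of parameters + 2", call. = FALSE)
  structure(list(parameters = parameters, n_samples = as.integer(n_samples),
                 seed = as.integer(seed), output = output, window = window),
            class = "prcc_spec")
}

#' Latin hypercube design for a PRCC study
#'
#' One sample per equiprobable stratum per dimension, with independent
#' random permutations across dimensions, mapped through each parameter's
#' marginal distribution.  Seeded and reproducible.
#'
#' @param spec a [prcc_spec()]
#' @return `n_samples x n_params` numeric matrix with parameter-path column
#'   names
#' @export
lhs_sample <- function(spec) {
  stopifnot(inherits(spec, "prcc_spec"))
  set.seed(spec$seed)
  u <- lhs::randomLHS(spec$n_samples, length(spec$parameters))
  x <- matrix(NA_real_, nrow(u), ncol(u),
              dimnames = list(NULL,
                              vapply(spec$parameters, `[[`, "", "name")))
  for (j in seq_along(spec$parameters)) {
    p <- spec$parameters[[j]]
    x[, j] <- if (p$dist == "uniform")
      p$lower + u[, j] * (p$upper - p$lower)
    else
      exp(log(p$lower) + u[, j] * (log(p$upper) - log(p$lower)))
  }
  x
}

#' Partial rank correlation coefficients
#'
#' Rank-transforms inputs and output, then correlates, for each parameter,
#' the residuals of its ranks and the output's ranks after linear
#' adjustment for all remaining parameters.  Approximate p-values use the
#' t distribution with `n - k - 1` degrees of freedom (k adjusting
#' covariates plus the correlate).
#'
#' @param x design matrix (no constant columns)
#' @param y output vector
#' @return data frame with `parameter`, `prcc`, `p_value`
#' @export
prcc <- function(x, y) {
  x <- as.matrix(x)
  n <- nrow(x); np <- ncol(x)
  stopifnot(length(y) == n, n > np + 2)
  if (any(apply(x, 2, function(col) length(unique(col)) == 1)))
    stop("design contains constant column(s)", call. = FALSE)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(np))
  rx <- apply(x, 2, rank)
  ry <- rank(y)
  out <- data.frame(parameter = colnames(x), prcc = NA_real_,
                    p_value = NA_real_)
  for (j in seq_len(np)) {
    others <- rx[, -j, drop = FALSE]
    if (ncol(others)) {
      q <- qr(cbind(1, others))
      if (q$rank < ncol(others) + 1)
        stop("rank-deficient adjusted design; collinear parameter(s): ",
             paste(colnames(x)[-j], collapse = ", "), call. = FALSE)
      ej <- qr.resid(q, rx[, j])
      ey <- qr.resid(q, ry)
    } else {
      ej <- rx[, j] - mean(rx[, j])
      ey <- ry - mean(ry)
    }
    r <- sum(ej * ey) / sqrt(sum(ej^2) * sum(ey^2))
    df <- n - np - 1
    tval <- r * sqrt(df / max(1 - r^2, 1e-300))
    out$prcc[j] <- r
    out$p_value[j] <- 2 * pt(-abs(tval), df)
  }
  out
}

.prcc_output <- function(cfg, spec) {
  reg <- cfg$regimen
  model <- if (cfg$system$species == "human")
    build_human_pk(cfg$molecule, cfg$system)
  else build_mouse_pk(cfg$molecule, cfg$system)
  model <- couple_tumor(model, cfg$tgi)
  grid <- sort(unique(c(seq(0, spec$window, length.out = 57),
                        (seq_len(reg$n_doses) - 1) * reg$interval)))
  grid <- grid[grid <= spec$window]
  tv <- simulate_tgi(model, reg, grid,
                     solver = list(rtol = 1e-6, atol = 1e-9))
  auc_trapz(tv$time, tv$tumor_volume)
}

#' Run an LHS-PRCC sensitivity study on a configured model
#'
#' Samples the design, runs the coupled PK + tumor + TGI simulation for
#' every parameter set under the configured dosing scenario, computes the
#' scalar output (tumor volume AUC over the window) and returns PRCC values
#' sorted by magnitude.  Failing simulations are excluded and counted; the
#' study aborts if more than 10% fail.
#'
#' @param spec a [prcc_spec()]
#' @param config an `adc_config` with `tgi` and `regimen` sections
#' @return data frame of parameters with `prcc` and `p_value`, sorted by
#'   `abs(prcc)` decreasing, with attributes `n_failed`, `scenario`
#' @export
run_prcc_study <- function(spec, config) {
  stopifnot(inherits(spec, "prcc_spec"), inherits(config, "adc_config"))
  if (is.null(config$tgi) || is.null(config$regimen))
    stop("PRCC study needs 'tgi' and 'regimen' config sections",
         call. = FALSE)
  x <- lhs_sample(spec)
  y <- rep(NA_real_, nrow(x))
  for (i in seq_len(nrow(x))) {
    cfg_i <- try(set_params(config, as.list(setNames(x[i, ], colnames(x)))),
                 silent = TRUE)
    if (inherits(cfg_i, "try-error")) next
    val <- try(suppressWarnings(.prcc_output(cfg_i, spec)), silent = TRUE)
    if (!inherits(val, "try-error") && is.finite(val)) y[i] <- val
  }
  failed <- sum(is.na(y))
  if (failed > 0.1 * nrow(x))
    stop(sprintf("%d/%d simulations failed in the PRCC study", failed,
                 nrow(x)), call. = FALSE)
  ok <- !is.na(y)
  res <- prcc(x[ok, , drop = FALSE], y[ok])
  res <- res[order(-abs(res$prcc)), ]
  rownames(res) <- NULL
  attr(res, "n_failed") <- failed
  attr(res, "scenario") <- list(
    dose_mg_per_kg = config$regimen$dose_mg_per_kg,
    interval = config$regimen$interval, n_doses = config$regimen$n_doses,
    output = spec$output, window = spec$window)
  res
}
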