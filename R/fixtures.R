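# Synthetic observed datasets: simulate a known-parameter model, sample at
# stated times, apply multiplicative lognormal noise.  Truth is attached as
# an attribute so recovery tests can compare estimates against it.

#' Specification for a synthetic observed dataset
#'
#' @param config generating `adc_config` (the truth)
#' @param scenario `"pk"` (plasma analytes), `"tgi"` (tumor volumes across
#'   dose groups) or `"invitro"`
#' @param times sampling times (day), increasing
#' @param dose_groups numeric vector of dose levels (mg/kg); for
#'   `"invitro"`, initial media concentrations (nM)
#' @param analytes character vector of analytes to sample; defaults per
#'   scenario (`pk`: `adc`, `total_ab`; `tgi`: `tumor_volume`;
#'   `invitro`: `payload` in media and intracellular)
#' @param cv lognormal coefficient of variation of the multiplicative
#'   noise (0 = noise-free)
#' @param seed RNG seed
#' @return a `fixture_spec`
#' @export
fixture_spec <- function(config, scenario = c("pk", "tgi", "invitro"),
                         times, dose_groups, analytes = NULL, cv = 0.1,
                         seed = 1) {
  scenario <- match.arg(scenario)
  stopifnot(inherits(config, "adc_config"), cv >= 0,
            !is.unsorted(times, strictly = TRUE), all(times >= 0))
  if (is.null(analytes))
    analytes <- switch(scenario, pk = c("adc", "total_ab"),
                       tgi = "tumor_volume", invitro = "payload")
  structure(list(config = config, scenario = scenario, times = times,
                 dose_groups = dose_groups, analytes = analytes, cv = cv,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

.fixture_truth_rows <- function(spec, dose) {
  cfg <- spec$config
  if (spec$scenario == "invitro") {
    iv <- cfg$invitro
    model <- build_cellular_model(cfg$molecule, cfg$system, iv$n_cells,
                                  iv$v_media)
    traj <- simulate_cellular(model, sort(unique(c(0, spec$times))),
                              dose_conc = dose)
    conc <- cellular_concentrations(traj)
    out <- do.call(rbind, lapply(spec$analytes, function(a) {
      cmp <- if (a == "payload") c("media", "intracellular") else "media"
      do.call(rbind, lapply(cmp, function(cc) {
        col <- switch(paste(a, cc, sep = "/"),
                      "payload/media" = "payload_media",
                      "payload/intracellular" = "payload_intracellular",
                      "adc/media" = "adc_media",
                      "total_ab/media" = "ab_media")
        data.frame(time = spec$times, analyte = a, compartment = cc,
                   value = approx(conc$time, conc[[col]],
                                  xout = spec$times, rule = 2)$y)
      }))
    }))
    return(out)
  }
  reg <- cfg$regimen
  reg$dose_mg_per_kg <- dose
  model <- if (cfg$system$species == "human")
    build_human_pk(cfg$molecule, cfg$system)
  else build_mouse_pk(cfg$molecule, cfg$system)
  if (spec$scenario == "tgi") model <- couple_tumor(model, cfg$tgi)
  dose_times <- (seq_len(reg$n_doses) - 1) * reg$interval
  grid <- sort(unique(c(0, dose_times, spec$times)))
  traj <- simulate_regimen(model, reg, grid)
  if (spec$scenario == "tgi") {
    tu <- tumor_observables(traj)
    data.frame(time = spec$times, analyte = "tumor_volume",
               compartment = "tumor",
               value = approx(tu$time, tu$tumor_volume, xout = spec$times,
                              rule = 2)$y)
  } else {
    pc <- plasma_concentrations(traj, "central")
    do.call(rbind, lapply(spec$analytes, function(a) {
      data.frame(time = spec$times, analyte = a, compartment = "central",
                 value = approx(pc$time, pc[[a]], xout = spec$times,
                                rule = 2)$y)
    }))
  }
}

#' Generate a synthetic observed dataset
#'
#' Simulates the generating model for every dose group, samples at the
#' specified times and applies multiplicative lognormal noise
#' (median-preserving, `sdlog = sqrt(log(1 + CV^2))`).  The noise-free
#' predictions are kept in a `truth` column and the generating parameter
#' values as the `truth_params` attribute.
#'
#' @param spec a [fixture_spec()]
#' @return an [observed_dataset()] with extra column `truth`
#' @export
generate_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  rows <- do.call(rbind, lapply(spec$dose_groups, function(d) {
    r <- .fixture_truth_rows(spec, d)
    r$dose_group <- d
    r
  }))
  rows$truth <- rows$value
  if (spec$cv > 0) {
    sdlog <- sqrt(log(1 + spec$cv^2))
    rows$value <- rows$value * rlnorm(nrow(rows), 0, sdlog)
  }
  ds <- observed_dataset(rows, source = sprintf("synthetic (%s, CV %.2g)",
                                                spec$scenario, spec$cv))
  attr(ds, "truth_params") <- list(
    molecule = unclass(spec$config$molecule),
    system = unclass(spec$config$system),
    tgi = if (!is.null(spec$config$tgi)) unclass(spec$config$tgi))
  ds
}
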