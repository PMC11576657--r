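# Configuration files: YAML with sections molecule / system / tgi / regimen /
# invitro / trial / prcc.  Every numeric entry is a {value, unit} pair drawn
# from a controlled unit vocabulary and converted to canonical units
# (nM, day, L, mm^3, cm) on load.

.unit_table <- list(
  frac = setNames(rep(1, 4), c("", "1", "dimensionless", "fraction")),
  count = c("count" = 1, "cells" = 1, "receptors/cell" = 1, "1/cell" = 1,
            "patients" = 1, "doses" = 1),
  time = c(day = 1, days = 1, d = 1, h = 1 / 24, hr = 1 / 24, hour = 1 / 24,
           hours = 1 / 24, week = 7, weeks = 7, month = 30.4375,
           months = 30.4375, min = 1 / 1440, s = 1 / 86400),
  rate = c("1/day" = 1, "1/d" = 1, "1/h" = 24, "1/hr" = 24, "1/hour" = 24,
           "1/week" = 1 / 7, "1/s" = 86400, "1/min" = 1440,
           "1/month" = 1 / 30.4375),
  assoc = c("1/nM/day" = 1, "1/nM/h" = 24, "1/M/s" = 86400 / 1e9,
            "1/uM/day" = 1e-3, "1/uM/h" = 24e-3),
  conc = c(nM = 1, uM = 1e3, pM = 1e-3, mM = 1e6, M = 1e9),
  vol_l = c(L = 1, l = 1, mL = 1e-3, ml = 1e-3, uL = 1e-6, ul = 1e-6,
            pL = 1e-12, fL = 1e-15, "um^3" = 1e-15),
  vol_mm3 = c("mm^3" = 1, mm3 = 1, "cm^3" = 1e3, cm3 = 1e3, uL = 1, mL = 1e3),
  length = c(cm = 1, mm = 0.1, um = 1e-4, nm = 1e-7),
  diff = c("cm^2/day" = 1, "cm2/day" = 1, "um^2/s" = 8.64e-4,
           "cm^2/s" = 86400),
  perm = c("cm/day" = 1, "um/day" = 1e-4, "cm/s" = 86400, "um/s" = 8.64,
           "nm/s" = 8.64e-3, "um/h" = 2.4e-3),
  dose = c("mg/kg" = 1, "ug/kg" = 1e-3, "g/kg" = 1e3),
  mass = c(kg = 1, g = 1e-3),
  mw = c("g/mol" = 1, Da = 1, kDa = 1e3),
  dens = c("cells/mm^3" = 1, "cells/uL" = 1, "cells/mL" = 1e-3,
           "cells/cm^3" = 1e-3),
  lingrow = c("mm^3/day" = 1, "mm^3/week" = 1 / 7, "mm^3/h" = 24)
)

.canonical_unit <- c(frac = "", count = "count", time = "day", rate = "1/day",
                     assoc = "1/nM/day", conc = "nM", vol_l = "L",
                     vol_mm3 = "mm^3", length = "cm", diff = "cm^2/day",
                     perm = "cm/day", dose = "mg/kg", mass = "kg",
                     mw = "g/mol", dens = "cells/mm^3", lingrow = "mm^3/day")

# dimension of every schema entry; "chr" marks plain-string fields
.config_schema <- list(
  molecule = c(name = "chr", linker_type = "chr", dar = "frac",
               k_dec = "rate", k_on_ab = "assoc", k_off_ab = "rate",
               k_cleave = "rate", k_in_pl = "rate", k_out_pl = "rate",
               k_on_pl = "assoc", k_off_pl = "rate",
               mw_adc = "mw", mw_pl = "mw"),
  system = c(k_endo_her2 = "rate", k_endo_her2ab = "rate",
             k_rec_her2 = "rate", k_rec_her2ab = "rate",
             k_deg_her2 = "rate", k_deg_her2ab = "rate",
             r_total_per_cell = "count", target_conc = "conc",
             k12 = "rate", k21 = "rate", k12_pl = "rate", k21_pl = "rate",
             k_elim_ab = "rate", k_elim_pl = "rate",
             v_central = "vol_l", v_peripheral = "vol_l",
             v_tumor_init = "vol_mm3", k_shed = "rate",
             t_half_sher2 = "time", t_half_sher2ab = "time",
             n_healthy_central = "count", n_healthy_peripheral = "count",
             r_healthy_per_cell = "count",
             d_ab = "diff", p_ab = "perm", d_pl = "diff", p_pl = "perm",
             r_cap = "length", r_krogh = "length",
             eps_ab = "frac", eps_pl = "frac",
             cell_density = "dens", v_cell = "vol_l",
             body_weight = "mass", species = "chr"),
  tgi = c(t_double = "time", k_lin = "lingrow", v_tumor_max = "vol_mm3",
          psi = "frac", tau = "time", k_kill_max = "rate", kc50 = "conc"),
  regimen = c(dose_mg_per_kg = "dose", interval = "time", n_doses = "count",
              analyte = "chr", route = "chr", duration = "time"),
  invitro = c(n_cells = "count", v_media = "vol_l", dose_conc = "conc",
              duration = "time"),
  trial = c(n_patients = "count", duration = "time",
            assessment_interval = "time", dropout_rate = "rate",
            her2_receptors_per_cell = "count", label = "chr"),
  prcc = c(n_samples = "count", output = "chr", window = "time")
)

.convert_entry <- function(x, dim, key) {
  if (dim == "chr") {
    if (!is.character(x) || length(x) != 1L)
      stop(sprintf("config entry '%s' must be a string", key), call. = FALSE)
    return(x)
  }
  if (is.numeric(x) && length(x) == 1L) {
    # bare number: interpreted as already canonical only for dimensionless
    if (dim %in% c("frac", "count")) return(as.numeric(x))
    stop(sprintf("config entry '%s' needs an explicit unit (got bare number)",
                 key), call. = FALSE)
  }
  if (!is.list(x) || is.null(x$value) || is.null(x$unit))
    stop(sprintf("config entry '%s' must be a {value, unit} pair", key),
         call. = FALSE)
  tab <- .unit_table[[dim]]
  u <- as.character(x$unit)
  if (!u %in% names(tab))
    stop(sprintf("config entry '%s': unit '%s' is not a valid %s unit",
                 key, u, dim), call. = FALSE)
  as.numeric(x$value) * unname(tab[[u]])
}

.convert_section <- function(raw, section) {
  sch <- .config_schema[[section]]
  extra <- setdiff(names(raw), names(sch))
  if (length(extra))
    stop(sprintf("unknown key(s) in config section '%s': %s", section,
                 paste(extra, collapse = ", ")), call. = FALSE)
  out <- list()
  for (nm in names(raw))
    out[[nm]] <- .convert_entry(raw[[nm]], sch[[nm]],
                                paste(section, nm, sep = "."))
  out
}

.deep_merge <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]) &&
        !("value" %in% names(override[[nm]])))
      base[[nm]] <- .deep_merge(base[[nm]], override[[nm]])
    else
      base[[nm]] <- override[[nm]]
  }
  base
}

.read_raw_config <- function(path, depth = 0) {
  if (depth > 5) stop("config 'extends' chain too deep", call. = FALSE)
  if (!file.exists(path))
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$extends)) {
    base_path <- file.path(dirname(path), raw$extends)
    base <- .read_raw_config(base_path, depth + 1)
    raw$extends <- NULL
    raw <- .deep_merge(base, raw)
  }
  raw
}

#' Load and validate a model configuration file
#'
#' Reads a YAML configuration with sections `molecule`, `system` and
#' optionally `tgi`, `regimen`, `invitro`, `trial` and `prcc`.  Every numeric
#' entry must be a `{value, unit}` pair; values are converted to the
#' canonical unit system (nM, day, L, mm^3, cm) and validated against the
#' parameter invariants.  Unknown sections, unknown keys and unknown units
#' are rejected.  A top-level `extends: <relative path>` key merges the
#' file over a base configuration.
#'
#' @param path path to a YAML configuration file
#' @return an object of class `adc_config`: a list with validated
#'   `molecule_params`, `system_params` and optional `tgi_params`,
#'   `regimen`, `invitro`, `trial` and `prcc` components
#' @seealso [default_config()] for configurations shipped with the package
#' @export
load_config <- function(path) {
  raw <- .read_raw_config(path)
  known <- c(names(.config_schema))
  extra <- setdiff(names(raw), known)
  if (length(extra))
    stop(sprintf("unknown config section(s): %s", paste(extra, collapse = ", ")),
         call. = FALSE)
  if (is.null(raw$molecule) || is.null(raw$system))
    stop("config must contain 'molecule' and 'system' sections",
         call. = FALSE)

  cfg <- list()
  cfg$molecule <- do.call(molecule_params, .convert_section(raw$molecule,
                                                            "molecule"))
  cfg$system <- do.call(system_params, .convert_section(raw$system, "system"))
  if (!is.null(raw$tgi))
    cfg$tgi <- do.call(tgi_params, .convert_section(raw$tgi, "tgi"))
  if (!is.null(raw$regimen))
    cfg$regimen <- do.call(regimen, .convert_section(raw$regimen, "regimen"))
  if (!is.null(raw$invitro))
    cfg$invitro <- .convert_section(raw$invitro, "invitro")
  if (!is.null(raw$trial)) {
    tr <- raw$trial
    cv <- tr$cv
    strata <- tr$her2_strata
    tr$cv <- NULL
    tr$her2_strata <- NULL
    cfg$trial <- .convert_section(tr, "trial")
    if (!is.null(cv)) {
      bad <- setdiff(names(cv), c("t_double", "k_lin", "k_kill_max", "kc50"))
      if (length(bad))
        stop(sprintf("unknown key(s) in trial.cv: %s",
                     paste(bad, collapse = ", ")), call. = FALSE)
      if (any(unlist(cv) < 0)) stop("trial CVs must be >= 0", call. = FALSE)
      cfg$trial$cv <- lapply(cv, as.numeric)
    }
    if (!is.null(strata)) cfg$trial$her2_strata <- as.numeric(unlist(strata))
  }
  if (!is.null(raw$prcc)) {
    pr <- raw$prcc
    pars <- pr$parameters
    pr$parameters <- NULL
    cfg$prcc <- .convert_section(pr, "prcc")
    cfg$prcc$parameters <- lapply(pars, function(p) {
      stopifnot(is.character(p$name))
      dim <- .param_dimension(p$name)
      list(name = p$name,
           lower = .convert_entry(p$lower, dim, paste0("prcc:", p$name)),
           upper = .convert_entry(p$upper, dim, paste0("prcc:", p$name)),
           dist = if (is.null(p$dist)) "uniform" else p$dist)
    })
  }
  structure(cfg, class = "adc_config", source = path)
}

.param_dimension <- function(path) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  if (length(parts) != 2 || is.null(.config_schema[[parts[1]]]) ||
      !parts[2] %in% names(.config_schema[[parts[1]]]))
    stop(sprintf("unknown parameter path '%s'", path), call. = FALSE)
  .config_schema[[parts[1]]][[parts[2]]]
}

#' Get a configuration parameter by path
#' @param cfg an `adc_config`
#' @param path a `"section.name"` string, e.g. `"tgi.t_double"`
#' @return the canonical-unit value
#' @export
get_param <- function(cfg, path) {
  .param_dimension(path)
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  cfg[[parts[1]]][[parts[2]]]
}

#' Set configuration parameters by path
#'
#' Values are in canonical units.  Re-runs constructor validation for the
#' touched sections.
#'
#' @param cfg an `adc_config`
#' @param values named numeric vector or list; names are `"section.name"`
#'   paths
#' @return the modified `adc_config`
#' @export
set_params <- function(cfg, values) {
  touched <- character()
  for (path in names(values)) {
    .param_dimension(path)
    parts <- strsplit(path, ".", fixed = TRUE)[[1]]
    if (is.null(cfg[[parts[1]]]))
      stop(sprintf("config has no '%s' section", parts[1]), call. = FALSE)
    cfg[[parts[1]]][[parts[2]]] <- as.numeric(values[[path]])
    touched <- union(touched, parts[1])
  }
  ctor <- list(molecule = molecule_params, system = system_params,
               tgi = tgi_params, regimen = regimen)
  for (sec in intersect(touched, names(ctor)))
    cfg[[sec]] <- do.call(ctor[[sec]], unclass(cfg[[sec]]))
  cfg
}

.dump_section <- function(obj, section) {
  sch <- .config_schema[[section]]
  out <- list()
  for (nm in intersect(names(obj), names(sch))) {
    v <- obj[[nm]]
    if (is.null(v)) next
    dim <- sch[[nm]]
    if (dim == "chr") out[[nm]] <- v
    else if (dim %in% c("frac", "count")) out[[nm]] <- as.numeric(v)
    else out[[nm]] <- list(value = as.numeric(v),
                           unit = unname(.canonical_unit[[dim]]))
  }
  out
}

#' Write a configuration back to YAML in canonical units
#' @param cfg an `adc_config`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_config <- function(cfg, path) {
  out <- list()
  for (sec in c("molecule", "system", "tgi", "regimen", "invitro")) {
    if (!is.null(cfg[[sec]])) out[[sec]] <- .dump_section(cfg[[sec]], sec)
  }
  if (!is.null(cfg$trial)) {
    tr <- .dump_section(cfg$trial, "trial")
    if (!is.null(cfg$trial$cv)) tr$cv <- cfg$trial$cv
    if (!is.null(cfg$trial$her2_strata))
      tr$her2_strata <- as.numeric(cfg$trial$her2_strata)
    out$trial <- tr
  }
  if (!is.null(cfg$prcc)) {
    pr <- .dump_section(cfg$prcc, "prcc")
    pr$parameters <- lapply(cfg$prcc$parameters, function(p) {
      dim <- .param_dimension(p$name)
      cu <- unname(.canonical_unit[[dim]])
      list(name = p$name,
           lower = list(value = p$lower, unit = cu),
           upper = list(value = p$upper, unit = cu),
           dist = p$dist)
    })
    out$prcc <- pr
  }
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' Path to (or loaded copy of) a configuration shipped with the package
#'
#' Available names: `tdm1_mouse`, `tdxd_mouse`, `tdm1_human`, `tdxd_human`,
#' `tdm1_invitro`, `trial_tdm1_ph2`, `trial_tdxd_ph2`, `trial_tdxd_ph3`,
#' `prcc_tdm1`.
#'
#' @param name configuration name
#' @param load if `TRUE` (default) return the loaded `adc_config`, otherwise
#'   the file path
#' @return an `adc_config` or a file path
#' @export
default_config <- function(name, load = TRUE) {
  path <- system.file("extdata", "config", paste0(name, ".yaml"),
                      package = "adcsim")
  if (path == "")
    stop(sprintf("no shipped configuration named '%s'", name), call. = FALSE)
  if (load) load_config(path) else path
}

#' @export
print.adc_config <- function(x, ...) {
  cat("<adc_config>", paste(names(x), collapse = ", "), "\n")
  invisible(x)
}
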