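#' Load a scenario configuration file
#'
#' Reads a YAML scenario description and validates it into the same objects
#' [preset_scenario()] builds. Top-level keys: `reactor` (`V_liq`, `V_gas`,
#' `HRT`, `T`), `influent` (`type` = `vfa`|`composite`, `total_cod`,
#' `cod_fractions`, `S_IC_in`, `S_IN_in`, `S_cat_in`, `S_an_in`), `kinetics`
#' (`preset`, optional per-guild overrides), `feeding` (`regime` =
#' `continuous`|`discontinuous`, `pulse_fraction`, `period`,
#' `pulse_duration`), `initial` (`inoculum_vs`, `partition`, `solubles`) and
#' `t_end`. Unknown keys and non-summing fractions are rejected.
#'
#' @param path path to a YAML file
#' @return an `adm1_scenario`
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  known <- c("name", "reactor", "influent", "kinetics", "feeding",
             "initial", "t_end")
  bad <- setdiff(names(cfg), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  rc <- cfg$reactor
  inf <- cfg$influent
  fr <- unlist(inf$cod_fractions)
  if (abs(sum(fr) - 1) > 1e-9)
    stop("influent cod_fractions sum to ", sum(fr), ", expected 1")
  influent <- if (identical(inf$type, "composite")) {
    composite_influent(inf$total_cod, fr, S_IC_in = inf$S_IC_in,
                       S_IN_in = inf$S_IN_in, S_cat_in = inf$S_cat_in,
                       S_an_in = inf$S_an_in)
  } else {
    vfa_influent(inf$total_cod, fr, S_IC_in = inf$S_IC_in,
                 S_IN_in = inf$S_IN_in, S_cat_in = inf$S_cat_in,
                 S_an_in = inf$S_an_in)
  }
  config <- reactor_config(rc$V_liq, rc$HRT, influent,
                           V_gas = if (is.null(rc$V_gas)) rc$V_liq / 10 else rc$V_gas,
                           T = if (is.null(rc$T)) 310.15 else rc$T)
  kin <- cfg$kinetics
  overrides <- list()
  for (g in setdiff(names(kin), c("preset", "kLa"))) {
    o <- kin[[g]]
    overrides[[g]] <- population_kinetics(
      g, o$Y, o$k_m, o$K, o$k_dec,
      pH_ul = if (is.null(o$pH_ul)) NA_real_ else o$pH_ul,
      pH_ll = if (is.null(o$pH_ll)) NA_real_ else o$pH_ll)
  }
  params <- adm1_parameters(preset = kin$preset, overrides = overrides,
                            T = config$T,
                            kLa = if (is.null(kin$kLa)) 200 else kin$kLa)
  t_end <- cfg$t_end
  fd <- cfg$feeding
  schedule <- if (identical(fd$regime, "discontinuous")) {
    discontinuous_schedule(config, t_end = t_end,
                           pulse_fraction = fd$pulse_fraction,
                           period = if (is.null(fd$period)) 1 else fd$period,
                           pulse_duration = if (is.null(fd$pulse_duration))
                             20 / 1440 else fd$pulse_duration)
  } else continuous_schedule(config)
  ini <- cfg$initial
  y0 <- initial_state(inoculum_vs = ini$inoculum_vs,
                      partition = unlist(ini$partition),
                      solubles = unlist(ini$solubles))
  structure(list(name = cfg$name, config = config, params = params,
                 schedule = schedule, y0 = y0, t_end = t_end,
                 training_end = NA_real_, disturbance_day = NA_real_),
            class = "adm1_scenario")
}

#' Write a trajectory as delimited text
#'
#' One row per time point, all state and derived columns, tab-separated.
#'
#' @param traj an `adm1_trajectory`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_trajectory <- function(traj, path) {
  utils::write.table(as.data.frame(traj), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run scenarios end to end and record a manifest
#'
#' Simulates each named scenario, writes its time series and summary, audits
#' the COD balance, and returns (and writes) a run manifest. Deterministic
#' scenarios reproduce their outputs bit-identically.
#'
#' @param scenario_names character vector of [preset_scenario()] names
#' @param out_dir output directory (created if needed)
#' @param t_end optional horizon override applied to every scenario, days
#' @param ... passed to [run_scenario()]
#' @return the manifest (list), invisibly written as YAML to
#'   `manifest.yaml` in `out_dir`
#' @export
run_pipeline <- function(scenario_names, out_dir, t_end = NULL, ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("acetoclast")),
                   scenarios = list(), outputs = character())
  for (nm in scenario_names) {
    sc <- preset_scenario(nm, t_end = t_end)
    traj <- run_scenario(sc, ...)
    f <- file.path(out_dir, paste0(nm, "_timeseries.tsv"))
    write_trajectory(traj, f)
    audit <- cod_balance(traj)
    smry <- if (!is.na(sc$training_end) && max(traj$time) >= sc$training_end)
      unclass(summarize_run(traj, sc$training_end)) else list()
    manifest$scenarios[[nm]] <- list(
      t_end = sc$t_end,
      cod_balance_residual = audit$residual,
      summary = lapply(smry, function(x) unname(x)))
    manifest$outputs <- c(manifest$outputs, f)
  }
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(manifest)
}
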