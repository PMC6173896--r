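#' Reactor configuration
#'
#' @param V_liq liquid working volume, L
#' @param V_gas headspace volume, L (defaults to a tenth of `V_liq`)
#' @param HRT hydraulic retention time, days
#' @param T operating temperature, K
#' @param influent named influent state vector (see [vfa_influent()])
#' @param cod_per_vs biomass COD-to-VS conversion, gCOD/gVS
#' @return an object of class `reactor_config`
#' @export
reactor_config <- function(V_liq, HRT, influent, V_gas = V_liq / 10,
                           T = 310.15, cod_per_vs = 1.42) {
  stopifnot(V_liq > 0, V_gas > 0, HRT > 0)
  structure(list(V_liq = V_liq, V_gas = V_gas, HRT = HRT, T = T,
                 influent = influent, cod_per_vs = cod_per_vs),
            class = "reactor_config")
}

new_schedule <- function(base_flow, base_influent, events, V_liq, HRT) {
  structure(list(base_flow = base_flow, base_influent = base_influent,
                 events = events, V_liq = V_liq, HRT = HRT),
            class = "feed_schedule")
}

#' Continuous feeding schedule
#'
#' Constant flow `V_liq / HRT` with constant influent composition.
#'
#' @param config a [reactor_config()]
#' @return a `feed_schedule`
#' @export
continuous_schedule <- function(config) {
  new_schedule(config$V_liq / config$HRT, config$influent, list(),
               config$V_liq, config$HRT)
}

#' Discontinuous (pulsed) feeding schedule
#'
#' Each period delivers `pulse_fraction` of the period's ration in one short
#' pulse and the remainder as continuous base flow, so any whole number of
#' periods delivers the same substrate mass as the continuous schedule.
#'
#' @param config a [reactor_config()]
#' @param t_end horizon over which pulse events are laid out, days
#' @param pulse_fraction fraction of the ration delivered in the pulse
#' @param period feeding period, days
#' @param pulse_duration pulse length, days (default 20 min)
#' @param first_pulse start time of the first pulse, days
#' @return a `feed_schedule`
#' @export
discontinuous_schedule <- function(config, t_end, pulse_fraction = 1,
                                   period = 1, pulse_duration = 20 / 1440,
                                   first_pulse = 0) {
  stopifnot(pulse_fraction >= 0, pulse_fraction <= 1, period > 0,
            pulse_duration > 0, pulse_duration < period)
  q_avg <- config$V_liq / config$HRT
  pulse_flow <- pulse_fraction * q_avg * period / pulse_duration
  starts <- seq(first_pulse, t_end, by = period)
  events <- lapply(starts, function(s)
    list(start = s, duration = pulse_duration, flow = pulse_flow,
         influent = config$influent))
  new_schedule((1 - pulse_fraction) * q_avg, config$influent, events,
               config$V_liq, config$HRT)
}

#' Add an organic-overloading disturbance
#'
#' Appends one pulse event delivering `extra_cod_g` grams of COD of the
#' given influent composition (default: the schedule's own substrate at
#' four-fold concentration, mimicking a concentrated shock load).
#'
#' @param schedule a `feed_schedule`
#' @param day start time of the disturbance, days
#' @param extra_cod_g COD mass added, g
#' @param duration delivery time, days
#' @param influent influent vector for the disturbance; defaults to the
#'   base influent with all COD species scaled 4x
#' @return the schedule with the disturbance appended
#' @export
add_disturbance <- function(schedule, day, extra_cod_g,
                            duration = 20 / 1440, influent = NULL) {
  if (extra_cod_g == 0) return(schedule)
  if (is.null(influent)) {
    influent <- schedule$base_influent
    influent[COD_IDX] <- influent[COD_IDX] * 4
  }
  conc <- state_total_cod(influent)
  if (conc <= 0) stop("disturbance influent carries no COD")
  flow <- extra_cod_g / conc / duration
  schedule$events <- c(schedule$events,
                       list(list(start = day, duration = duration,
                                 flow = flow, influent = influent)))
  schedule
}

## Piecewise-constant description of a schedule: event edge times.
schedule_edges <- function(schedule, t_end) {
  tt <- unlist(lapply(schedule$events, function(e)
    c(e$start, e$start + e$duration)))
  tt <- tt[tt > 0 & tt < t_end]
  sort(unique(c(0, tt, t_end)))
}

## Total flow (L/d) and influent mass flux (units/d per state entry) on the
## segment containing time t (segments are open intervals between edges).
schedule_segment <- function(schedule, t) {
  q <- schedule$base_flow
  influx <- schedule$base_flow * schedule$base_influent
  for (e in schedule$events) {
    if (t >= e$start && t < e$start + e$duration) {
      q <- q + e$flow
      influx <- influx + e$flow * e$influent
    }
  }
  list(q = q, influx = influx)
}

#' COD delivered by a schedule over a time window
#'
#' Exact (analytic) integral of flow times influent COD over `[t0, t1]`.
#'
#' @param schedule a `feed_schedule`
#' @param t0,t1 window bounds, days
#' @return delivered COD, g
#' @export
delivered_cod <- function(schedule, t0, t1) {
  total <- (t1 - t0) * schedule$base_flow * state_total_cod(schedule$base_influent)
  for (e in schedule$events) {
    ov <- max(0, min(t1, e$start + e$duration) - max(t0, e$start))
    total <- total + ov * e$flow * state_total_cod(e$influent)
  }
  total
}

#' Long-run average flow of a schedule
#'
#' @param schedule a `feed_schedule`
#' @param t0,t1 averaging window, days
#' @return mean flow, L/day
#' @export
average_flow <- function(schedule, t0, t1) {
  vol <- (t1 - t0) * schedule$base_flow
  for (e in schedule$events) {
    ov <- max(0, min(t1, e$start + e$duration) - max(t0, e$start))
    vol <- vol + ov * e$flow
  }
  vol / (t1 - t0)
}
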