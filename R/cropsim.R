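#' Crop parameters for the lightweight winter-wheat simulator
#'
#' A daily radiation-use-efficiency growth model driven by thermal time.
#' Phenology is a piecewise-linear map from cumulative growing degree days to
#' the BBCH decimal scale; development pauses on days with `tmean` at or below
#' `base_temp` (no degree days accrue), which stands in for winter dormancy.
#' Above-ground biomass grows as
#' `RUE x radiation x (1 - exp(-k LAI)) x f_temp x f_water x f_fert x f_sow`,
#' with leaf area tied to biomass through a specific-leaf coefficient until
#' anthesis and senescing linearly in thermal time afterwards. Grain
#' (generative) biomass accumulates after anthesis from a fixed partition of
#' new growth plus remobilised pre-anthesis reserves.
#'
#' @param base_temp base temperature for thermal time, degC.
#' @param tt_stages named numeric vector of cumulative degree-day thresholds
#'   (degC d from sowing) for the BBCH milestones
#'   `emergence` (BBCH 10), `tillering` (25), `stem_ext` (30),
#'   `flag_leaf` (39), `anthesis` (61) and `maturity` (92). Must be strictly
#'   increasing.
#' @param maturity_bbch BBCH value at which harvest is triggered.
#' @param rue radiation-use efficiency, g dry matter per MJ intercepted.
#' @param k_ext canopy light-extinction coefficient.
#' @param max_lai maximum leaf area index, m2 m-2.
#' @param sla_coef leaf area per unit above-ground biomass, m2 m-2 per kg ha-1.
#' @param grain_partition fraction of post-anthesis growth routed to grain.
#' @param remobilisation fraction of anthesis biomass remobilised to grain
#'   over the grain-filling phase.
#' @param fert_boost multiplicative growth bonus while a fertilization window
#'   is active (length 3, one per application).
#' @param fert_window days each fertilization bonus stays active.
#' @param temp_opt air temperature at which the temperature factor saturates.
#' @param water_sens exponent of the water-stress factor (1 = linear in root
#'   zone available-water fraction).
#' @param sowing_penalty relative yield-potential loss per day of sowing delay
#'   beyond `penalty_ref_doy` (later autumn sowing shortens pre-winter
#'   development and erodes yield potential).
#' @param penalty_ref_doy first day of the plausible sowing window.
#' @param sowing_window integer range of plausible sowing days of year.
#' @param et_coef potential evapotranspiration per unit radiation,
#'   mm per MJ m-2.
#' @param seed_agb above-ground biomass at emergence, kg ha-1.
#' @return an object of class `crop_params`.
#' @export
crop_params <- function(base_temp = 0,
                        tt_stages = c(emergence = 150, tillering = 550,
                                      stem_ext = 800, flag_leaf = 1050,
                                      anthesis = 1400, maturity = 2000),
                        maturity_bbch = 92,
                        rue = 1.85,
                        k_ext = 0.6,
                        max_lai = 7,
                        sla_coef = 0.0011,
                        grain_partition = 0.7,
                        remobilisation = 0.25,
                        fert_boost = c(1.15, 1.15, 1.1),
                        fert_window = 25,
                        temp_opt = 14,
                        water_sens = 1,
                        sowing_penalty = 0.0048,
                        penalty_ref_doy = 283,
                        sowing_window = c(270, 340),
                        et_coef = 0.13,
                        seed_agb = 100) {
  stage_names <- c("emergence", "tillering", "stem_ext", "flag_leaf",
                   "anthesis", "maturity")
  if (!all(stage_names %in% names(tt_stages))) {
    stop_invalid("crop_params: tt_stages must name ",
                 paste(stage_names, collapse = ", "))
  }
  tt_stages <- tt_stages[stage_names]
  if (any(diff(tt_stages) <= 0) || any(tt_stages <= 0)) {
    stop_invalid("crop_params: BBCH thresholds must be strictly increasing and positive")
  }
  if (grain_partition < 0 || grain_partition > 1) {
    stop_invalid("crop_params: grain_partition must lie in [0, 1]")
  }
  if (rue < 0 || k_ext < 0 || max_lai < 0 || sla_coef < 0 ||
      remobilisation < 0 || any(fert_boost < 0) || et_coef < 0) {
    stop_invalid("crop_params: rates and fractions must be >= 0")
  }
  structure(list(
    base_temp = base_temp, tt_stages = tt_stages,
    maturity_bbch = maturity_bbch, rue = rue, k_ext = k_ext,
    max_lai = max_lai, sla_coef = sla_coef,
    grain_partition = grain_partition, remobilisation = remobilisation,
    fert_boost = fert_boost, fert_window = fert_window,
    temp_opt = temp_opt, water_sens = water_sens,
    sowing_penalty = sowing_penalty, penalty_ref_doy = penalty_ref_doy,
    sowing_window = as.integer(sowing_window), et_coef = et_coef,
    seed_agb = seed_agb
  ), class = "crop_params")
}

#' Soil profile for the layered bucket water model and damped temperature
#'
#' Water is tracked as volumetric content in layers bounded by the
#' observation depths; soil temperature is a first-order lagged response to
#' air temperature with an exponentially depth-damped response rate.
#'
#' @param water_depths lower boundaries of the water observation layers, cm
#'   (strictly increasing; layer thicknesses are the successive differences).
#' @param temp_depths soil temperature observation depths, cm.
#' @param field_capacity volumetric field capacity per layer, percent.
#' @param wilting_point volumetric wilting point per layer, percent.
#' @param init_water initial content per layer, percent (defaults to field
#'   capacity: autumn sowing follows a recharged profile).
#' @param damping_depth e-folding depth of the temperature response rate, cm.
#' @param surface_rate daily response rate of the surface layer, in `(0, 1]`.
#' @param root_weights transpiration extraction weights per water layer.
#' @return an object of class `soil_profile`.
#' @export
soil_profile <- function(water_depths = c(30, 60, 90, 120),
                         temp_depths = c(5, 10, 50),
                         field_capacity = c(34, 33, 32, 31),
                         wilting_point = c(12, 12, 13, 13),
                         init_water = field_capacity,
                         damping_depth = 40,
                         surface_rate = 0.25,
                         root_weights = c(0.4, 0.3, 0.2, 0.1)) {
  nl <- length(water_depths)
  if (any(diff(water_depths) <= 0) || any(water_depths <= 0)) {
    stop_invalid("soil_profile: water_depths must be positive and strictly increasing")
  }
  if (any(diff(temp_depths) <= 0) || any(temp_depths <= 0)) {
    stop_invalid("soil_profile: temp_depths must be positive and strictly increasing")
  }
  if (length(field_capacity) != nl || length(wilting_point) != nl ||
      length(init_water) != nl || length(root_weights) != nl) {
    stop_invalid("soil_profile: per-layer fields must match water_depths")
  }
  if (any(wilting_point >= field_capacity)) {
    stop_invalid("soil_profile: wilting point must be below field capacity in every layer")
  }
  structure(list(
    water_depths = water_depths, temp_depths = temp_depths,
    thickness_mm = diff(c(0, water_depths)) * 10,
    field_capacity = field_capacity, wilting_point = wilting_point,
    init_water = init_water, damping_depth = damping_depth,
    surface_rate = surface_rate,
    root_weights = root_weights / sum(root_weights)
  ), class = "soil_profile")
}

#' Cumulative thermal time along a weather series
#'
#' Growing degree days accumulated from a start day: the daily increment is
#' `max(0, tmean - base_temp)`, so the sequence is non-decreasing.
#'
#' @param series a `weather_series`.
#' @param start_year,start_doy first day counted.
#' @param base_temp base temperature, degC.
#' @return numeric vector of cumulative degree days, one element per day from
#'   the start day to the end of the series.
#' @export
thermal_time <- function(series, start_year, start_doy, base_temp = 0) {
  i0 <- which(series$year == start_year & series$doy == start_doy)
  if (length(i0) != 1L) {
    stop_invalid("thermal_time: start day not found in series")
  }
  tm <- series$tmean[i0:nrow(series)]
  cumsum(pmax(0, tm - base_temp))
}

#' Depth-damped soil temperature response to an air temperature history
#'
#' First-order lag: each depth relaxes toward the day's air temperature at
#' rate `surface_rate * exp(-depth / damping_depth)`, so shallow depths track
#' the air closely while deep layers respond slowly and with reduced
#' amplitude. Under constant forcing every depth converges to the air
#' temperature.
#'
#' @param air_temp numeric vector of daily air (mean) temperatures, degC.
#' @param depths observation depths, cm.
#' @param damping_depth e-folding depth of the response rate, cm.
#' @param surface_rate daily response rate at depth 0.
#' @param init initial temperature of all layers (defaults to `air_temp[1]`).
#' @return a matrix with one row per day and one column per depth
#'   (columns named `st_<depth>`).
#' @export
soil_temperature_profile <- function(air_temp, depths = c(5, 10, 50),
                                     damping_depth = 40, surface_rate = 0.25,
                                     init = air_temp[1]) {
  if (length(air_temp) < 1L) stop_invalid("soil_temperature_profile: empty history")
  if (any(depths <= 0)) stop_invalid("soil_temperature_profile: depths must be positive")
  rates <- surface_rate * exp(-depths / damping_depth)
  out <- matrix(NA_real_, nrow = length(air_temp), ncol = length(depths),
                dimnames = list(NULL, paste0("st_", depths)))
  st <- rep(init, length(depths))
  for (i in seq_along(air_temp)) {
    st <- st + rates * (air_temp[i] - st)
    out[i, ] <- st
  }
  out
}

#' One daily step of the layered soil water bucket
#'
#' Mass-balance update in mm over the layer stack: precipitation infiltrates
#' the top layer, content above field capacity cascades to the layer below
#' (and out of the profile at the bottom), and evapotranspiration demand is
#' met from soil evaporation (top layer) plus transpiration extracted along
#' the root weights, never drawing a layer below its wilting point.
#'
#' @param water volumetric content per layer, percent.
#' @param precip day's precipitation, mm.
#' @param pet potential evapotranspiration, mm.
#' @param lai leaf area index (partitions `pet` into transpiration and soil
#'   evaporation through canopy cover).
#' @param soil a [soil_profile()].
#' @param k_ext canopy light-extinction coefficient.
#' @return list with `water` (updated percent content per layer), `drainage`
#'   (mm leaving the profile), `et` (mm actually evapotranspired), and
#'   `stress` (root-zone available water fraction in `[0, 1]`).
#' @export
step_soil_water <- function(water, precip, pet, lai, soil, k_ext = 0.6) {
  thick <- soil$thickness_mm
  mm <- water / 100 * thick           # store as mm per layer
  fc_mm <- soil$field_capacity / 100 * thick
  wp_mm <- soil$wilting_point / 100 * thick

  # infiltration + downward cascade of any excess over field capacity
  push <- precip
  for (l in seq_along(mm)) {
    mm[l] <- mm[l] + push
    push <- max(0, mm[l] - fc_mm[l])
    mm[l] <- mm[l] - push
  }
  drainage <- push

  cover <- 1 - exp(-k_ext * max(0, lai))
  demand_t <- pet * cover             # transpiration demand
  demand_e <- pet * (1 - cover) * 0.5 # bare-soil evaporation, top layer only
  avail <- pmax(0, mm - wp_mm)

  evap <- min(demand_e, avail[1])
  mm[1] <- mm[1] - evap
  avail[1] <- avail[1] - evap

  w <- soil$root_weights
  take <- pmin(demand_t * w, avail)
  # redistribute unmet demand once across layers that still have water
  unmet <- demand_t - sum(take)
  if (unmet > 1e-12) {
    room <- avail - take
    open <- room > 1e-12
    if (any(open)) {
      extra <- pmin(room, unmet * (room / sum(room)))
      take <- take + extra
    }
  }
  mm <- mm - take
  et <- evap + sum(take)

  frac <- sum(w * pmax(0, mm - wp_mm) / (fc_mm - wp_mm))
  list(water = mm / thick * 100, drainage = drainage, et = et,
       stress = min(1, max(0, frac)))
}

# piecewise-linear BBCH from cumulative thermal time
bbch_from_tt <- function(tt, crop) {
  st <- crop$tt_stages
  knots_tt <- c(0, st[["emergence"]], st[["tillering"]], st[["stem_ext"]],
                st[["flag_leaf"]], st[["anthesis"]], st[["maturity"]])
  knots_bbch <- c(0, 10, 25, 30, 39, 61, 92)
  # extrapolate past maturity at the final phase rate, capped at BBCH 100
  out <- stats::approx(knots_tt, knots_bbch, xout = tt, rule = 2)$y
  over <- tt > st[["maturity"]]
  if (any(over)) {
    rate <- (92 - 61) / (st[["maturity"]] - st[["anthesis"]])
    out[over] <- pmin(100, 92 + rate * (tt[over] - st[["maturity"]]))
  }
  out
}

#' Simulate one winter-wheat season
#'
#' Runs the daily growth, soil water and soil temperature model from a sowing
#' day to crop maturity. Fertilization events fire on the first day BBCH
#' reaches 25, 30 and 39 respectively; harvest fires on the first day BBCH
#' reaches the maturity threshold. Final grain yield is the generative
#' biomass at harvest converted from kg/ha to dt/ha. If the series ends
#' before maturity the trace is flagged failed with zero yield.
#'
#' Alongside the daily states, the trace records end-of-day snapshots at the
#' eight observation points (OPs) of the monitoring scheme: OP0 is the sowing
#' day itself, OP1 is 30 days after sowing, OP2/4/5 are the three
#' fertilizations, OP3 and OP6 are 14 days after the first and third
#' fertilization, OP7 is harvest. At OP1-6 the biomass parameter observed is
#' above-ground biomass; at OP7 it is generative (grain) biomass.
#'
#' @param series a `weather_series` covering the sowing year and the year
#'   after.
#' @param sowing_year year (within `series`) in which sowing occurs.
#' @param sowing_doy sowing day of year, inside the crop's plausible window.
#' @param crop a [crop_params()].
#' @param soil a [soil_profile()].
#' @return a `growth_trace`: list with elements `sowing_doy`, `sowing_year`,
#'   `daily` (data frame of daily states), `events`, `ops` (observation-point
#'   snapshots), `yield` (dt/ha), and `failed`.
#' @export
simulate_season <- function(series, sowing_year, sowing_doy, crop = crop_params(),
                            soil = soil_profile()) {
  if (sowing_doy < crop$sowing_window[1] || sowing_doy > crop$sowing_window[2]) {
    stop_invalid("simulate_season: sowing_doy ", sowing_doy,
                 " outside plausible window [", crop$sowing_window[1], ", ",
                 crop$sowing_window[2], "]")
  }
  i0 <- which(series$year == sowing_year & series$doy == sowing_doy)
  if (length(i0) != 1L) stop_invalid("simulate_season: sowing day not in series")

  idx <- i0:nrow(series)
  n <- length(idx)
  tmean <- series$tmean[idx]
  precip <- series$precip[idx]
  rad <- series$radiation[idx]
  yr <- series$year[idx]
  dy <- series$doy[idx]

  tt <- cumsum(pmax(0, tmean - crop$base_temp))
  bbch <- bbch_from_tt(tt, crop)

  st_mat <- soil_temperature_profile(tmean, soil$temp_depths,
                                     soil$damping_depth, soil$surface_rate)

  nl <- length(soil$water_depths)
  sw_mat <- matrix(NA_real_, n, nl,
                   dimnames = list(NULL, paste0("sw_", soil$water_depths)))
  lai_v <- agb_v <- gen_v <- numeric(n)

  pen <- max(0.3, 1 - crop$sowing_penalty * max(0, sowing_doy - crop$penalty_ref_doy))
  fert_until <- rep(-Inf, 3)          # day index each fert bonus expires
  fert_day <- rep(NA_integer_, 3)
  fert_bbch <- c(25, 30, 39)
  harvest_day <- NA_integer_

  water <- soil$init_water
  agb <- crop$seed_agb
  gen <- 0
  lai <- 0
  tt_anth <- crop$tt_stages[["anthesis"]]
  tt_mat <- crop$tt_stages[["maturity"]]
  agb_anth <- NA_real_
  lai_at_anth <- 0
  emerged_tt <- crop$tt_stages[["emergence"]]

  for (i in seq_len(n)) {
    # management triggers (checked on state at start of day i)
    for (f in 1:3) {
      if (is.na(fert_day[f]) && bbch[i] >= fert_bbch[f]) {
        fert_day[f] <- i
        fert_until[f] <- i + crop$fert_window
      }
    }
    # canopy from biomass (pre-anthesis) or senescence (post-anthesis)
    if (tt[i] < tt_anth) {
      lai <- min(crop$max_lai, crop$sla_coef * agb)
      lai_at_anth <- lai
    } else {
      if (is.na(agb_anth)) agb_anth <- agb
      frac_fill <- (tt[i] - tt_anth) / (tt_mat - tt_anth)
      lai <- max(0, lai_at_anth * (1 - frac_fill))
    }

    pet <- crop$et_coef * rad[i]
    wstep <- step_soil_water(water, precip[i], pet, lai, soil, crop$k_ext)
    water <- wstep$water
    sw_mat[i, ] <- water

    if (tt[i] >= emerged_tt) {
      f_temp <- min(1, max(0, (tmean[i] - crop$base_temp) /
                                (crop$temp_opt - crop$base_temp)))
      f_water <- wstep$stress^crop$water_sens
      f_fert <- 1
      for (f in 1:3) if (!is.na(fert_day[f]) && i <= fert_until[f]) {
        f_fert <- f_fert * crop$fert_boost[f]
      }
      fint <- 1 - exp(-crop$k_ext * lai)
      growth <- crop$rue * rad[i] * fint * f_temp * f_water * f_fert * pen * 10
      agb <- agb + growth
      if (tt[i] >= tt_anth) {
        # remobilised reserves spread over the expected grain-fill duration
        remob <- crop$remobilisation * agb_anth /
          max(20, (tt_mat - tt_anth) / 16)
        gen <- min(gen + crop$grain_partition * growth + remob, 0.6 * agb)
      }
    }
    agb_v[i] <- agb; gen_v[i] <- gen; lai_v[i] <- lai

    if (bbch[i] >= crop$maturity_bbch) {
      harvest_day <- i
      break
    }
  }

  failed <- is.na(harvest_day)
  if (failed) {
    warning("simulate_season: maturity not reached before the series end ",
            "(sowing year ", sowing_year, ", DOY ", sowing_doy,
            "); season flagged failed", call. = FALSE)
  }
  last <- if (failed) n else harvest_day
  keep <- seq_len(last)
  daily <- data.frame(year = yr[keep], doy = dy[keep], bbch = bbch[keep],
                      lai = lai_v[keep], agb = agb_v[keep],
                      gen_biomass = gen_v[keep])
  daily <- cbind(daily, as.data.frame(sw_mat[keep, , drop = FALSE]),
                 as.data.frame(st_mat[keep, , drop = FALSE]))

  events <- data.frame(kind = "sowing", year = sowing_year, doy = sowing_doy,
                       stringsAsFactors = FALSE)
  for (f in 1:3) {
    if (!is.na(fert_day[f])) {
      events <- rbind(events, data.frame(
        kind = paste0("fertilization_", f),
        year = yr[fert_day[f]], doy = dy[fert_day[f]]))
    }
  }
  if (!failed) {
    events <- rbind(events, data.frame(kind = "harvest",
                                       year = yr[harvest_day],
                                       doy = dy[harvest_day]))
  }

  yield <- if (failed) 0 else gen_v[harvest_day] / 100  # kg/ha -> dt/ha

  trace <- structure(list(
    sowing_year = sowing_year, sowing_doy = as.integer(sowing_doy),
    daily = daily, events = events, yield = yield, failed = failed
  ), class = "growth_trace")
  trace$ops <- op_snapshots(trace, fert_day = fert_day,
                            harvest_day = harvest_day, n_days = last)
  trace
}

# End-of-day OP snapshots. OP anchors: OP1 = sowing+30 d; OP2/4/5 = the three
# fertilizations; OP3 = fert1+14 d; OP6 = fert3+14 d; OP7 = harvest. Biomass
# parameter is above-ground at OP1-6, generative at OP7. Unreached OPs yield
# NA rows (scored maximally risky downstream).
op_snapshots <- function(trace, fert_day, harvest_day, n_days) {
  anchor <- c(`1` = 31L,  # day index of sowing is 1, so +30 d
              `2` = fert_day[1], `3` = fert_day[1] + 14L,
              `4` = fert_day[2], `5` = fert_day[3],
              `6` = fert_day[3] + 14L, `7` = harvest_day)
  params <- op_parameter_names(trace$daily)
  out <- data.frame(op = 1:7, day_index = as.integer(anchor))
  mat <- matrix(NA_real_, 7, length(params), dimnames = list(NULL, params))
  for (k in 1:7) {
    di <- anchor[[k]]
    if (!is.na(di) && di <= n_days) {
      row <- trace$daily[di, ]
      mat[k, "lai"] <- row$lai
      mat[k, "bbch"] <- row$bbch
      mat[k, "biomass"] <- if (k == 7) row$gen_biomass else row$agb
      others <- setdiff(params, c("lai", "bbch", "biomass"))
      for (p in others) mat[k, p] <- row[[p]]
    }
  }
  cbind(out, as.data.frame(mat))
}

op_parameter_names <- function(daily) {
  sw <- grep("^sw_", names(daily), value = TRUE)
  st <- grep("^st_", names(daily), value = TRUE)
  c("lai", sw, st, "biomass", "bbch")
}

#' @export
print.growth_trace <- function(x, ...) {
  cat(sprintf("<growth_trace> sowing DOY %d (year %s): %s, yield %.1f dt/ha\n",
              x$sowing_doy, x$sowing_year,
              if (x$failed) "FAILED (maturity not reached)" else "completed",
              x$yield))
  invisible(x)
}

#' Write / read growth traces as long-format CSV
#'
#' Three plain CSV files sharing a `PREFIX`: `PREFIX_daily.csv` (daily
#' states), `PREFIX_events.csv` (management events) and `PREFIX_meta.csv`
#' (per-trace sowing day, yield, failure flag). OP snapshots are
#' reconstructed on read from the stored events and daily states.
#'
#' @param traces a list of `growth_trace` objects.
#' @param prefix file path prefix.
#' @return `write_traces` returns `prefix` invisibly; `read_traces` returns a
#'   list of `growth_trace`.
#' @export
write_traces <- function(traces, prefix) {
  daily <- do.call(rbind, lapply(seq_along(traces), function(i) {
    cbind(trace_id = i, traces[[i]]$daily)
  }))
  events <- do.call(rbind, lapply(seq_along(traces), function(i) {
    cbind(trace_id = i, traces[[i]]$events)
  }))
  meta <- do.call(rbind, lapply(seq_along(traces), function(i) {
    t <- traces[[i]]
    data.frame(trace_id = i, sowing_year = t$sowing_year,
               sowing_doy = t$sowing_doy, yield = t$yield, failed = t$failed)
  }))
  num <- vapply(daily, is.numeric, logical(1)) & names(daily) != "trace_id"
  for (cn in names(daily)[num]) daily[[cn]] <- sprintf("%.9g", daily[[cn]])
  write_csv_strict(daily, paste0(prefix, "_daily.csv"))
  write_csv_strict(events, paste0(prefix, "_events.csv"))
  write_csv_strict(meta, paste0(prefix, "_meta.csv"))
  invisible(prefix)
}

#' @rdname write_traces
#' @export
read_traces <- function(prefix) {
  daily <- read_csv_strict(paste0(prefix, "_daily.csv"))
  events <- read_csv_strict(paste0(prefix, "_events.csv"))
  meta <- read_csv_strict(paste0(prefix, "_meta.csv"))
  lapply(meta$trace_id, function(id) {
    d <- daily[daily$trace_id == id, setdiff(names(daily), "trace_id")]
    rownames(d) <- NULL
    e <- events[events$trace_id == id, setdiff(names(events), "trace_id")]
    rownames(e) <- NULL
    m <- meta[meta$trace_id == id, ]
    tr <- structure(list(
      sowing_year = m$sowing_year, sowing_doy = m$sowing_doy,
      daily = d, events = e, yield = m$yield, failed = m$failed
    ), class = "growth_trace")
    fert_day <- vapply(1:3, function(f) {
      ev <- e[e$kind == paste0("fertilization_", f), ]
      if (nrow(ev) == 0) return(NA_integer_)
      match_day(d, ev$year[1], ev$doy[1])
    }, integer(1))
    hv <- e[e$kind == "harvest", ]
    harvest_day <- if (nrow(hv) == 0) NA_integer_ else
      match_day(d, hv$year[1], hv$doy[1])
    tr$ops <- op_snapshots(tr, fert_day, harvest_day, nrow(d))
    tr
  })
}

match_day <- function(daily, year, doy) {
  i <- which(daily$year == year & daily$doy == doy)
  if (length(i) != 1L) NA_integer_ else as.integer(i)
}
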