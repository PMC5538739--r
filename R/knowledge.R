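#' Observation scheme for mid-season risk monitoring
#'
#' The default scheme scores ten field parameters at seven observation points
#' (OP1-7) plus OP0, the sowing day itself. The parameters are leaf area
#' index, soil water content at four depths, soil temperature at three
#' depths, biomass (above-ground at OP1-6, generative at OP7) and the BBCH
#' development stage. OP0 carries no parameters: it is scored from the
#' historical success frequency of the sowing day of year.
#'
#' @param soil a [soil_profile()] supplying the observation depths.
#' @param include_bbch score BBCH as an observed parameter (`TRUE`, the
#'   default) or use it only as an event trigger.
#' @return an `op_spec`: list with `ops` (integer 1..7, with their anchor
#'   descriptions) and `parameters` (character vector).
#' @export
op_spec <- function(soil = soil_profile(), include_bbch = TRUE) {
  params <- c("lai",
              paste0("sw_", soil$water_depths),
              paste0("st_", soil$temp_depths),
              "biomass")
  if (include_bbch) params <- c(params, "bbch")
  structure(list(
    ops = 1:7,
    anchors = c("sowing + 30 d", "fertilization 1", "fertilization 1 + 14 d",
                "fertilization 2", "fertilization 3", "fertilization 3 + 14 d",
                "harvest"),
    parameters = params
  ), class = "op_spec")
}

#' Build a sowing-date x weather-year grid of simulated seasons
#'
#' Runs [simulate_season()] for every combination of sowing day of year and
#' sowing year, the what-if experience grid from which a knowledge pool is
#' initialised. By default every series year that has a following year is
#' used as a sowing year (the final year cannot host a full season).
#'
#' @param series a `weather_series`.
#' @param doys integer vector of sowing days of year.
#' @param crop a [crop_params()].
#' @param soil a [soil_profile()].
#' @param years sowing years to use; defaults to all but the last series year.
#' @return list of `growth_trace`, of length `length(doys) * length(years)`.
#' @export
build_grid <- function(series, doys, crop = crop_params(), soil = soil_profile(),
                       years = NULL) {
  if (length(doys) < 1L) stop_invalid("build_grid: doys must be non-empty")
  if (is.null(years)) {
    yrs <- sort(unique(series$year))
    if (length(yrs) < 2L) stop_invalid("build_grid: series must span at least 2 years")
    years <- yrs[-length(yrs)]
  }
  combos <- expand.grid(doy = as.integer(doys), year = years)
  traces <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    traces[[i]] <- simulate_season(series, combos$year[i], combos$doy[i],
                                   crop, soil)
  }
  traces
}

#' Keep only seasons whose yield met the still-good-yield threshold
#'
#' A season is kept iff its final yield did not fall below `sgy`
#' (boundary inclusive: yield equal to `sgy` is acceptable).
#'
#' @param traces list of `growth_trace`.
#' @param sgy still-good-yield threshold, dt/ha.
#' @return the kept subset of `traces`.
#' @export
filter_by_sgy <- function(traces, sgy) {
  if (length(traces) < 1L) stop_invalid("filter_by_sgy: no traces supplied")
  yields <- vapply(traces, function(t) t$yield, numeric(1))
  kept <- traces[yields >= sgy]
  if (length(kept) == 0L) {
    stop_invalid("filter_by_sgy: no season reached sgy = ", sgy,
                 " dt/ha; lower the threshold or widen the simulation grid")
  }
  kept
}

#' Tukey boxplot whisker range of a sample
#'
#' Outliers are points below `q1 - 1.5 IQR` or above `q3 + 1.5 IQR`; the
#' whiskers are the most extreme data points that are not outliers, so both
#' returned bounds are actual sample values. Quartiles use linear
#' interpolation between order statistics (R quantile type 7).
#'
#' @param values numeric vector, at least 4 finite values.
#' @return named numeric vector `c(lower, upper)` with attributes `q1`, `q3`,
#'   `iqr` and `n`.
#' @export
#' @examples
#' tukey_whisker_range(c(1:9, 100))  # 100 is fenced out: range (1, 9)
tukey_whisker_range <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 4L) {
    stop_invalid("tukey_whisker_range: need at least 4 finite values")
  }
  q <- stats::quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[2] + 1.5 * iqr
  inner <- values[values >= lo_fence & values <= hi_fence]
  structure(c(lower = min(inner), upper = max(inner)),
            q1 = q[1], q3 = q[2], iqr = iqr, n = length(values))
}

#' Relative sowing-success frequency per day of year
#'
#' For each sowing day of year, the share of simulated seasons whose final
#' yield reached the still-good-yield threshold: the OP0 acceptance
#' information of the knowledge pool.
#'
#' @param traces list of `growth_trace` (all seasons, unfiltered).
#' @param sgy still-good-yield threshold, dt/ha.
#' @return data frame with columns `doy`, `n`, `n_success`, `freq`.
#' @export
op0_frequencies <- function(traces, sgy) {
  if (length(traces) < 1L) stop_invalid("op0_frequencies: no traces supplied")
  doy <- vapply(traces, function(t) t$sowing_doy, integer(1))
  ok <- vapply(traces, function(t) t$yield >= sgy, logical(1))
  agg <- stats::aggregate(list(n = rep(1L, length(doy)), n_success = as.integer(ok)),
                          by = list(doy = doy), FUN = sum)
  agg$freq <- agg$n_success / agg$n
  agg[order(agg$doy), ]
}

#' Initialise a knowledge pool from a simulated experience grid
#'
#' The pool is the modelled farmer's accumulated experience: per-OP,
#' per-parameter acceptance ranges set at the Tukey whiskers of observation
#' values from seasons whose yield reached the still-good-yield threshold,
#' plus per-sowing-DOY success frequencies computed over *all* seasons.
#' Failed seasons (maturity never reached) count as OP0 failures and
#' contribute no snapshots to the ranges.
#'
#' @param traces list of `growth_trace` (the full, unfiltered grid).
#' @param sgy still-good-yield threshold, dt/ha.
#' @param spec an [op_spec()].
#' @return a `knowledge_pool`: list with `sgy`, `ranges` (data frame:
#'   `op, parameter, lower, upper, q1, q3, iqr, n_values`), `op0_freq`,
#'   `values` (the per-(op, parameter) samples retained for later
#'   adaptation), `op0_counts`, `n_traces`, `n_kept` and `provenance`.
#' @export
build_pool <- function(traces, sgy, spec = op_spec()) {
  kept <- filter_by_sgy(traces, sgy)
  op0 <- op0_frequencies(traces, sgy)

  values <- list()
  for (opi in spec$ops) {
    for (p in spec$parameters) {
      v <- vapply(kept, function(t) {
        ops <- t$ops
        if (is.null(ops) || !(p %in% names(ops))) return(NA_real_)
        ops[ops$op == opi, p][1]
      }, numeric(1))
      v <- v[is.finite(v)]
      if (length(v) < 4L) {
        stop_invalid("build_pool: fewer than 4 observations for OP", opi,
                     " parameter '", p, "'; check the observation scheme")
      }
      values[[paste0("op", opi, ".", p)]] <- v
    }
  }

  ranges <- do.call(rbind, lapply(spec$ops, function(opi) {
    do.call(rbind, lapply(spec$parameters, function(p) {
      v <- values[[paste0("op", opi, ".", p)]]
      w <- tukey_whisker_range(v)
      data.frame(op = opi, parameter = p,
                 lower = unname(w["lower"]), upper = unname(w["upper"]),
                 q1 = attr(w, "q1"), q3 = attr(w, "q3"),
                 iqr = attr(w, "iqr"), n_values = attr(w, "n"),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(ranges) <- NULL

  structure(list(
    sgy = sgy,
    ranges = ranges,
    op0_freq = stats::setNames(op0$freq, op0$doy),
    op0_counts = op0[c("doy", "n", "n_success")],
    values = values,
    parameters = spec$parameters,
    ops = spec$ops,
    n_traces = length(traces),
    n_kept = length(kept),
    provenance = list(quantile_type = 7L, whisker = "tukey-1.5-iqr",
                      boundary = "inclusive")
  ), class = "knowledge_pool")
}

#' @export
print.knowledge_pool <- function(x, ...) {
  cat(sprintf("<knowledge_pool> sgy %.2f dt/ha: %d/%d seasons kept, %d ranges, %d sowing DOYs\n",
              x$sgy, x$n_kept, x$n_traces, nrow(x$ranges), length(x$op0_freq)))
  invisible(x)
}

#' Save / load a knowledge pool as JSON
#'
#' The serialization retains the raw per-(OP, parameter) value sets, so a
#' reloaded pool supports year-on-year adaptation exactly like the original;
#' the round trip is lossless.
#'
#' @param pool a `knowledge_pool`.
#' @param path file path.
#' @return `write_pool` returns `path` invisibly; `read_pool` returns a
#'   `knowledge_pool`.
#' @export
write_pool <- function(pool, path) {
  stopifnot(inherits(pool, "knowledge_pool"))
  obj <- unclass(pool)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_pool
#' @export
read_pool <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$ranges <- as.data.frame(obj$ranges, stringsAsFactors = FALSE)
  obj$op0_counts <- as.data.frame(obj$op0_counts)
  # rebuild the named frequency vector from the counts (JSON arrays are
  # nameless)
  obj$op0_freq <- stats::setNames(obj$op0_counts$n_success / obj$op0_counts$n,
                                  obj$op0_counts$doy)
  obj$values <- lapply(obj$values, as.numeric)
  obj$ops <- as.integer(obj$ops)
  obj$n_traces <- as.integer(obj$n_traces)
  obj$n_kept <- as.integer(obj$n_kept)
  structure(obj, class = "knowledge_pool")
}

#' Acceptance-range report in wide (one row per OP bound) form
#'
#' @param pool a `knowledge_pool`.
#' @return data frame with columns `op`, `bound` (`min` / `max`) and one
#'   column per observed parameter.
#' @export
ranges_report <- function(pool) {
  params <- pool$parameters
  out <- do.call(rbind, lapply(pool$ops, function(opi) {
    r <- pool$ranges[pool$ranges$op == opi, ]
    lo <- stats::setNames(r$lower, r$parameter)[params]
    hi <- stats::setNames(r$upper, r$parameter)[params]
    rbind(data.frame(op = opi, bound = "min", t(lo)),
          data.frame(op = opi, bound = "max", t(hi)))
  }))
  rownames(out) <- NULL
  out
}
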