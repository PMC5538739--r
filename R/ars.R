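#' Binary utility score of one observation against its acceptance range
#'
#' Scores 0 (no perceived risk) when the observed value lies inside the
#' acceptance range, boundaries inclusive, and 1 (risky) when it lies
#' outside. Inclusive boundaries reflect that whisker values come from
#' seasons that themselves met the yield threshold.
#'
#' @param value observed parameter value (finite).
#' @param lower,upper acceptance-range bounds.
#' @return integer 0 or 1 (vectorised over `value`).
#' @export
#' @examples
#' score_observation(3.0, 1.32, 4.17)   # inside  -> 0
#' score_observation(5.0, 1.32, 4.17)   # outside -> 1
score_observation <- function(value, lower, upper) {
  if (any(!is.finite(value))) {
    stop_invalid("score_observation: value must be finite")
  }
  as.integer(value < lower | value > upper)
}

#' Per-observation-point utility sum
#'
#' The OP-level risk score is the count of observed parameters lying outside
#' their acceptance ranges at that observation point.
#'
#' @param obs named numeric vector of parameter values at one OP.
#' @param op_index which OP the observations belong to (1..7).
#' @param pool a `knowledge_pool`.
#' @return integer in `[0, n_parameters]`.
#' @export
score_op <- function(obs, op_index, pool) {
  r <- pool$ranges[pool$ranges$op == op_index, ]
  if (nrow(r) == 0L) stop_invalid("score_op: pool has no ranges for OP", op_index)
  missing <- setdiff(names(obs), r$parameter)
  if (length(missing) > 0L) {
    stop_invalid("score_op: no acceptance range for parameter(s) ",
                 paste(missing, collapse = ", "), " at OP", op_index)
  }
  total <- 0L
  for (p in names(obs)) {
    ri <- r[r$parameter == p, ]
    total <- total + score_observation(obs[[p]], ri$lower, ri$upper)
  }
  total
}

#' OP0 score: desirability of the sowing day
#'
#' A sowing day whose historical relative frequency of yields at or above
#' the still-good-yield threshold is below 0.5 scores 1 (more than half of
#' past seasons from that day disappointed); a frequency of exactly 0.5 or
#' more scores 0. A day absent from the pool is treated as risky, with a
#' warning.
#'
#' @param sowing_doy sowing day of year.
#' @param pool a `knowledge_pool`.
#' @return integer 0 or 1.
#' @export
score_op0 <- function(sowing_doy, pool) {
  f <- pool$op0_freq[as.character(sowing_doy)]
  if (is.na(f)) {
    warning("score_op0: sowing DOY ", sowing_doy,
            " not in pool; scored as risky", call. = FALSE)
    return(1L)
  }
  as.integer(f < 0.5)
}

#' Annual Risk Score of one season
#'
#' Sums the binary per-parameter utilities over all observation points plus
#' the OP0 sowing-day score. Observation points the season never reached
#' (failed seasons) score their full parameter count: a season that dies
#' mid-way must not out-score a completed risky one. Scoring never mutates
#' the trace or the pool.
#'
#' @param trace a `growth_trace`.
#' @param pool a `knowledge_pool`.
#' @return an `ars_record`: list with `year`, `sowing_doy`, `op0`,
#'   `alpha` (per-OP utility sums, named `alpha_1`..`alpha_7`), `total`,
#'   `max_possible`, `yield` and `failed`.
#' @export
score_season <- function(trace, pool) {
  params <- pool$parameters
  ops <- pool$ops
  if (is.null(trace$ops)) stop_invalid("score_season: trace carries no OP snapshots")
  if (!all(params %in% names(trace$ops))) {
    stop_invalid("score_season: trace snapshots lack parameter(s) ",
                 paste(setdiff(params, names(trace$ops)), collapse = ", "))
  }
  alpha <- integer(length(ops))
  names(alpha) <- paste0("alpha_", ops)
  for (k in seq_along(ops)) {
    row <- trace$ops[trace$ops$op == ops[k], params]
    vals <- as.numeric(row[1, ])
    if (any(!is.finite(vals))) {
      alpha[k] <- length(params)  # OP not reached: maximally risky
    } else {
      alpha[k] <- score_op(stats::setNames(vals, params), ops[k], pool)
    }
  }
  op0 <- score_op0(trace$sowing_doy, pool)
  structure(list(
    year = trace$sowing_year, sowing_doy = trace$sowing_doy,
    op0 = op0, alpha = alpha,
    total = op0 + sum(alpha),
    max_possible = 1L + length(ops) * length(params),
    yield = trace$yield, failed = trace$failed
  ), class = "ars_record")
}

#' @export
print.ars_record <- function(x, ...) {
  cat(sprintf("<ars_record> year %s, DOY %d: ARS %d / %d (yield %.1f dt/ha)\n",
              x$year, x$sowing_doy, x$total, x$max_possible, x$yield))
  invisible(x)
}

#' Score a set of seasons and tabulate the records
#'
#' @param traces list of `growth_trace`.
#' @param pool a `knowledge_pool`.
#' @return data frame with one row per season: `year`, `sowing_doy`, `op0`,
#'   `alpha_1`..`alpha_7`, `total`, `max_possible`, `yield`, `failed`.
#' @export
score_seasons <- function(traces, pool) {
  rows <- lapply(traces, function(t) {
    r <- score_season(t, pool)
    cbind(data.frame(year = r$year, sowing_doy = r$sowing_doy, op0 = r$op0),
          as.data.frame(as.list(r$alpha)),
          data.frame(total = r$total, max_possible = r$max_possible,
                     yield = r$yield, failed = r$failed))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write / read a season score table as CSV
#'
#' @param scores data frame from [score_seasons()].
#' @param path file path.
#' @return `write_scores` returns `path` invisibly; `read_scores` the table.
#' @export
write_scores <- function(scores, path) {
  df <- scores
  df$yield <- sprintf("%.6f", df$yield)
  write_csv_strict(df, path)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  read_csv_strict(path)
}
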