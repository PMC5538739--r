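# Shared miniature fixtures, built once per test run.

fix_env <- new.env()

# 6-year weather series under the default climate
tiny_weather <- function() {
  if (is.null(fix_env$weather)) {
    fix_env$weather <- generate_weather(climate_params(), 6, seed = 42)
  }
  fix_env$weather
}

# 3 sowing DOYs x 5 years = 15 traces
tiny_traces <- function() {
  if (is.null(fix_env$traces)) {
    fix_env$traces <- build_grid(tiny_weather(), c(285, 300, 315))
  }
  fix_env$traces
}

# pool over the tiny grid; sgy low enough that >= 4 seasons survive per cell
tiny_pool <- function(sgy = 55) {
  key <- paste0("pool", sgy)
  if (is.null(fix_env[[key]])) {
    fix_env[[key]] <- build_pool(tiny_traces(), sgy)
  }
  fix_env[[key]]
}

# A hand-made pool whose ranges and OP0 table are fully controlled.
# `ranges` maps every (op 1..7, parameter) to the same (lower, upper).
fake_pool <- function(lower, upper, params = c("lai", "biomass"),
                      op0 = c(`290` = 0.8, `320` = 0.2), sgy = 69.17) {
  ranges <- expand.grid(op = 1:7, parameter = params,
                        stringsAsFactors = FALSE)
  ranges$lower <- lower
  ranges$upper <- upper
  ranges$q1 <- lower; ranges$q3 <- upper
  ranges$iqr <- upper - lower; ranges$n_values <- 10L
  structure(list(
    sgy = sgy, ranges = ranges, op0_freq = op0,
    op0_counts = data.frame(doy = as.integer(names(op0)),
                            n = 10L, n_success = as.integer(10 * op0)),
    values = list(), parameters = params, ops = 1:7,
    n_traces = 10L, n_kept = 8L,
    provenance = list(quantile_type = 7L)
  ), class = "knowledge_pool")
}

# A hand-made trace carrying only what scoring needs: one OP-snapshot value
# per (op, parameter), a sowing DOY and a yield.
fake_trace <- function(op_values, params, sowing_doy = 290, yield = 75,
                       failed = FALSE) {
  ops <- data.frame(op = 1:7)
  for (p in params) ops[[p]] <- op_values[[p]]
  structure(list(sowing_year = 1L, sowing_doy = as.integer(sowing_doy),
                 daily = NULL, events = NULL, ops = ops,
                 yield = yield, failed = failed),
            class = "growth_trace")
}

# Independent O(n^2) fence-scan oracle for the whisker rule: quartiles by
# linear interpolation, then scan every data point against the fences.
oracle_whiskers <- function(x) {
  q1 <- stats::quantile(x, 0.25, type = 7, names = FALSE)
  q3 <- stats::quantile(x, 0.75, type = 7, names = FALSE)
  iqr <- q3 - q1
  lo <- Inf; hi <- -Inf
  for (v in x) {
    if (v >= q1 - 1.5 * iqr && v < lo) lo <- v
    if (v <= q3 + 1.5 * iqr && v > hi) hi <- v
  }
  c(lo, hi)
}
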