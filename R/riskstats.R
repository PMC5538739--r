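#' Moment skewness of a sample
#'
#' Population moment-ratio estimator `m3 / m2^(3/2)` with central moments
#' `m_k = mean((x - mean(x))^k)`. Returns `NA` when the sample has no
#' spread (skewness undefined).
#'
#' @param x numeric vector.
#' @return numeric scalar (or `NA`).
#' @export
skewness <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 2L) return(NA_real_)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 <= 0) return(NA_real_)
  mean((x - m)^3) / m2^1.5
}

#' Mean-standard-deviation risk summary of one scenario
#'
#' Summarises a yield series and its Annual Risk Scores into the
#' comparative-statics row used for scenario analysis: yield moments
#' (mean, SD with the n-1 denominator, moment skewness, coefficient of
#' variation), the relative frequency of yields at or above the
#' still-good-yield threshold (boundary inclusive), and the mean and SD of
#' the ARS series.
#'
#' @param yields numeric vector of seasonal yields, dt/ha.
#' @param ars numeric vector of ARS totals, same length as `yields`.
#' @param sgy still-good-yield threshold, dt/ha.
#' @param label scenario label.
#' @return one-row data frame of class `yield_risk_summary` with columns
#'   `scenario, mean_yield, sd_yield, skewness, var_coef, freq_ge_sgy,
#'   mean_ars, sd_ars, n`.
#' @export
summarize_risk <- function(yields, ars, sgy, label = "scenario") {
  if (length(yields) != length(ars)) {
    stop_invalid("summarize_risk: yields and ars must have equal length")
  }
  if (length(yields) < 2L) {
    stop_invalid("summarize_risk: need at least 2 seasons")
  }
  m <- mean(yields)
  s <- stats::sd(yields)
  out <- data.frame(
    scenario = label,
    mean_yield = m,
    sd_yield = s,
    skewness = skewness(yields),
    var_coef = if (m != 0) s / m else NA_real_,
    freq_ge_sgy = mean(yields >= sgy),
    mean_ars = mean(ars),
    sd_ars = stats::sd(ars),
    n = length(yields),
    stringsAsFactors = FALSE
  )
  class(out) <- c("yield_risk_summary", "data.frame")
  out
}

#' Compare scenarios and flag yield-level vs ARS-level ranking divergence
#'
#' Builds one [summarize_risk()] row per scenario and flags scenarios where
#' the two statistic families tell different stories: a scenario whose rank
#' by yield standard deviation (a classic mean-variance risk reading)
#' differs from its rank by mean ARS (the mid-season perception reading) by
#' at least `rank_gap` positions. Such divergence is exactly the situation
#' where mid-season scoring adds information a yield-only analysis misses.
#'
#' @param scenarios named list; each element a list with numeric elements
#'   `yields` and `ars`.
#' @param sgy still-good-yield threshold, dt/ha.
#' @param rank_gap minimum rank difference that raises the divergence flag.
#' @return data frame: one summary row per scenario plus `rank_sd_yield`,
#'   `rank_mean_ars` and logical `divergent`.
#' @export
compare_scenarios <- function(scenarios, sgy, rank_gap = 3) {
  if (length(scenarios) < 1L) stop_invalid("compare_scenarios: no scenarios")
  labs <- names(scenarios)
  if (is.null(labs)) labs <- as.character(seq_along(scenarios))
  tab <- do.call(rbind, lapply(seq_along(scenarios), function(i) {
    s <- scenarios[[i]]
    summarize_risk(s$yields, s$ars, sgy, labs[i])
  }))
  tab$rank_sd_yield <- rank(tab$sd_yield, ties.method = "average")
  tab$rank_mean_ars <- rank(tab$mean_ars, ties.method = "average")
  tab$divergent <- abs(tab$rank_sd_yield - tab$rank_mean_ars) >= rank_gap
  rownames(tab) <- NULL
  tab
}
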