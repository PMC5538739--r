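#' Validate farmer yield elicitations
#'
#' Each record is a (peak yield, still-good yield, average yield) triple for
#' one farmer and crop. Peak yield must not fall below the still-good yield
#' (otherwise the tolerated fluctuation band would be negative) and all
#' present values must be positive. Invalid records are rejected with a
#' reason rather than silently dropped.
#'
#' @param records data frame with columns `farmer_id`, `crop`, `py`, `sgy`,
#'   `avy_farm` (missing values allowed field-wise).
#' @return list with `valid` (the accepted records) and `rejected`
#'   (data frame of records with a `reason` column).
#' @export
validate_elicitations <- function(records) {
  need <- c("farmer_id", "crop", "py", "sgy", "avy_farm")
  if (!all(need %in% names(records))) {
    stop_invalid("validate_elicitations: need columns ",
                 paste(need, collapse = ", "))
  }
  reason <- character(nrow(records))
  nonpos <- function(x) !is.na(x) & x <= 0
  bad_pos <- nonpos(records$py) | nonpos(records$sgy) | nonpos(records$avy_farm)
  reason[bad_pos] <- "non-positive yield value"
  bad_band <- !is.na(records$py) & !is.na(records$sgy) & records$py < records$sgy
  reason[bad_band & reason == ""] <- "peak yield below still-good yield"
  list(valid = records[reason == "", , drop = FALSE],
       rejected = cbind(records[reason != "", , drop = FALSE],
                        reason = reason[reason != ""]))
}

#' Willingness to accept yield fluctuation
#'
#' `wta = py - sgy`: the band of yield outcomes below the peak a farmer
#' tolerates before perceiving economic loss.
#'
#' @param py peak yield, dt/ha.
#' @param sgy still-good yield, dt/ha.
#' @return dt/ha (vectorised).
#' @export
#' @examples
#' wta(87.78, 69.17)  # 18.61 dt/ha
wta <- function(py, sgy) {
  if (any(py < sgy, na.rm = TRUE)) {
    stop_invalid("wta: peak yield below still-good yield")
  }
  py - sgy
}

#' Classify a farmer's downside-risk sensitivity type
#'
#' Two conditions define the type for a crop: whether the declared
#' still-good yield exceeds the farm's own average yield, and whether the
#' farm's average exceeds the regional average. A farmer declaring
#' `sgy > avy_farm` despite `avy_farm > avy_region` is highly sensitive to
#' yield fluctuation; `sgy <= avy_farm` with an above-region farm is the
#' low-sensitive case. The two below-region quadrants are labelled
#' `underperforming_context` (demanding sgy on a below-average farm) and
#' `standard`. Ties fall to the less sensitive side.
#'
#' @param sgy still-good yield, dt/ha.
#' @param avy_farm farm average yield, dt/ha.
#' @param avy_region regional average yield, dt/ha (> 0).
#' @return factor with levels `high_sensitive`, `low_sensitive`,
#'   `underperforming_context`, `standard` (vectorised).
#' @export
classify_sensitivity <- function(sgy, avy_farm, avy_region) {
  if (any(avy_region <= 0)) stop_invalid("classify_sensitivity: avy_region must be > 0")
  demanding <- sgy > avy_farm          # ties -> not demanding (less sensitive)
  above_region <- avy_farm > avy_region
  out <- ifelse(above_region,
                ifelse(demanding, "high_sensitive", "low_sensitive"),
                ifelse(demanding, "underperforming_context", "standard"))
  factor(out, levels = c("high_sensitive", "low_sensitive",
                         "underperforming_context", "standard"))
}

#' Descriptive statistics of elicited yield triples
#'
#' Per-variable summary (mean, min, max, SD, moment skewness, variance,
#' coefficient of variation, n) over valid records, with per-variable n
#' reflecting field-wise missingness, plus the count and share of highly
#' sensitive farmers relative to the regional average yield.
#'
#' @param records data frame as in [validate_elicitations()].
#' @param avy_region regional average yield, dt/ha.
#' @return list with `stats` (data frame, one row per variable), `types`
#'   (per-record sensitivity factor), `n_high_sensitive` and
#'   `share_high_sensitive` (in percent).
#' @export
summarize_elicitations <- function(records, avy_region) {
  v <- validate_elicitations(records)$valid
  if (nrow(v) < 2L) stop_invalid("summarize_elicitations: need >= 2 valid records")
  one <- function(x, label) {
    x <- x[is.finite(x)]
    m <- mean(x); s <- stats::sd(x)
    data.frame(variable = label, mean = m, min = min(x), max = max(x),
               sd = s, skewness = skewness(x), variance = stats::var(x),
               var_coef = if (m != 0) s / m else NA_real_, n = length(x),
               stringsAsFactors = FALSE)
  }
  stats_tab <- rbind(one(v$py, "peak_yield"),
                     one(v$sgy, "still_good_yield"),
                     one(v$avy_farm, "average_yield"))
  complete <- !is.na(v$sgy) & !is.na(v$avy_farm)
  types <- rep(NA_character_, nrow(v))
  types[complete] <- as.character(
    classify_sensitivity(v$sgy[complete], v$avy_farm[complete], avy_region))
  n_high <- sum(types == "high_sensitive", na.rm = TRUE)
  n_typed <- sum(complete)
  list(stats = stats_tab,
       types = factor(types, levels = levels(classify_sensitivity(1, 2, 1))),
       n_high_sensitive = n_high,
       share_high_sensitive = if (n_typed > 0) 100 * n_high / n_typed else NA_real_)
}

#' Read a survey CSV (`farmer_id,crop,py,sgy,avy_farm`)
#'
#' @param path file path.
#' @return data frame.
#' @export
read_survey <- function(path) {
  df <- read_csv_strict(path)
  need <- c("farmer_id", "crop", "py", "sgy", "avy_farm")
  if (!all(need %in% names(df))) {
    stop_invalid("read_survey: missing columns: ",
                 paste(setdiff(need, names(df)), collapse = ", "))
  }
  df
}
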