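#' Year-on-year adaptation of a knowledge pool
#'
#' After a season has been scored, the modelled farmer's experience pool may
#' absorb it. Three situations arise. If the season's yield reached the
#' still-good-yield threshold, its observation values join the per-(OP,
#' parameter) value sets — whether they fell inside the current ranges (no
#' shift expected) or outside (a non-downside-risk outlier that, as such
#' values accumulate, gradually shifts the range) — and the whisker ranges
#' are recomputed on the enlarged sets. If the yield fell below the
#' threshold, the expected loss confirms the current perception and the
#' ranges are left untouched. OP0 sowing-success counts can optionally be
#' updated with the season's outcome in either case (`update_op0 = TRUE`);
#' the default leaves the pool bit-identical for below-threshold seasons.
#'
#' @param pool a `knowledge_pool`.
#' @param trace the season's `growth_trace` (must carry OP snapshots).
#' @param record the season's `ars_record` from [score_season()] (used for
#'   consistency checks; the yield gate reads the trace).
#' @param update_op0 also fold the season's sowing outcome into the OP0
#'   frequencies (default `FALSE`).
#' @return the updated `knowledge_pool` (the input pool is not modified).
#' @export
update_pool <- function(pool, trace, record, update_op0 = FALSE) {
  stopifnot(inherits(pool, "knowledge_pool"))
  if (is.null(trace$ops)) stop_invalid("update_pool: trace carries no OP snapshots")
  if (!all(pool$parameters %in% names(trace$ops))) {
    stop_invalid("update_pool: trace snapshots do not cover the pool's parameters")
  }
  if (!is.null(record$yield) && !isTRUE(all.equal(record$yield, trace$yield))) {
    stop_invalid("update_pool: record and trace disagree on yield; was the trace scored against this pool?")
  }
  out <- pool
  acceptable <- trace$yield >= pool$sgy
  if (acceptable) {
    for (opi in pool$ops) {
      row <- trace$ops[trace$ops$op == opi, pool$parameters]
      for (p in pool$parameters) {
        v <- row[[p]][1]
        if (!is.finite(v)) next  # unreached OP contributes nothing
        key <- paste0("op", opi, ".", p)
        out$values[[key]] <- c(out$values[[key]], v)
        w <- tukey_whisker_range(out$values[[key]])
        sel <- out$ranges$op == opi & out$ranges$parameter == p
        out$ranges[sel, c("lower", "upper", "q1", "q3", "iqr", "n_values")] <-
          list(unname(w["lower"]), unname(w["upper"]),
               attr(w, "q1"), attr(w, "q3"), attr(w, "iqr"), attr(w, "n"))
      }
    }
    out$n_traces <- out$n_traces + 1L
    out$n_kept <- out$n_kept + 1L
  }
  if (update_op0) {
    d <- as.character(trace$sowing_doy)
    oc <- out$op0_counts
    i <- match(trace$sowing_doy, oc$doy)
    if (is.na(i)) {
      oc <- rbind(oc, data.frame(doy = trace$sowing_doy, n = 1L,
                                 n_success = as.integer(acceptable)))
      oc <- oc[order(oc$doy), ]
    } else {
      oc$n[i] <- oc$n[i] + 1L
      oc$n_success[i] <- oc$n_success[i] + as.integer(acceptable)
    }
    out$op0_counts <- oc
    out$op0_freq <- stats::setNames(oc$n_success / oc$n, oc$doy)
    if (!acceptable) out$n_traces <- out$n_traces + 1L
  }
  out
}

#' Expected Annual Risk Score from a scoring history
#'
#' Weighted mean of past ARS totals for a crop. How past seasons are
#' weighted is a modelling choice about learning, so the scheme is
#' pluggable: `uniform` (the default: plain average of past scores),
#' `exp_decay` (weights proportional to `lambda^age`, age 0 = most recent),
#' or `window` (uniform over the most recent `window` seasons). Explicit
#' `weights` override the scheme.
#'
#' @param totals numeric vector of past ARS totals, oldest first.
#' @param scheme weighting scheme.
#' @param lambda decay factor in `(0, 1]` for `exp_decay`.
#' @param window number of most recent seasons for `window`.
#' @param weights optional explicit non-negative weights (same length as
#'   `totals`); normalised to sum 1.
#' @return the expected ARS (numeric scalar).
#' @export
#' @examples
#' expected_ars(c(4, 5, 3))                                  # 4
#' expected_ars(c(2, 4, 6), weights = c(0.2, 0.3, 0.5))      # 4.6
expected_ars <- function(totals, scheme = c("uniform", "exp_decay", "window"),
                         lambda = 0.8, window = 5, weights = NULL) {
  if (length(totals) < 1L) stop_invalid("expected_ars: empty history")
  if (!is.null(weights)) {
    if (length(weights) != length(totals) || any(weights < 0) ||
        any(!is.finite(weights)) || sum(weights) <= 0) {
      stop_invalid("expected_ars: weights must be non-negative, finite, matching length")
    }
    return(sum(totals * weights / sum(weights)))
  }
  scheme <- match.arg(scheme)
  n <- length(totals)
  w <- switch(scheme,
    uniform = rep(1, n),
    exp_decay = {
      if (lambda <= 0 || lambda > 1) stop_invalid("expected_ars: lambda must be in (0, 1]")
      lambda^((n - 1):0)
    },
    window = c(rep(0, max(0, n - window)), rep(1, min(n, window)))
  )
  sum(totals * w / sum(w))
}

#' Evaluate the per-crop planning constraint
#'
#' For each crop, the ARS totals of the current year's fields allocated to
#' that crop are summed and compared with the crop's expected ARS. Two
#' readings of the comparison ship: `literal` keeps the constraint
#' "current score >= expected" as stated for planning; `inverted` flips it
#' to the risk-averse reading (a higher ARS means more perceived risk, so a
#' current score above expectation flags the crop). Crops violating the
#' active rule are candidates for reallocation of their fields.
#'
#' @param fields data frame with columns `field`, `crop`, `ars` (the latest
#'   year's ARS per field).
#' @param expected named numeric vector: expected ARS per crop, e.g. from
#'   [expected_ars()].
#' @param mode `"literal"` or `"inverted"`.
#' @return data frame: one row per crop with `crop`, `ars_sum`,
#'   `expected`, `satisfied`, plus attribute `violating_fields`.
#' @export
planning_constraint <- function(fields, expected, mode = c("literal", "inverted")) {
  mode <- match.arg(mode)
  need <- c("field", "crop", "ars")
  if (!all(need %in% names(fields))) {
    stop_invalid("planning_constraint: fields needs columns ",
                 paste(need, collapse = ", "))
  }
  crops <- unique(fields$crop)
  missing <- setdiff(crops, names(expected))
  if (length(missing) > 0L) {
    stop_invalid("planning_constraint: no expected ARS for crop(s) ",
                 paste(missing, collapse = ", "))
  }
  out <- do.call(rbind, lapply(crops, function(cr) {
    s <- sum(fields$ars[fields$crop == cr])
    e <- unname(expected[[cr]])
    data.frame(crop = cr, ars_sum = s, expected = e,
               satisfied = if (mode == "literal") s >= e else s <= e,
               stringsAsFactors = FALSE)
  }))
  bad_crops <- out$crop[!out$satisfied]
  attr(out, "violating_fields") <- fields[fields$crop %in% bad_crops,
                                          c("field", "crop", "ars")]
  attr(out, "mode") <- mode
  out
}
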