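test_that("the what-if grid has one trace per (sowing DOY, weather year)", {
  traces <- tiny_traces()
  expect_length(traces, 3 * 5)
  combos <- unique(data.frame(
    doy = vapply(traces, `[[`, integer(1), "sowing_doy"),
    year = vapply(traces, `[[`, 0, "sowing_year")))
  expect_equal(nrow(combos), 15)
  # identical inputs -> identical trace set
  again <- build_grid(tiny_weather(), c(285, 300, 315))
  expect_equal(again, traces)
  expect_error(build_grid(tiny_weather(), integer(0)), "non-empty")
})

test_that("the sgy filter keeps seasons at or above the threshold, boundary inclusive", {
  mk <- function(y) fake_trace(list(lai = 1, biomass = 1),
                               c("lai", "biomass"), yield = y)
  traces <- lapply(c(70, 68, 69.17), mk)
  kept <- filter_by_sgy(traces, 69.17)
  expect_equal(vapply(kept, `[[`, 0, "yield"), c(70, 69.17))
  expect_length(filter_by_sgy(traces, 0), 3)
  expect_error(filter_by_sgy(traces, 1000), "lower the threshold")
})

test_that("whisker bounds are inner data points under the 1.5 IQR fences", {
  expect_equal(as.numeric(tukey_whisker_range(c(5, 5, 5, 5))), c(5, 5))
  expect_equal(as.numeric(tukey_whisker_range(1:10)), c(1, 10))
  # 100 lies beyond q3 + 1.5 IQR; the upper whisker falls back to 9
  expect_equal(as.numeric(tukey_whisker_range(c(1:9, 100))), c(1, 9))
  expect_error(tukey_whisker_range(c(1, 2, 3)), "at least 4")
  # property: equals (min, max) when no fence is crossed, and always matches
  # the exhaustive fence-scan oracle
  set.seed(7)
  for (i in 1:200) {
    x <- stats::rlnorm(sample(4:40, 1), sdlog = sample(c(0.2, 1.5), 1))
    w <- tukey_whisker_range(x)
    expect_equal(as.numeric(w), oracle_whiskers(x))
    expect_gte(w[["lower"]], min(x))
    expect_lte(w[["upper"]], max(x))
  }
})

test_that("OP0 frequencies are per-DOY success ratios over all seasons", {
  mk <- function(doy, y) fake_trace(list(lai = 1, biomass = 1),
                                    c("lai", "biomass"),
                                    sowing_doy = doy, yield = y)
  traces <- c(lapply(c(80, 60, 70, 75), mk, doy = 290),
              lapply(c(60, 60, 80), mk, doy = 300))
  f <- op0_frequencies(traces, sgy = 69.17)
  expect_equal(f$freq[f$doy == 290], 3 / 4)
  expect_equal(f$freq[f$doy == 300], 1 / 3)
  expect_equal(f$n, c(4L, 3L))
  # brute-force tally over a simulated set
  f2 <- op0_frequencies(tiny_traces(), 65)
  for (d in f2$doy) {
    ys <- vapply(Filter(function(t) t$sowing_doy == d, tiny_traces()),
                 `[[`, 0, "yield")
    expect_equal(f2$freq[f2$doy == d], mean(ys >= 65))
  }
})

test_that("the pool covers every (OP, parameter), built on filtered seasons only", {
  pool <- tiny_pool()
  spec <- op_spec()
  expect_equal(nrow(pool$ranges), 7 * 10)
  expect_equal(nrow(unique(pool$ranges[c("op", "parameter")])), 70)
  expect_true(all(pool$ranges$lower <= pool$ranges$upper))
  expect_lte(pool$n_kept, pool$n_traces)
  # every range lies within the min/max of its contributing values
  for (i in seq_len(nrow(pool$ranges))) {
    r <- pool$ranges[i, ]
    v <- pool$values[[paste0("op", r$op, ".", r$parameter)]]
    expect_gte(r$lower, min(v))
    expect_lte(r$upper, max(v))
    expect_equal(r$n_values, length(v))
  }
})

test_that("filtering never widens a range relative to the unfiltered pool", {
  pool_f <- tiny_pool(55)
  pool_all <- build_pool(tiny_traces(), sgy = 0)
  m <- merge(pool_f$ranges, pool_all$ranges, by = c("op", "parameter"),
             suffixes = c("_f", "_all"))
  width_f <- m$upper_f - m$lower_f
  width_all <- m$upper_all - m$lower_all
  expect_true(all(width_f <= width_all + 1e-9))
})

test_that("the harvest OP observes generative, not above-ground, biomass", {
  tr <- tiny_traces()[[1]]
  hv <- tr$events[tr$events$kind == "harvest", ]
  i <- which(tr$daily$year == hv$year & tr$daily$doy == hv$doy)
  expect_equal(tr$ops$biomass[tr$ops$op == 7], tr$daily$gen_biomass[i])
  expect_equal(tr$ops$biomass[tr$ops$op == 1],
               tr$daily$agb[tr$ops$day_index[tr$ops$op == 1]])
})

test_that("a pool round-trips losslessly through JSON", {
  pool <- tiny_pool()
  path <- withr::local_tempfile(fileext = ".json")
  write_pool(pool, path)
  back <- read_pool(path)
  expect_equal(back$ranges, pool$ranges)
  expect_equal(back$op0_freq, pool$op0_freq)
  expect_equal(back$values, pool$values)
  expect_equal(back$sgy, pool$sgy)
  expect_equal(back$n_kept, pool$n_kept)
  # byte-determinism of the serialization itself
  path2 <- withr::local_tempfile(fileext = ".json")
  write_pool(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("relative range widths tighten toward harvest (logged diagnostic)", {
  pool <- tiny_pool()
  r <- pool$ranges
  relw <- function(op, p) {
    x <- r[r$op == op & r$parameter == p, ]
    (x$upper - x$lower) / abs((x$upper + x$lower) / 2)
  }
  tighter <- vapply(pool$parameters, function(p) relw(7, p) < relw(1, p),
                    logical(1))
  # distribution-dependent (and undefined where the mid-point is 0, e.g. a
  # fully senesced canopy), so report rather than hard-assert every parameter
  expect_gte(sum(tighter, na.rm = TRUE), 1)
})
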