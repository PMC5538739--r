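test_that("thermal time accumulates max(0, tmean - base) and matches a day loop", {
  w <- tiny_weather()
  # constant-temperature arithmetic on a synthetic series
  ws <- w
  ws$tmean <- 5
  expect_equal(thermal_time(ws, 1, 1, base_temp = 5)[1:10], rep(0, 10))
  ws$tmean <- 10
  expect_equal(thermal_time(ws, 1, 1, base_temp = 5)[10], 50)
  # mixed real series vs an independent loop
  tt <- thermal_time(w, 2, 100, base_temp = 0)
  idx <- which(w$year == 2 & w$doy == 100)
  acc <- 0; oracle <- numeric(length(tt))
  for (i in seq_along(tt)) {
    acc <- acc + max(0, w$tmean[idx + i - 1])
    oracle[i] <- acc
  }
  expect_equal(tt, oracle)
  expect_true(all(diff(tt) >= 0))
  expect_error(thermal_time(w, 99, 1), "not found")
})

test_that("soil temperature is a damped, lagged response to air temperature", {
  # constant forcing: every depth converges to the air temperature
  st <- soil_temperature_profile(rep(12, 400), depths = c(5, 10, 50), init = 0)
  expect_equal(unname(st[400, ]), rep(12, 3), tolerance = 1e-3)
  # sinusoidal forcing: amplitude shrinks with depth
  air <- 10 + 8 * sin(2 * pi * (1:730) / 365)
  st <- soil_temperature_profile(air, depths = c(5, 50))
  amp <- apply(st[366:730, ], 2, function(x) diff(range(x)))
  expect_lt(amp["st_50"], amp["st_5"])
  # step forcing: time to half-response grows with depth
  st <- soil_temperature_profile(c(rep(0, 50), rep(10, 200)), depths = c(5, 50),
                                 init = 0)
  half <- apply(st[51:250, ], 2, function(x) which(x >= 5)[1])
  expect_gt(half["st_50"], half["st_5"])
  expect_error(soil_temperature_profile(numeric(0)), "empty")
})

test_that("the soil water bucket conserves mass and respects capacity", {
  soil <- soil_profile()
  # closed system: no rain, no demand, no crop -> contents unchanged
  s0 <- step_soil_water(soil$init_water, precip = 0, pet = 0, lai = 0, soil)
  expect_equal(s0$water, soil$init_water)
  expect_equal(s0$drainage + s0$et, 0)
  # heavy rain from field capacity: layers capped, excess leaves the profile
  s1 <- step_soil_water(soil$field_capacity, precip = 50, pet = 0, lai = 0, soil)
  expect_true(all(s1$water <= soil$field_capacity + 1e-9))
  expect_equal(s1$drainage, 50, tolerance = 1e-9)
  # daily mass balance closes to 1e-9 across random forcing
  set.seed(1)
  water <- soil$init_water
  for (i in 1:200) {
    pr <- stats::rexp(1, 1 / 4) * (stats::runif(1) < 0.4)
    pet <- stats::runif(1, 0, 5)
    lai <- stats::runif(1, 0, 6)
    s <- step_soil_water(water, pr, pet, lai, soil)
    old_mm <- sum(water / 100 * soil$thickness_mm)
    new_mm <- sum(s$water / 100 * soil$thickness_mm)
    expect_equal(new_mm, old_mm + pr - s$drainage - s$et, tolerance = 1e-9)
    expect_true(all(s$water >= soil$wilting_point - 1e-9))
    water <- s$water
  }
  # dry spell under full canopy: top layer drains down monotonically
  water <- soil$init_water
  top <- numeric(30)
  for (i in 1:30) {
    s <- step_soil_water(water, 0, 3, lai = 5, soil)
    top[i] <- s$water[1]
    water <- s$water
  }
  expect_true(all(diff(top) < 1e-12))
})

test_that("a season fires management events in order with BBCH-consistent triggers", {
  tr <- simulate_season(tiny_weather(), 1, 285)
  ev <- tr$events
  expect_identical(ev$kind, c("sowing", "fertilization_1", "fertilization_2",
                              "fertilization_3", "harvest"))
  day_no <- (ev$year - 1) * 365 + ev$doy
  expect_true(all(diff(day_no) > 0))
  # BBCH at each fertilization is at or past its trigger stage
  for (f in 1:3) {
    e <- ev[ev$kind == paste0("fertilization_", f), ]
    b <- tr$daily$bbch[tr$daily$year == e$year & tr$daily$doy == e$doy]
    expect_gte(b, c(25, 30, 39)[f])
  }
  expect_true(all(diff(tr$daily$bbch) >= 0))
  expect_true(all(tr$daily$gen_biomass <= tr$daily$agb + 1e-9))
  expect_equal(tr$yield, tr$daily$gen_biomass[nrow(tr$daily)] / 100)
})

test_that("no radiation means no assimilation and effectively no yield", {
  w <- tiny_weather()
  w$radiation <- 0
  tr <- simulate_season(w, 1, 285)
  expect_equal(max(tr$daily$agb), crop_params()$seed_agb)
  expect_lt(tr$yield, 1)
})

test_that("a season that cannot reach maturity is flagged failed with zero yield", {
  w <- generate_weather(climate_params(), 2, seed = 2)
  # sown in the final series year, so the series ends before maturity
  expect_warning(tr <- simulate_season(w, 2, 300), "maturity")
  expect_true(tr$failed)
  expect_equal(tr$yield, 0)
  expect_false("harvest" %in% tr$events$kind)
  expect_true(any(is.na(tr$ops$biomass)))  # unreached OPs carry NA snapshots
})

test_that("earlier autumn sowing out-yields the latest sowing on average", {
  w <- tiny_weather()
  early <- vapply(1:5, function(y) simulate_season(w, y, 283)$yield, numeric(1))
  late <- vapply(1:5, function(y) simulate_season(w, y, 328)$yield, numeric(1))
  expect_gt(mean(early), mean(late))
})

test_that("growth traces round-trip through the long-format CSV files", {
  traces <- tiny_traces()[1:3]
  prefix <- file.path(withr::local_tempdir(), "tr")
  write_traces(traces, prefix)
  back <- read_traces(prefix)
  expect_length(back, 3)
  for (i in 1:3) {
    expect_equal(back[[i]]$yield, traces[[i]]$yield, tolerance = 1e-6)
    expect_identical(back[[i]]$events$kind, traces[[i]]$events$kind)
    expect_equal(back[[i]]$ops$lai, traces[[i]]$ops$lai, tolerance = 1e-6)
    expect_equal(back[[i]]$ops$biomass, traces[[i]]$ops$biomass, tolerance = 1e-4)
  }
})

test_that("sowing outside the plausible window is rejected", {
  expect_error(simulate_season(tiny_weather(), 1, 180), "window")
})
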