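test_that("an observation scores 0 inside its range (boundaries inclusive), 1 outside", {
  expect_equal(score_observation(3.0, 1.32, 4.17), 0L)
  expect_equal(score_observation(5.0, 1.32, 4.17), 1L)
  expect_equal(score_observation(4.17, 1.32, 4.17), 0L)
  expect_equal(score_observation(1.32, 1.32, 4.17), 0L)
  expect_equal(score_observation(c(0, 2, 9), 1.32, 4.17), c(1L, 0L, 1L))
  expect_error(score_observation(NA_real_, 0, 1), "finite")
})

test_that("the OP utility sum counts out-of-range parameters", {
  pool <- fake_pool(lower = 10, upper = 20,
                    params = paste0("p", 1:10))
  all_in <- stats::setNames(rep(15, 10), paste0("p", 1:10))
  expect_equal(score_op(all_in, 3, pool), 0L)
  three_out <- all_in
  three_out[c("p2", "p5", "p9")] <- c(9, 21, 100)
  expect_equal(score_op(three_out, 3, pool), 3L)
  # random vectors vs an independent per-parameter loop
  set.seed(11)
  for (i in 1:100) {
    v <- stats::runif(10, 0, 30)
    obs <- stats::setNames(v, paste0("p", 1:10))
    oracle <- sum(v < 10 | v > 20)
    expect_equal(score_op(obs, sample(1:7, 1), pool), oracle)
  }
  expect_error(score_op(c(unknown = 1), 1, pool), "no acceptance range")
})

test_that("OP0 scores 1 only below a 0.5 success frequency", {
  pool <- fake_pool(0, 1, op0 = c(`290` = 0.7, `300` = 0.3, `310` = 0.5))
  expect_equal(score_op0(290, pool), 0L)
  expect_equal(score_op0(300, pool), 1L)
  expect_equal(score_op0(310, pool), 0L)  # exactly 0.5: strict "less than"
  expect_warning(s <- score_op0(999, pool), "not in pool")
  expect_equal(s, 1L)
})

test_that("season totals satisfy the summation identity at both extremes", {
  params <- c("lai", paste0("sw_", c(30, 60, 90, 120)),
              paste0("st_", c(5, 10, 50)), "biomass", "bbch")
  pool <- fake_pool(10, 20, params = params,
                    op0 = c(`290` = 0.8, `320` = 0.2))
  good <- fake_trace(as.list(stats::setNames(rep(15, 10), params)), params,
                     sowing_doy = 290)
  r <- score_season(good, pool)
  expect_equal(r$total, 0L)
  expect_equal(r$max_possible, 71L)
  bad <- fake_trace(as.list(stats::setNames(rep(99, 10), params)), params,
                    sowing_doy = 320)
  rb <- score_season(bad, pool)
  expect_equal(rb$total, 71L)
  expect_equal(rb$total, rb$op0 + sum(rb$alpha))
})

test_that("a constructed season with known violations scores exactly its count", {
  params <- c("a", "b", "c")
  pool <- fake_pool(0, 10, params = params, op0 = c(`290` = 0.9))
  ops <- data.frame(op = 1:7, a = 5, b = 5, c = 5)
  ops[ops$op == 2, c("a", "b")] <- c(-1, 99)  # 2 violations at OP2
  ops[ops$op == 5, "c"] <- 11                 # 1 violation at OP5
  tr <- structure(list(sowing_year = 1, sowing_doy = 290L, ops = ops,
                       yield = 75, failed = FALSE), class = "growth_trace")
  r <- score_season(tr, pool)
  expect_equal(unname(r$alpha), c(0L, 2L, 0L, 0L, 1L, 0L, 0L))
  expect_equal(r$total, 3L)
})

test_that("unreached OPs in a failed season score their full parameter count", {
  params <- c("a", "b")
  pool <- fake_pool(0, 10, params = params, op0 = c(`290` = 0.9))
  ops <- data.frame(op = 1:7, a = c(5, 5, 5, NA, NA, NA, NA),
                    b = c(5, 5, 5, NA, NA, NA, NA))
  tr <- structure(list(sowing_year = 1, sowing_doy = 290L, ops = ops,
                       yield = 0, failed = TRUE), class = "growth_trace")
  r <- score_season(tr, pool)
  expect_equal(unname(r$alpha), c(0L, 0L, 0L, 2L, 2L, 2L, 2L))
  expect_equal(r$total, 8L)
})

test_that("scoring is monotone in range width and never mutates its inputs", {
  set.seed(23)
  params <- paste0("p", 1:5)
  for (i in 1:50) {
    lo <- stats::runif(1, 0, 5); hi <- lo + stats::runif(1, 0.5, 5)
    pool <- fake_pool(lo, hi, params = params, op0 = c(`290` = 0.4))
    vals <- as.list(stats::setNames(stats::runif(5, -2, 12), params))
    tr <- fake_trace(vals, params, sowing_doy = 290)
    before <- tr
    r1 <- score_season(tr, pool)
    expect_identical(tr, before)  # scoring is observation-only
    wider <- pool
    eps <- stats::runif(1, 0, 3)
    wider$ranges$lower <- wider$ranges$lower - eps
    wider$ranges$upper <- wider$ranges$upper + eps
    r2 <- score_season(tr, wider)
    expect_lte(r2$total, r1$total)
    expect_true(all(r2$alpha <= r1$alpha))
  }
})

test_that("score tables round-trip through the scores CSV", {
  pool <- tiny_pool()
  scores <- score_seasons(tiny_traces()[1:4], pool)
  expect_identical(names(scores)[1:3], c("year", "sowing_doy", "op0"))
  expect_true(all(scores$total == scores$op0 + rowSums(scores[paste0("alpha_", 1:7)])))
  path <- withr::local_tempfile(fileext = ".csv")
  write_scores(scores, path)
  back <- read_scores(path)
  expect_equal(back$total, scores$total)
  expect_equal(back$yield, scores$yield, tolerance = 1e-6)
})
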