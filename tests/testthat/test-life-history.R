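# Degree-day phenology, adult life spans, oviposition rhythm.

test_that("daily thermal energy is the positive part of T - T_T", {
  expect_equal(daily_energy(30, 11.2), 18.8)
  expect_equal(daily_energy(11.2, 11.2), 0)
  expect_equal(daily_energy(10, 13.6), 0)
  expect_equal(daily_energy(30, c(11.2, 7.3, 10.6)), c(18.8, 22.7, 19.4))
})

# independent oracle: day-by-day accumulation loop with the nearest-day
# molt rule (a stage completes once its accumulated energy reaches
# K - E/2, i.e. a final day more than half filled counts as complete)
accumulate_days <- function(K, T_T, temp) {
  E <- max(0, temp - T_T)
  acc <- 0
  n <- 0
  while (acc < K - E / 2) {
    acc <- acc + E
    n <- n + 1
    if (n > 10000) stop("no development")
  }
  max(n, 1)
}

test_that("stage durations equal the accumulation loop at 30 degrees", {
  stages <- list(
    egg      = c(K = 67.47,  T_T = 11.2),
    larva    = c(K = 516.96, T_T = 7.3),
    pupa     = c(K = 126.08, T_T = 10.6),
    immature = c(K = 130.98, T_T = 13.6)
  )
  for (nm in names(stages)) {
    st <- stages[[nm]]
    expect_identical(stage_duration(st["K"], st["T_T"], 30),
                     as.integer(accumulate_days(st["K"], st["T_T"], 30)),
                     label = nm)
  }
  # frozen values from the oracle: egg 4, larva 23, pupa 6, immature 8
  expect_identical(stage_duration(67.47, 11.2, 30), 4L)
  expect_identical(stage_duration(516.96, 7.3, 30), 23L)
  expect_identical(stage_duration(126.08, 10.6, 30), 6L)
  expect_identical(stage_duration(130.98, 13.6, 30), 8L)
})

test_that("stage_duration signals non-development at or below threshold", {
  expect_error(stage_duration(67.47, 11.2, 11.2), "no development")
  expect_error(stage_duration(67.47, 11.2, 5), "no development")
})

test_that("life spans are Normal, rounded, floored at one day", {
  set.seed(1)
  expect_identical(sample_longevity(3, 8.60, 0), rep(9L, 3))
  draws <- sample_longevity(1e4, 1.0, 5.0)
  expect_true(all(draws >= 1L))
  draws <- sample_longevity(1e5, 8.9, 0.7)
  expect_lt(abs(mean(draws) - 8.9), 0.05)
})

test_that("daily egg schedule declines and telescopes to the lifetime total", {
  expect_equal(eggs_on_day(0:10, 0, 0.5), rep(0, 11))
  expect_equal(eggs_on_day(0, 84, 0.3), 21.77, tolerance = 1e-3)
  expect_equal(sum(eggs_on_day(0:2000, 84, 0.3)), 84, tolerance = 1e-9)
  expect_equal(sum(eggs_on_day(0:2000, 57, 0.33)), 57, tolerance = 1e-9)
  o <- eggs_on_day(0:60, 182.6, 0.33)
  expect_true(all(diff(o) < 0))
  # a female with adult laying span L realizes fecundity * (1 - e^(-rhythm L))
  L <- 6
  expect_equal(sum(eggs_on_day(0:(L - 1), 100, 0.4)),
               100 * (1 - exp(-0.4 * L)))
})
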