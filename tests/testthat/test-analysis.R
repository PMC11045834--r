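# Replicate summaries, ratio series, fold reductions, scenario matrix.

test_that("replicate summaries: mean and Normal confidence band", {
  x <- fake_scenario(cbind(c(0, 2, 4), c(0, 2, 4)))
  s <- summarize_replicates(x)
  expect_equal(s$mean, c(0, 2, 4))
  expect_equal(s$lower, s$mean)          # identical replicates: width 0
  expect_equal(s$upper, s$mean)
  x <- fake_scenario(cbind(0, 2))
  expect_equal(summarize_replicates(x)$mean, 1)
  # single replicate: zero-width band by convention
  s1 <- summarize_replicates(fake_scenario(cbind(c(1, 5))))
  expect_equal(s1$lower, s1$mean)
})

test_that("the confidence band attains nominal coverage", {
  set.seed(31)
  hits <- 0L
  for (b in 1:1000) {
    x <- fake_scenario(matrix(rnorm(20, 100, 10), nrow = 1))
    s <- summarize_replicates(x)
    if (s$lower <= 100 && 100 <= s$upper) hits <- hits + 1L
  }
  expect_gt(hits / 1000, 0.92)
  expect_lt(hits / 1000, 0.98)
})

test_that("bootstrap band brackets the mean", {
  set.seed(8)
  x <- fake_scenario(matrix(rnorm(30, 50, 5), nrow = 1))
  s <- summarize_replicates(x, method = "boot", boot_n = 500)
  expect_true(s$lower <= s$mean && s$mean <= s$upper)
})

test_that("larval ratio series guards zero denominators", {
  a <- fake_scenario(cbind(c(0, 10, 20), c(0, 30, 40)))
  r <- ratio_n(a, a)
  expect_true(is.na(r$ratio[1]))         # 0/0 undefined, not a number
  expect_equal(r$ratio[-1], c(1, 1))     # self-ratio is 1 wherever defined
  zero <- fake_scenario(cbind(c(0, 0, 0), c(0, 0, 0)))
  expect_equal(ratio_n(zero, a)$ratio[-1], c(0, 0))
  expect_true(all(is.na(ratio_n(a, zero)$ratio)))
})

test_that("fold reduction is baseline over improved at the chosen day", {
  b <- fake_scenario(cbind(c(1, 300)))
  i <- fake_scenario(cbind(c(1, 100)))
  expect_equal(fold_reduction(b, b), 1)
  expect_equal(fold_reduction(b, i), 3)
  expect_equal(fold_reduction(fake_scenario(cbind(c(1, 3000))), i), 30)
  z <- fake_scenario(cbind(c(1, 0)))
  expect_warning(f <- fold_reduction(b, z), "infinite")
  expect_identical(f, Inf)
})

test_that("post-release slope flags decline versus growth", {
  days <- 0:40
  growing <- fake_scenario(cbind(exp(0.05 * days)), release_day = 10L)
  falling <- fake_scenario(cbind(100 * exp(-0.05 * days)), release_day = 10L)
  expect_gt(trichosim:::post_release_slope(growing), 0)
  expect_lt(trichosim:::post_release_slope(falling), 0)
})

test_that("the release-strategy matrix pairs scenarios by seed", {
  cfg <- scenario_config(grid = list(side_length = 24L), horizon = 45L,
                         replicates = 2L,
                         release = list(area_rule = "central-square",
                                        square_side_m = 6))
  mx <- run_release_matrix(cfg, base_seed = 21L)
  expect_identical(nrow(mx$table), 5L)
  expect_setequal(mx$table$label,
                  c("3x50k", "3x100k", "3x200k", "4x50k", "5x50k"))
  expect_equal(mx$table$fold_vs_standard[mx$table$label == "3x50k"], 1)
  # common random numbers: every scenario reuses the same replicate seeds
  seeds <- lapply(mx$results, `[[`, "seeds")
  expect_true(all(vapply(seeds, identical, logical(1), seeds[[1]])))
  expect_identical(mx$table$total_per_ha,
                   c(150000, 300000, 600000, 200000, 250000))
})
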