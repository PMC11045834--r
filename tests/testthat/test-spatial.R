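# Dispersal kernel, lattice displacement, host-directed search, immigration.

test_that("move distances follow the truncated exponential kernel", {
  expect_identical(sample_move_distance(5, 0.2, 0), rep(0, 5))
  set.seed(42)
  d <- sample_move_distance(1e5, 0.2, 50, round_to_cell = FALSE)
  expect_true(all(d >= 0 & d <= 50))
  # closed-form truncated mean, computed independently
  beta <- 0.2; dmax <- 50
  m <- 1 / beta - dmax * exp(-beta * dmax) / (1 - exp(-beta * dmax))
  expect_lt(abs(mean(d) - m) / m, 0.02)
  # distributional check against the closed-form CDF
  cdf <- function(x) (1 - exp(-beta * x)) / (1 - exp(-beta * dmax))
  ks <- suppressWarnings(ks.test(d, cdf))
  expect_gt(ks$p.value, 0.01)
  # rounding maps to whole cells
  set.seed(42)
  dr <- sample_move_distance(100, 0.2, 50)
  expect_identical(dr, round(dr))
})

test_that("displacement is polar arithmetic with clipping and contact log", {
  mv <- displace(7L, 3L, 0, 1.2, 10L)
  expect_identical(c(mv$x, mv$y), c(7L, 3L))
  expect_identical(mv$contacts, 0L)
  mv <- displace(500L, 500L, 3, 0, 1000L)
  expect_identical(c(mv$x, mv$y), c(503L, 500L))
  # corner move pointing off-grid: clipped, contact counted
  mv <- displace(0L, 0L, 10, pi, 10L)
  expect_identical(c(mv$x, mv$y), c(0L, 0L))
  expect_identical(mv$contacts, 1L)
})

test_that("parasitoid destination weights follow in-radius egg density", {
  side <- 21L
  eggs <- integer(side * side)
  at <- function(x, y) x + y * side + 1L
  # exactly one cell with eggs in radius: chosen with probability 1
  eggs[at(12L, 10L)] <- 4L
  set.seed(7)
  for (i in 1:25) {
    ch <- parasitoid_choose_cell(10L, 10L, eggs, side, 10, 0.2, 10)
    expect_true(ch$directed)
    expect_identical(c(ch$x, ch$y), c(12L, 10L))
  }
  # two cells with 30 and 10 eggs: 0.75 / 0.25 selection frequencies
  eggs[] <- 0L
  eggs[at(12L, 10L)] <- 30L
  eggs[at(8L, 10L)] <- 10L
  set.seed(7)
  picks <- replicate(1e4, {
    ch <- parasitoid_choose_cell(10L, 10L, eggs, side, 10, 0.2, 10)
    ch$x
  })
  expect_lt(abs(mean(picks == 12L) - 0.75), 0.02)
  expect_lt(abs(mean(picks == 8L) - 0.25), 0.02)
})

test_that("empty disk degrades exactly to undirected movement", {
  side <- 31L
  eggs <- integer(side * side)
  # eggs present but outside the 5-m radius: still undirected
  eggs[28L + 28L * side + 1L] <- 100L
  set.seed(11)
  ch <- parasitoid_choose_cell(15L, 15L, eggs, side, 5, 0.2, 5)
  expect_false(ch$directed)
  set.seed(11)
  d <- sample_move_distance(1, 0.2, 5, round_to_cell = FALSE)
  a <- runif(1) * 2 * pi
  mv <- displace(15L, 15L, d, a, side)
  expect_identical(c(ch$x, ch$y), c(mv$x, mv$y))
})

test_that("background infestation is one Bernoulli arrival per day", {
  set.seed(3)
  expect_identical(sample_immigration(100L, 0), 0L)
  # zero probability consumes no randomness
  s0 <- .Random.seed
  sample_immigration(100L, 0)
  expect_identical(s0, .Random.seed)
  expect_true(all(replicate(50, sample_immigration(100L, 1)) >= 1L))
  arrivals <- sum(replicate(1e4, sample_immigration(100L, 0.01)) > 0L)
  # Binomial(1e4, 0.01) oracle bounds at the 1e-4 tails
  expect_gte(arrivals, qbinom(1e-4, 1e4, 0.01))
  expect_lte(arrivals, qbinom(1 - 1e-4, 1e4, 0.01))
})
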