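# Parasitism, emergence from parasitized eggs, trigger latch, releases.

test_that("cell parasitism is Poisson-capped by the available eggs", {
  set.seed(5)
  expect_identical(parasitize_cell(0, 12.5), 0L)
  expect_identical(parasitize_cell(100, 0), 0L)
  # saturation: huge capacity always takes every egg
  expect_true(all(replicate(200, parasitize_cell(5, 100)) == 5L))
  draws <- replicate(500, parasitize_cell(8, 3))
  expect_true(all(draws <= 8L))
  expect_true(all(draws >= 0L))
})

test_that("parasitoid emergence: offspring count, sex ratio, life spans", {
  set.seed(9)
  em <- emerge_parasitoids(10, 2L, 0.89, 8.9, 0.7)
  expect_identical(em$count, 20L)
  expect_lte(em$females, 20L)
  expect_length(em$longevity, 20L)
  expect_true(all(em$longevity >= 1L))
  em0 <- emerge_parasitoids(0, 2L, 0.89, 8.9, 0.7)
  expect_identical(em0$count, 0L)
  expect_length(em0$longevity, 0L)
  # female fraction converges to the sex ratio
  tot <- 0
  fem <- 0
  for (i in 1:400) {
    em <- emerge_parasitoids(25, 2L, 0.89, 8.9, 0.7)
    tot <- tot + em$count
    fem <- fem + em$females
  }
  expect_lt(abs(fem / tot - 0.89), 0.01)
})

test_that("release trigger is inclusive at tau and latches", {
  expect_false(check_trigger(4, 5, FALSE))
  expect_true(check_trigger(5, 5, FALSE))
  expect_true(check_trigger(6, 5, FALSE))
  expect_true(check_trigger(0, 5, TRUE))   # latch persists after decline
  expect_identical(trichosim:::schedule_releases(36L, 3L, 7L),
                   c(36L, 43L, 50L))
  expect_identical(trichosim:::schedule_releases(10L, 0L, 7L), integer(0))
})

test_that("releases scale with area and spread uniformly over its cells", {
  set.seed(13)
  area <- 1:25                          # 25 one-metre cells
  expect_identical(apply_release(area, 0), integer(0))
  expect_error(apply_release(integer(0), 50000), "release area is empty")
  # one full hectare at the operational density
  rel <- apply_release(1:10000, 50000)
  expect_length(rel, 50000L)
  # occupancy uniform across area cells
  rel <- apply_release(area, 4e7)       # 25 m2 * 4e7/ha = 100,000 wasps
  expect_length(rel, 100000L)
  cnt <- tabulate(rel, 25)
  chi <- chisq.test(cnt)
  expect_gt(chi$p.value, 0.01)
})
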