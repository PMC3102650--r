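# the 3-cell instance from the contract: c0 = {s1, s2}, c1 = {s2}, c2 = {s3}
contract_instance <- function() {
  pa <- rbind(s1 = c(1L, 0L, 0L), s2 = c(1L, 1L, 0L), s3 = c(0L, 0L, 1L))
  colnames(pa) <- as.character(0:2)
  pa
}

light <- function() anneal_schedule(iterations = 5000, restarts = 2)

test_that("capped_targets caps the goal at occupancy", {
  pa <- tiny_pa() # occupancies 3, 1, 5, 2, 4, 2
  tg <- capped_targets(pa, goal = 3)
  expect_equal(tg$target, c(3L, 1L, 3L, 2L, 3L, 2L))
  expect_true(all(capped_targets(pa, 1)$target == 1L))
  expect_error(capped_targets(pa, 0), "positive")
})

test_that("min_cover_cost equals size when feasible, penalises shortfalls", {
  pa <- contract_instance()
  tg <- capped_targets(pa, 1)
  expect_equal(min_cover_cost(c(0L, 2L), pa, tg, spf = 10), 2)
  expect_equal(min_cover_cost(integer(0), pa, tg, spf = 10), 30)
  # hand computation: select c1 only -> s1 and s3 short by 1 each
  expect_equal(min_cover_cost(1L, pa, tg, spf = 7), 1 + 7 * 2)
  # goal-2 targets: s2 has occupancy 2 -> target 2; selecting c0 leaves
  # s2 short 1, s3 short 1 at spf 5 -> 1 + 5 * 2
  tg2 <- capped_targets(pa, 2)
  expect_equal(min_cover_cost(0L, pa, tg2, spf = 5), 11)
})

test_that("greedy_min_cover follows the largest-shortfall rule", {
  pa <- contract_instance()
  sol <- greedy_min_cover(pa, capped_targets(pa, 1))
  expect_setequal(sol$cells, c(0L, 2L))
  expect_true(sol$feasible)

  one_cell <- rbind(a = c(1L, 1L), b = c(1L, 0L), c = c(1L, 0L))
  colnames(one_cell) <- c("0", "1")
  sol2 <- greedy_min_cover(one_cell, capped_targets(one_cell, 1))
  expect_equal(sol2$cells, 0L)

  # targets equal to occupancy force every occupied cell of every species
  pa3 <- tiny_pa()
  tg3 <- capped_targets(pa3, 99)
  sol3 <- greedy_min_cover(pa3, tg3)
  expect_setequal(sol3$cells, 0:4)
})

test_that("brute_force is exact and refuses oversized instances", {
  pa <- contract_instance()
  bf <- brute_force(pa, capped_targets(pa, 1), "min_set")
  expect_equal(length(bf$cells), 2)
  expect_setequal(bf$cells, c(0L, 2L))

  expect_equal(brute_force(pa, capped_targets(pa, 1), "max_coverage",
                           budget = 0)$objective, 0L)

  one_cell <- rbind(a = c(1L, 0L), b = c(1L, 0L))
  colnames(one_cell) <- c("0", "1")
  expect_equal(brute_force(one_cell, capped_targets(one_cell, 1),
                           "min_set")$cells, 0L)

  big <- random_instance(3, 21)
  expect_error(brute_force(big, capped_targets(big, 1), "min_set"),
               "more than 20")
})

test_that("anneal solves the contract instances", {
  pa <- contract_instance()
  tg <- capped_targets(pa, 1)
  sol <- anneal(pa, tg, "min_set", schedule = light(), seed = 4)
  expect_equal(length(sol$cells), 2) # brute-force optimum
  expect_true(sol$feasible)

  sat <- anneal(pa, tg, "max_coverage", budget = 5, schedule = light(),
                seed = 4)
  expect_equal(sat$objective, 3L) # budget >= n_cells covers everything

  pa2 <- rbind(s1 = c(1L, 0L), s2 = c(1L, 0L), s3 = c(0L, 1L))
  colnames(pa2) <- c("0", "1")
  b1 <- anneal(pa2, capped_targets(pa2, 1), "max_coverage", budget = 1,
               schedule = light(), seed = 9)
  expect_equal(b1$cells, 0L) # c0 covers two species, c1 only one
  expect_equal(b1$objective, 2L)
})

test_that("anneal is deterministic in the seed", {
  set.seed(123)
  pa <- random_instance(8, 10)
  tg <- capped_targets(pa, 2)
  s1 <- anneal(pa, tg, "min_set", schedule = light(), seed = 42)
  s2 <- anneal(pa, tg, "min_set", schedule = light(), seed = 42)
  expect_identical(s1$cells, s2$cells)
  m1 <- anneal(pa, tg, "max_coverage", budget = 3, schedule = light(),
               seed = 42)
  m2 <- anneal(pa, tg, "max_coverage", budget = 3, schedule = light(),
               seed = 42)
  expect_identical(m1$cells, m2$cells)
})

test_that("oracle dominance holds: brute <= anneal <= greedy", {
  set.seed(5)
  for (rep in 1:15) {
    pa <- random_instance(sample(4:8, 1), sample(5:10, 1))
    tg <- capped_targets(pa, sample(1:3, 1))
    bf <- brute_force(pa, tg, "min_set")
    an <- anneal(pa, tg, "min_set", schedule = light(), seed = rep)
    gr <- greedy_min_cover(pa, tg)
    expect_lte(length(bf$cells), length(an$cells))
    expect_lte(length(an$cells), length(gr$cells))
    expect_true(an$feasible)
  }
})

test_that("max-coverage objective is non-decreasing in the budget", {
  set.seed(6)
  for (rep in 1:8) {
    pa <- random_instance(sample(5:9, 1), sample(8:12, 1))
    tg <- capped_targets(pa, 2)
    covs <- vapply(1:4, function(b) {
      anneal(pa, tg, "max_coverage", budget = b,
             schedule = anneal_schedule(iterations = 20000, restarts = 3),
             seed = rep)$objective
    }, integer(1))
    expect_true(all(diff(covs) >= 0))
  }
})

test_that("solution objects tidy into per-species and one-row summaries", {
  pa <- contract_instance()
  sol <- greedy_min_cover(pa, capped_targets(pa, 1))
  td <- tidy(sol)
  expect_equal(td$species_id, rownames(pa))
  expect_equal(td$representation[td$species_id == "s2"], 1L)
  gl <- glance(sol)
  expect_equal(gl$n_cells, 2L)
  expect_true(gl$feasible)
})
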