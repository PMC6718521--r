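test_that("pattern constructor enforces the constraints", {
  p <- ingestion_pattern(c(50, rep(0, 12)))
  expect_s3_class(p, "ogtt_pattern")
  expect_equal(sum(p), 50)
  expect_error(ingestion_pattern(c(0, 50, rep(0, 11))), "first slot")
  expect_error(ingestion_pattern(c(1.5, rep(0, 12))), "integer")
  expect_error(ingestion_pattern(c(2, -1, rep(0, 11))), "integer|nonneg")
})

test_that("patterns convert to schedules with the 0.5-min convention", {
  bolus <- ingestion_pattern(c(50, rep(0, 12)))
  sched <- pattern_to_schedule(bolus)
  expect_equal(nrow(sched), 1)
  expect_equal(ingestion_flux(sched, 0.25), 100)

  split <- ingestion_pattern(c(1, rep(0, 11), 49))
  s2 <- pattern_to_schedule(split)
  expect_equal(s2$start, c(0, 60))
  expect_equal(total_grams(s2), 50)
  expect_equal(ingestion_flux(s2, 60.4), 98)
})

test_that("mutation preserves total grams and the first-slot floor", {
  withr::with_seed(10, {
    for (rep in 1:200) {
      u <- init_population(3, 50, 13)[3, ]
      L <- sample(0:20, 1)
      v <- mutate_pattern(u, L)
      expect_equal(sum(v), 50)
      expect_gte(v[1], 1)
      expect_true(all(v >= 0))
    }
  })
})

test_that("mutation with zero transfers is the identity", {
  u <- c(5L, 3L, 2L)
  expect_identical(mutate_pattern(u, 0), u)
})

test_that("the strict source rule never empties a donor slot below 1", {
  withr::with_seed(4, {
    u <- c(1L, 1L, 1L, 47L)
    for (rep in 1:50) {
      v <- mutate_pattern(u, 10, source_rule = "more_than_1")
      expect_equal(sum(v), 50)
      expect_gte(v[1], 1)
    }
  })
})

test_that("initial population contains the two anchor patterns", {
  withr::with_seed(2, {
    U <- init_population(30, 50, 13)
    expect_equal(U[1, ], c(50L, rep(0L, 12)))
    expect_equal(U[2, ], c(1L, rep(0L, 11), 49L))
    expect_true(all(rowSums(U) == 50))
    expect_true(all(U[, 1] >= 1))
  })
  u1 <- withr::with_seed(7, init_population(20, 50, 13))
  u2 <- withr::with_seed(7, init_population(20, 50, 13))
  expect_identical(u1, u2)
})

test_that("tournament scores count strictly worse opponents", {
  withr::with_seed(1, {
    J <- c(1, 2, 3, 4, 5, 6)
    sc <- tournament_scores(J, 50)
    expect_equal(sc[1], 50L)          # unique minimum beats everyone
    expect_true(all(sc >= 0 & sc <= 50))
    expect_true(all(tournament_scores(rep(3, 10), 20) == 0L))
    # a middling individual wins about half its encounters
    many <- replicate(200, tournament_scores(c(1, 2, 3), 10)[2])
    expect_equal(mean(many) / 10, 0.5, tolerance = 0.15)
  })
})

test_that("pattern enumeration matches stars-and-bars counting", {
  expect_equal(enumerate_patterns(2, 2),
               rbind(c(1L, 1L), c(2L, 0L)),
               ignore_attr = TRUE)
  for (total in c(3, 5, 8)) {
    for (slots in c(2, 3, 4)) {
      pats <- enumerate_patterns(total, slots)
      expect_equal(nrow(pats), choose(total - 1 + slots - 1, slots - 1))
      expect_equal(nrow(pats), pattern_count(total, slots))
      expect_true(all(rowSums(pats) == total))
      expect_true(all(pats[, 1] >= 1))
      expect_equal(nrow(unique(pats)), nrow(pats))
    }
  }
  expect_error(enumerate_patterns(50, 13), "too large")
})

test_that("exact binomial arithmetic reproduces known values", {
  expect_identical(exact_choose(5, 2), 10)
  expect_identical(exact_choose(10, 0), 1)
  expect_equal(exact_choose(62, 13), choose(62, 13))
  expect_equal(pattern_count(50, 13), choose(61, 12))
})

test_that("objective evaluation is representation-invariant", {
  subj <- fixture_subject("A")
  pat <- ingestion_pattern(c(20, rep(0, 11), 30))
  j1 <- evaluate_objective(pat, subj, "glucose_peak", step = 0.01,
                           horizon = 240)
  sched <- pattern_to_schedule(pat)
  tr <- simulate_subject(subj, sched, quick_solver(step = 0.01,
                                                   horizon = 240))
  expect_equal(j1, peak_value(tr, "G"), tolerance = 1e-9)
})

test_that("optimizer traces are non-increasing and seeded runs repeat", {
  subj <- fixture_subject("A")
  st <- pattern_settings(pop = 20, generations = 10, trials = 1,
                         search_step = 0.05, final_step = 0.05,
                         horizon = 240, seed = 3)
  o1 <- optimize_pattern(subj, "glucose_peak", st, total = 10,
                         slots = c(0, 30, 60))
  o2 <- optimize_pattern(subj, "glucose_peak", st, total = 10,
                         slots = c(0, 30, 60))
  expect_identical(as.integer(o1$best_pattern),
                   as.integer(o2$best_pattern))
  expect_identical(o1$trace$best_J, o2$trace$best_J)
  expect_true(all(diff(o1$trace$best_J) <= 0))
  expect_equal(sum(o1$best_pattern), 10)
  expect_gte(o1$best_pattern[1], 1)
})

test_that("the transfer-count schedule decreases as configured", {
  st <- pattern_settings(L_init = 20, L_decrement = 1, L_interval = 25)
  expect_equal(ogttdesign:::transfer_count(1, st), 20)
  expect_equal(ogttdesign:::transfer_count(25, st), 20)
  expect_equal(ogttdesign:::transfer_count(26, st), 19)
  expect_equal(ogttdesign:::transfer_count(501, st), 0)
})
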