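test_that("zero-ingestion trajectories stay at the closed steady state", {
  empty <- ingestion_schedule(numeric(0), numeric(0))
  for (seed in c(2, 11)) {
    subj <- random_subject(seed = seed)
    tr <- simulate_subject(subj, empty, quick_solver(step = 0.01,
                                                     horizon = 480))
    m <- as.matrix(tr[, -1])
    rel <- abs(sweep(m, 2, m[1, ])) / pmax(abs(m[1, ]), 1e-12)[col(m)]
    expect_lt(max(rel), 1e-6)
  }
})

test_that("euler and adaptive integrators agree on a bolus response", {
  subj <- fixture_subject("B")
  times <- seq(0, 240, by = 5)
  tr_e <- simulate_subject(subj, bolus_schedule(50),
                           quick_solver(step = 0.005), times = times)
  tr_a <- simulate_subject(subj, bolus_schedule(50),
                           solver_settings("adaptive", horizon = 240),
                           times = times)
  for (sp in c("G", "I", "CP", "GIP", "GLP1")) {
    rng <- max(tr_a[[sp]]) - min(tr_a[[sp]])
    expect_lt(max(abs(tr_e[[sp]] - tr_a[[sp]])) / rng, 5e-3)
  }
})

test_that("halving the Euler step barely moves the peak", {
  subj <- fixture_subject("A")
  p1 <- peak_value(simulate_subject(subj, bolus_schedule(50),
                                    quick_solver(step = 0.02)), "G")
  p2 <- peak_value(simulate_subject(subj, bolus_schedule(50),
                                    quick_solver(step = 0.01)), "G")
  expect_lt(abs(p1 - p2) / p2, 1e-3)
})

test_that("fixed-step simulation is deterministic", {
  subj <- fixture_subject("C")
  t1 <- simulate_subject(subj, bolus_schedule(25), quick_solver())
  t2 <- simulate_subject(subj, bolus_schedule(25), quick_solver())
  expect_identical(as.matrix(t1), as.matrix(t2))
})

test_that("absorbed glucose is bounded by and approaches the dose", {
  subj <- fixture_subject("B")
  k6 <- subj$kinetics[["k6"]]
  L6 <- subj$kinetics[["L6"]]
  for (horizon in c(240, 480)) {
    tr <- simulate_subject(subj, bolus_schedule(50),
                           quick_solver(step = 0.01, horizon = horizon))
    v6 <- k6 * tr$Intest_G / (L6 + tr$Intest_G)
    dt <- diff(tr$time)
    absorbed <- sum((v6[-1] + v6[-length(v6)]) / 2 * dt)
    expect_lte(absorbed, 50 * (1 + 1e-6))
    if (horizon == 480) expect_gt(absorbed, 49.5)
  }
})

test_that("states remain nonnegative along physiological trajectories", {
  for (id in c("A", "B", "C")) {
    tr <- simulate_subject(fixture_subject(id), bolus_schedule(75),
                           quick_solver(step = 0.01, horizon = 480))
    expect_gte(min(as.matrix(tr[, -1])), 0)
  }
})

test_that("sample_at interpolates linearly and errors out of range", {
  subj <- fixture_subject("A")
  tr <- simulate_subject(subj, bolus_schedule(50), quick_solver(),
                         times = seq(0, 240, by = 10))
  expect_equal(sample_at(tr, c(0, 50, 240), "G"),
               tr$G[match(c(0, 50, 240), tr$time)])
  mid <- sample_at(tr, 15, "G")
  expect_equal(mid, (tr$G[tr$time == 10] + tr$G[tr$time == 20]) / 2)
  expect_error(sample_at(tr, 250, "G"), "outside")
  expect_error(sample_at(tr, 100, "XYZ"), "unknown species")
  tab <- sample_at(tr, c(0, 30), c("G", "I"))
  expect_named(tab, c("time", "G", "I"))
})

test_that("peak_value matches a brute-force denser re-integration", {
  subj <- fixture_subject("C")
  tr <- simulate_subject(subj, bolus_schedule(50),
                         quick_solver(step = 0.05))
  tr_dense <- simulate_subject(subj, bolus_schedule(50),
                               quick_solver(step = 0.005))
  expect_equal(peak_value(tr, "G"), max(tr$G))
  expect_lt(abs(peak_value(tr, "G") - peak_value(tr_dense, "G")) /
              peak_value(tr_dense, "G"), 1e-3)
  expect_error(peak_value(tr, "CP"))
})

test_that("misaligned Euler steps against event boundaries are refused", {
  subj <- fixture_subject("A")
  sched <- ingestion_schedule(0.31, 10, 0.5)
  expect_error(simulate_subject(subj, sched, quick_solver(step = 0.05)),
               "divide")
})

test_that("trajectory CSV export is faithful", {
  subj <- fixture_subject("A")
  tr <- simulate_subject(subj, bolus_schedule(50), quick_solver(),
                         times = seq(0, 240, by = 30))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(tr, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(back$time_min, tr$time)
  expect_equal(back$G, tr$G)
})
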