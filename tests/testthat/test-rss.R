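test_that("RSS is zero when simulation equals the data", {
  subj <- fixture_subject("A")
  ds <- generate_dataset(subj, noise = 0, seed = 1)
  val <- rss(ds, subj, quick_solver())
  expect_equal(val, 0, tolerance = 1e-20)
})

test_that("RSS matches an independently coded min-max-normalized sum", {
  subj <- fixture_subject("B")
  truth <- fixture_subject("C")   # deliberate model-data mismatch
  ds <- generate_dataset(truth, noise = 0.05, seed = 9)
  st <- quick_solver()
  # oracle: recompute from scratch with base R
  oracle <- 0
  for (cond in unique(ds$condition)) {
    traj <- simulate_subject(subj, condition_schedule(cond), st,
                             times = sort(unique(
                               ds$time_min[ds$condition == cond])))
    for (sp in unique(ds$species[ds$condition == cond])) {
      d <- ds[ds$condition == cond & ds$species == sp, ]
      sim <- stats::approx(traj$time, traj[[sp]], xout = d$time_min)$y
      oracle <- oracle +
        sum(((sim - d$value) / (max(d$value) - min(d$value)))^2)
    }
  }
  expect_equal(rss(ds, subj, st), oracle, tolerance = 1e-10)
})

test_that("RSS is invariant to jointly rescaling a species", {
  # scaling exp and sim jointly cancels through the range normalization:
  # verified directly on the formula via rss_terms arithmetic
  subj <- fixture_subject("A")
  ds <- generate_dataset(subj, noise = 0.1, seed = 2)
  terms <- rss_terms(ds, subj, quick_solver())
  ds2 <- ds
  scale10 <- ds2$species == "GIP"
  ds2$value[scale10] <- ds2$value[scale10] * 10
  # simulate a matched rescaled world by scaling the subject is not
  # possible; instead check the formula property: contribution depends on
  # residual/range only
  d <- ds[ds$condition == "50B" & ds$species == "G", ]
  sim <- sample_at(simulate_subject(subj, condition_schedule("50B"),
                                    quick_solver(), times = d$time_min),
                   d$time_min, "G")
  c1 <- sum(((sim - d$value) / (max(d$value) - min(d$value)))^2)
  c2 <- sum(((10 * sim - 10 * d$value) /
               (max(10 * d$value) - min(10 * d$value)))^2)
  expect_equal(c1, c2)
  expect_equal(terms$contribution[terms$condition == "50B" &
                                    terms$species == "G"], c1)
})

test_that("excluded conditions contribute nothing", {
  subj <- fixture_subject("A")
  ds <- generate_dataset(subj, noise = 0.05, seed = 4)
  full <- rss_terms(ds, subj, quick_solver())
  ds_excl <- ds
  ds_excl$included[ds_excl$condition == "75C"] <- FALSE
  part <- rss_terms(ds_excl, subj, quick_solver())
  expect_false("75C" %in% part$condition)
  expect_equal(sum(part$contribution),
               sum(full$contribution[full$condition != "75C"]))
})

test_that("degenerate flat series are rejected by name", {
  subj <- fixture_subject("A")
  ds <- generate_dataset(subj, noise = 0, seed = 1)
  ds$value[ds$condition == "25B" & ds$species == "GIP"] <- 7
  expect_error(rss(ds, subj, quick_solver()), "25B/GIP")
})

test_that("compiled batch RSS agrees with the reference path", {
  subj <- fixture_subject("B")
  ds <- generate_dataset(fixture_subject("C"), noise = 0.05, seed = 6)
  ref <- rss(ds, subj, quick_solver(step = 0.05))
  rd <- ogttdesign:::make_rss_data(ds, subj$structure)
  X <- matrix(c(subj$kinetics, subj$init), nrow = 1,
              dimnames = list(NULL, c(names(subj$kinetics),
                                      names(subj$init))))
  fast <- ogttdesign:::rss_fast(X, subj$structure, rd, step = 0.05)
  expect_equal(fast, ref, tolerance = 1e-8)
  # and against the adaptive integrator within discretization error
  ref_ad <- rss(ds, subj, solver_settings("adaptive"))
  expect_equal(fast, ref_ad, tolerance = 5e-3)
})

test_that("fitting data are invariant to row order", {
  subj <- fixture_subject("A")
  ds <- generate_dataset(subj, noise = 0.05, seed = 8)
  shuffled <- ds[withr::with_seed(1, sample(nrow(ds))), ]
  expect_equal(rss(shuffled, subj, quick_solver()),
               rss(ds, subj, quick_solver()))
})
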