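test_that("EP approaches the analytic minimum of a quadratic", {
  fn <- function(X) (X[, 1] - 3)^2
  res <- ep_minimize(fn, c(p = 0.01), c(p = 100), pop = 40,
                     generations = 50, seed = 1)
  expect_lt(abs(res$par[["p"]] - 3) / 3, 0.01)
  # best-so-far trace is non-increasing by elitist bookkeeping
  expect_true(all(diff(res$trace) <= 0))
})

test_that("EP is deterministic given a seed", {
  fn <- function(X) rowSums((X - 2)^2)
  lo <- c(a = 0.1, b = 0.1)
  hi <- c(a = 50, b = 50)
  r1 <- ep_minimize(fn, lo, hi, pop = 20, generations = 20, seed = 9)
  r2 <- ep_minimize(fn, lo, hi, pop = 20, generations = 20, seed = 9)
  expect_identical(r1$trace, r2$trace)
  expect_identical(r1$par, r2$par)
  r3 <- ep_minimize(fn, lo, hi, pop = 20, generations = 20, seed = 10)
  expect_false(identical(r1$trace, r3$trace))
})

test_that("EP respects its box constraints", {
  fn <- function(X) -rowSums(X)   # pushes toward the upper bound
  res <- ep_minimize(fn, c(x = 1), c(x = 10), pop = 15, generations = 30,
                     seed = 2)
  expect_true(all(res$population >= 1 - 1e-9 & res$population <= 10 + 1e-9))
})

test_that("default bounds anchor initial levels to fasting data", {
  subj <- fixture_subject("A")
  ds <- generate_dataset(subj, noise = 0, seed = 1)
  b <- default_fit_bounds(subj$structure, ds)
  expect_setequal(colnames(b),
                  c(kinetic_names(subj$structure),
                    initial_names(subj$structure)))
  g0 <- subj$init[["G0"]]
  expect_equal(b["lower", "G0"], 0.1 * g0, tolerance = 1e-6)
  expect_equal(b["upper", "G0"], 10 * g0, tolerance = 1e-6)
  expect_equal(unname(b[, "k2"]), c(1e-3, 1e3))
  expect_true(all(b["upper", ] > b["lower", ]))
})

test_that("refinement never worsens the objective", {
  subj <- fixture_subject("A")
  ds <- generate_dataset(subj, noise = 0.05, seed = 3)
  set <- quick_fit_settings(seed = 4)
  truth_par <- c(subj$kinetics, subj$init)
  # start from a perturbed truth: both refiners must descend
  start <- truth_par * exp(withr::with_seed(5,
    stats::rnorm(length(truth_par), 0, 0.2)))
  start_rss <- ogttdesign:::rss_fast(
    matrix(start, nrow = 1, dimnames = list(NULL, names(start))),
    subj$structure, ogttdesign:::make_rss_data(ds, subj$structure),
    step = set$step)
  ref_nm <- simplex_refine(start, ds, subj$structure, set)
  expect_lte(ref_nm$value, start_rss + 1e-9)
  ref_lm <- lm_refine(start, ds, subj$structure, set)
  expect_lte(ref_lm$value, start_rss + 1e-9)
  # at 5% noise the RSS floor is ~ n_obs * 0.05^2 ~ 0.7; LM from a
  # perturbed truth must get close to it
  expect_lt(ref_lm$value, 1.5)
  # restarting the simplex at a (near-)minimum stays put
  again <- simplex_refine(ref_lm$par, ds, subj$structure, set)
  expect_lte(again$value, ref_lm$value + 1e-6)
})

test_that("fit_subject bookkeeping is consistent", {
  subj <- fixture_subject("A")
  ds <- generate_dataset(subj, noise = 0.05, seed = 6)
  f <- fit_subject(ds, subj$structure,
                   quick_fit_settings(seed = 7, trials = 2))
  expect_s3_class(f, "ogtt_fit")
  expect_equal(nrow(f$trials), 2)
  expect_equal(f$best_rss, min(f$trials$rss))
  expect_equal(f$n_obs, sum(ds$included) / 1L)
  expect_true(all(purrr::map_lgl(f$traces, ~ all(diff(.x) <= 0))))
  td <- tidy(f)
  expect_setequal(td$term[td$type == "kinetic"],
                  kinetic_names(subj$structure))
  gl <- glance(f)
  expect_equal(gl$k, n_free_parameters(subj$structure))
  expect_equal(gl$aic, aic_score(f$best_rss, f$n_obs, gl$k))
})

test_that("fits are reproducible given a seed", {
  subj <- fixture_subject("A")
  ds <- generate_dataset(subj, noise = 0.05, seed = 8)
  f1 <- fit_subject(ds, subj$structure, quick_fit_settings(seed = 20))
  f2 <- fit_subject(ds, subj$structure, quick_fit_settings(seed = 20))
  expect_identical(f1$best_rss, f2$best_rss)
  expect_identical(f1$subject$kinetics, f2$subject$kinetics)
})
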