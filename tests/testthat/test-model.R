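test_that("ingestion flux follows the dose/duration convention", {
  bolus <- bolus_schedule(50)
  expect_identical(ingestion_flux(bolus, 0.25), 100)
  expect_identical(ingestion_flux(bolus, 0), 100)
  expect_identical(ingestion_flux(bolus, 0.5), 0)  # half-open window
  expect_identical(ingestion_flux(bolus, 10), 0)

  cont <- continuous_schedule(75, 120)
  expect_equal(ingestion_flux(cont, 60), 0.625)
  expect_identical(ingestion_flux(cont, 121), 0)

  multi <- ingestion_schedule(c(0, 60), c(1, 49), 0.5)
  expect_equal(ingestion_flux(multi, c(0.1, 30, 60.2, 61)),
               c(2, 0, 98, 0))
  expect_equal(total_grams(multi), 50)
})

test_that("flux integral over time recovers the total dose", {
  sched <- ingestion_schedule(c(0, 20, 45), c(5, 10, 35), c(0.5, 10, 2))
  tt <- seq(0, 60, by = 0.005)
  integral <- sum(ingestion_flux(sched, tt)) * 0.005
  expect_equal(integral, total_grams(sched), tolerance = 1e-2)
})

test_that("schedule validation rejects bad events", {
  expect_error(ingestion_schedule(0, -5, 0.5), "positive")
  expect_error(ingestion_schedule(0, 5, 0), "positive")
  expect_error(ingestion_schedule(c(0, 0.3), c(5, 5), 0.5), "overlap")
  # touching windows are fine
  expect_s3_class(ingestion_schedule(c(0, 0.5), c(5, 5), 0.5),
                  "ogtt_schedule")
})

test_that("closure reproduces the stated formulas", {
  s <- model_structure(a = FALSE, b = FALSE, c = FALSE, d = FALSE)
  kin <- c(k2 = 1, k3 = 1, k4 = 1, k5 = 1, k6 = 1, k7 = 1, k8 = 1,
           k10 = 1, L2 = 1, L4 = 1, L6 = 1, L8 = 3, L11 = 1, V = 1)
  ini <- c(GIP0 = 1, GLP10 = 1, G0 = 2, I0 = 1, CP0 = 1, X0 = 1)
  drv <- close_parameters(kin, ini, s)
  expect_equal(drv[["k9"]], 0.125)             # 1 / (2 * 1 * (1 + 3))
  expect_equal(drv[["GIP_B"]], ini[["GIP0"]])
  expect_equal(drv[["GLP1_B"]], ini[["GLP10"]])
  expect_equal(drv[["k13"]], 1 / ((1 + 1) * 1))

  # with free coefficients the secretion drive enters k11 and k12
  s2 <- model_structure()
  kin2 <- c(kin, a = 1, b = 0.5, c = 2, d = 0.25)
  drv2 <- close_parameters(kin2, ini, s2)
  S0 <- 2 + 1 * 1 + 0.5 * 2 * 1 + 2 * 1 + 0.25 * 2 * 1
  expect_equal(drv2[["k11"]], 1 * (1 + 1) / 1 * S0)
  expect_equal(drv2[["k12"]], 1 / 1 * S0)
})

test_that("closure rejects nonpositive levels that enter denominators", {
  s <- model_structure(a = FALSE, b = FALSE, c = FALSE, d = FALSE)
  kin <- c(k2 = 1, k3 = 1, k4 = 1, k5 = 1, k6 = 1, k7 = 1, k8 = 1,
           k10 = 1, L2 = 1, L4 = 1, L6 = 1, L8 = 3, L11 = 1, V = 1)
  ini <- c(GIP0 = 1, GLP10 = 1, G0 = 2, I0 = 1, CP0 = 1, X0 = 1)
  for (nm in c("G0", "X0", "I0", "CP0")) {
    bad <- ini
    bad[nm] <- 0
    expect_error(close_parameters(kin, bad, s), nm)
  }
  expect_error(close_parameters(replace(kin, "k8", -1), ini, s),
               "positive")
})

test_that("the closed steady state zeroes the right-hand side", {
  for (seed in 1:25) {
    subj <- random_subject(seed = seed)
    y0 <- setNames(ogttdesign:::initial_state_vector(subj),
                   state_names(subj$structure))
    dy <- model_rhs(y0, subj, glucose_flux = 0)
    scale <- pmax(abs(y0), 1)
    expect_lt(max(abs(dy) / scale), 1e-12)
  }
})

test_that("flux laws behave as stated", {
  subj <- random_subject(seed = 99)
  y <- setNames(ogttdesign:::initial_state_vector(subj),
                state_names(subj$structure))
  y["Intest_G"] <- 5
  y["A_GutG"] <- 3

  v <- flux_vector(y, subj, glucose_flux = 2)
  expect_equal(v[["v1"]], 2)
  # v9 is bilinear in G and X
  y2 <- y
  y2["G"] <- 2 * y[["G"]]
  y2["X"] <- 2 * y[["X"]]
  expect_equal(flux_vector(y2, subj)[["v9"]], 4 * v[["v9"]])
  # v2 saturates at k2
  ybig <- y
  ybig["Intest_G"] <- 1e9
  expect_equal(flux_vector(ybig, subj)[["v2"]], subj$kinetics[["k2"]],
               tolerance = 1e-6)
  # the Michaelis-Menten and mass-action fluxes are nonnegative at
  # nonnegative states; v3/v5 relax with the correct sign
  nonneg <- c("v1", "v2", "v4", "v6", "v7", "v8", "v9", "v10", "v11",
              "v12", "v13")
  expect_true(all(v[nonneg] >= 0))
  yhi <- y
  yhi["GIP"] <- subj$derived[["GIP_B"]] + 10
  expect_lt(flux_vector(yhi, subj)[["v3"]], 0)
  ylo <- y
  ylo["GIP"] <- subj$derived[["GIP_B"]] / 2
  expect_gt(flux_vector(ylo, subj)[["v3"]], 0)
})

test_that("zeroed coupling coefficients are masked completely", {
  st <- model_structure(a = FALSE, b = TRUE, c = FALSE, d = TRUE)
  kin <- c(k2 = 5, k3 = 0.08, k4 = 1.2, k5 = 0.1, k6 = 1.1, k7 = 0.07,
           k8 = 6, k10 = 0.09, L2 = 10, L4 = 15, L6 = 8, L8 = 2,
           L11 = 600, V = 0.15, b = 0.03, d = 0.02)
  ini <- c(GIP0 = 10, GLP10 = 5, G0 = 90, I0 = 40, CP0 = 500, X0 = 1)
  s1 <- ogtt_subject(kin, ini, st)
  # supplying values for the masked coefficients must change nothing
  s2 <- ogtt_subject(c(kin, a = 123, c = 456), ini, st)
  y <- setNames(ogttdesign:::initial_state_vector(s1),
                state_names(st))
  y["GIP"] <- 40
  y["GLP1"] <- 12
  expect_identical(flux_vector(y, s1), flux_vector(y, s2))
  expect_identical(s1$derived, s2$derived)
  # v10 reduces to k10 * G when all coefficients are zeroed
  st0 <- model_structure(a = FALSE, b = FALSE, c = FALSE, d = FALSE)
  s0 <- ogtt_subject(kin[setdiff(names(kin), c("b", "d"))], ini, st0)
  expect_equal(flux_vector(y, s0)[["v10"]], 0.09 * y[["G"]])
})

test_that("rhs identities hold and GLP-1-free systems have 7 states", {
  subj <- random_subject(seed = 3)
  y <- setNames(ogttdesign:::initial_state_vector(subj),
                state_names(subj$structure))
  y["Intest_G"] <- 4; y["A_GutG"] <- 2; y["G"] <- 140; y["I"] <- 90
  dy <- model_rhs(y, subj, glucose_flux = 1)
  v <- flux_vector(y, subj, glucose_flux = 1)
  # dCP/dt - dI/dt = v11 - v12 (shared v10 source cancels)
  expect_equal(dy[["CP"]] - dy[["I"]], v[["v11"]] - v[["v12"]])
  expect_equal(dy[["Intest_G"]], v[["v1"]] - v[["v6"]])

  free <- fixture_subject("A")
  expect_length(state_names(free$structure), 7)
  yf <- setNames(ogttdesign:::initial_state_vector(free),
                 state_names(model_structure()))
  dyf <- model_rhs(yf[state_names(free$structure)], free, 0)
  expect_named(dyf, state_names(free$structure))
  expect_false("GLP1" %in% names(dyf))
})

test_that("structure bookkeeping matches the stated parameter counts", {
  full <- model_structure()
  expect_length(kinetic_names(full), 18)
  expect_length(initial_names(full), 6)
  expect_equal(n_free_parameters(full), 24)
  expect_equal(structure_label(full), "full")

  bc0 <- model_structure(b = FALSE, c = FALSE)
  expect_equal(n_free_parameters(bc0), 22)
  expect_equal(structure_label(bc0), "b=c=0")

  gfree <- model_structure(a = FALSE, include_glp1 = FALSE)
  expect_equal(structure_label(gfree), "GLP1-free, a=0")
  expect_false(gfree$c_free)
  expect_false(gfree$d_free)
  expect_equal(n_free_parameters(gfree), 12 + 5)
  # forcing c/d free without the GLP-1 state is overridden
  forced <- model_structure(c = TRUE, d = TRUE, include_glp1 = FALSE)
  expect_false(forced$c_free)
})

test_that("subject JSON round-trips exactly", {
  subj <- fixture_subject("B")
  path <- withr::local_tempfile(fileext = ".json")
  write_subject_json(subj, path)
  back <- read_subject_json(path)
  expect_equal(back$kinetics, subj$kinetics)
  expect_equal(back$init, subj$init)
  expect_equal(back$derived, subj$derived)
  expect_equal(structure_label(back$structure),
               structure_label(subj$structure))
})
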