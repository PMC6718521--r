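# shared helpers for the suite: fast settings and a trajectory-RMSE metric

quick_solver <- function(step = 0.05, horizon = 240) {
  solver_settings("euler", step = step, horizon = horizon)
}

quick_fit_settings <- function(seed = 1, trials = 1, ...) {
  fit_settings(trials = trials, pop = 40, generations = 15, step = 0.1,
               lm_starts = 2, lm_maxiter = 60, lm_hops = 1,
               simplex_maxit = 100, seed = seed, ...)
}

# worst per-(condition, species) trajectory RMSE between two subjects,
# as a percentage of the reference subject's trajectory range
worst_trajectory_rmse <- function(truth, fitted,
                                  settings = quick_solver()) {
  worst <- 0
  for (cond in standard_protocols()$condition) {
    tt <- simulate_subject(truth, condition_schedule(cond), settings)
    tf <- simulate_subject(fitted, condition_schedule(cond), settings)
    for (sp in intersect(c("G", "I", "CP", "GIP", "GLP1"), names(tt))) {
      rng <- max(tt[[sp]]) - min(tt[[sp]])
      worst <- max(worst, sqrt(mean((tt[[sp]] - tf[[sp]])^2)) / rng * 100)
    }
  }
  worst
}

# random admissible parameter draw (positive kinetics, positive levels)
random_subject <- function(structure = model_structure(), seed = NULL) {
  draw <- function() {
    kin <- c(k2 = stats::runif(1, 0.5, 20),
             k3 = stats::runif(1, 0.01, 0.5),
             k4 = stats::runif(1, 0.1, 5),
             k5 = stats::runif(1, 0.01, 0.5),
             k6 = stats::runif(1, 0.2, 2),
             k7 = stats::runif(1, 0.01, 0.2),
             k8 = stats::runif(1, 1, 20),
             k10 = stats::runif(1, 0.01, 0.5),
             L2 = stats::runif(1, 1, 50),
             L4 = stats::runif(1, 1, 50),
             L6 = stats::runif(1, 1, 30),
             L8 = stats::runif(1, 0.5, 10),
             L11 = stats::runif(1, 50, 2000),
             V = stats::runif(1, 0.05, 1),
             a = stats::runif(1, 0.1, 5),
             b = stats::runif(1, 0.001, 0.1),
             c = stats::runif(1, 0.1, 5),
             d = stats::runif(1, 0.001, 0.1))
    ini <- c(GIP0 = stats::runif(1, 2, 50),
             GLP10 = stats::runif(1, 1, 20),
             G0 = stats::runif(1, 70, 110),
             I0 = stats::runif(1, 20, 100),
             CP0 = stats::runif(1, 200, 1000),
             X0 = stats::runif(1, 0.3, 3))
    ogtt_subject(kin, ini, structure)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}
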