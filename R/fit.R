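#' Settings for per-subject parameter estimation
#'
#' Estimation minimizes the normalized RSS with a global evolutionary-
#' programming (EP) search over log-transformed parameters followed by
#' Nelder--Mead simplex refinement, repeated over independent trials. The
#' defaults are desk-scale (a few minutes per subject on one core); a
#' cluster-scale configuration (say population 5000, 5000 generations,
#' 40 trials) is reachable through the same arguments.
#'
#' @param trials Number of independent EP + simplex trials.
#' @param pop EP population size (parents).
#' @param generations EP generations.
#' @param tournament Opponents per individual in survivor selection.
#' @param step Euler step (min) used for objective evaluation during
#'   fitting.
#' @param simplex_maxit Maximum Nelder--Mead iterations per restart.
#' @param simplex_restarts Additional simplex restarts from the previous
#'   optimum (restarting a collapsed simplex is standard practice in
#'   moderate dimension).
#' @param seed RNG seed; trial `j` uses `seed + j - 1`.
#' @param lm_starts Number of EP candidates (the incumbent best plus the
#'   top-ranked population members) used as starting points for the
#'   Levenberg--Marquardt polish; 0 disables the polish.
#' @param lm_maxiter Maximum LM iterations per start.
#' @param lm_hops Basin-hopping rounds: the LM optimum is perturbed
#'   log-normally and re-polished, keeping any improvement.
#' @param bounds Optional bounds matrix (rows `lower`, `upper`, columns
#'   named by free parameter); default [default_fit_bounds()].
#' @return A list of class `ogtt_fit_settings`.
#' @export
fit_settings <- function(trials = 2, pop = 200, generations = 80,
                         tournament = 10, step = 0.05,
                         simplex_maxit = 500, simplex_restarts = 0,
                         lm_starts = 4, lm_maxiter = 150, lm_hops = 10,
                         seed = 1, bounds = NULL) {
  stopifnot(trials >= 1, pop >= 2, generations >= 1, tournament >= 1,
            step > 0, lm_starts >= 0, lm_hops >= 0)
  structure(list(trials = trials, pop = pop, generations = generations,
                 tournament = tournament, step = step,
                 simplex_maxit = simplex_maxit,
                 simplex_restarts = simplex_restarts,
                 lm_starts = lm_starts, lm_maxiter = lm_maxiter,
                 lm_hops = lm_hops, seed = seed, bounds = bounds),
            class = "ogtt_fit_settings")
}

# robust residual vector for least-squares refinement: each observation's
# residual scaled by 1/range. A candidate whose integration goes non-finite
# gets a soft barrier graded by how early it blew up, so the refiner sees a
# slope back toward the feasible region instead of a flat plateau.
make_residual_fn <- function(structure, rss_data, step, par_names) {
  nres <- sum(vapply(rss_data$conds, function(cd) nrow(cd$obs), integer(1)))
  function(z) {
    X <- matrix(exp(z), nrow = 1, dimnames = list(NULL, par_names))
    m <- build_candidate_matrices(X, structure)
    out <- vector("list", length(rss_data$conds))
    for (i in seq_along(rss_data$conds)) {
      cd <- rss_data$conds[[i]]
      tend <- max(max(cd$times), max(cd$events[, 2]))
      sim <- tryCatch({
        tr <- cpp_euler_traj(m$P[1, ], m$Y0[1, ], cd$events, step, tend,
                             cd$times, FALSE)
        tr[cbind(cd$obs[, 2] + 1, cd$obs[, 1] + 1)]
      }, error = function(e) {
        tf <- suppressWarnings(as.numeric(
          sub(".*at t = ([0-9.eE+-]+) min.*", "\\1",
              conditionMessage(e))))
        if (!is.finite(tf)) tf <- 0
        attr(tf, "blowup") <- TRUE
        tf
      })
      if (isTRUE(attr(sim, "blowup"))) {
        return(rep(100 * (1 + (tend - as.numeric(sim)) / tend), nres))
      }
      out[[i]] <- (sim - cd$obs[, 3]) * sqrt(cd$obs[, 4])
    }
    unlist(out)
  }
}

#' Levenberg--Marquardt refinement of a candidate parameter vector
#'
#' Exploits the least-squares structure of the normalized RSS: the
#' per-observation residuals (scaled by each series' range) are minimized
#' with `minpack.lm::nls.lm` on the log-transformed parameters inside the
#' search box. Far more efficient per evaluation than direct search, but
#' local -- [fit_subject()] therefore runs it from several EP candidates.
#'
#' @inheritParams simplex_refine
#' @param maxiter Maximum LM iterations.
#' @return List with refined `par`, `value` (RSS), `start_value`.
#' @export
lm_refine <- function(par, dataset, structure, settings = fit_settings(),
                      protocols = standard_protocols(), bounds = NULL,
                      maxiter = settings$lm_maxiter) {
  bounds <- bounds %||% settings$bounds %||%
    default_fit_bounds(structure, dataset)
  rd <- make_rss_data(dataset, structure, protocols)
  nm <- colnames(bounds)
  fn <- make_residual_fn(structure, rd, settings$step, nm)
  z0 <- log(pmin(pmax(par[nm], bounds["lower", ]), bounds["upper", ]))
  start_value <- sum(fn(z0)^2)
  lm <- minpack.lm::nls.lm(
    z0, lower = log(bounds["lower", ]), upper = log(bounds["upper", ]),
    fn = fn,
    control = minpack.lm::nls.lm.control(maxiter = maxiter,
                                         maxfev = 100 * (length(nm) + 1)))
  value <- sum(lm$fvec^2)
  if (value <= start_value) {
    list(par = stats::setNames(exp(lm$par), nm), value = value,
         start_value = start_value)
  } else {
    list(par = par[nm], value = start_value, start_value = start_value)
  }
}

#' Default search bounds for free parameters
#'
#' Kinetic parameters are searched on a log scale inside per-class boxes
#' that are generous (two to four decades) around the physiological scales
#' of this system: first-order rates (`k3`, `k5`, `k7`, in 1/min) span
#' relaxation times from seconds to ~1000 min; secretion capacities (`k2`,
#' `k4`, pM/min) and the absorption capacity (`k6`, g/min) span three or
#' more decades; Michaelis constants span well past the dose and hormone
#' ranges. Scale-aware boxes keep the search away from the vast region
#' where rate constants exceed the reciprocal integration step, which is
#' numerically infeasible rather than physiologically meaningful. Initial
#' levels of the measured species are bounded by 0.1x and 10x their fasting
#' (earliest sampled) values in the dataset; the unobserved
#' effective-insulin level `X0` is searched over `[0.1, 10]` around its
#' dimensionless scale of 1.
#'
#' @param structure A [model_structure()].
#' @param dataset The dataset being fitted (for fasting levels).
#' @return Numeric matrix, rows `lower` and `upper`, columns named by the
#'   free parameters of the structure.
#' @export
default_fit_bounds <- function(structure, dataset) {
  kin <- kinetic_names(structure)
  ini <- initial_names(structure)
  class_bounds <- list(
    k2 = c(1e-3, 1e3), k3 = c(1e-3, 20), k4 = c(1e-3, 1e3),
    k5 = c(1e-3, 20), k6 = c(1e-3, 10), k7 = c(1e-3, 20),
    k8 = c(1e-2, 1e3), k10 = c(1e-4, 10),
    L2 = c(0.1, 500), L4 = c(0.1, 500), L6 = c(0.1, 500),
    L8 = c(0.01, 100), L11 = c(1, 1e5), V = c(1e-3, 10),
    a = c(1e-4, 1e3), b = c(1e-6, 10), c = c(1e-4, 1e3),
    d = c(1e-6, 10))
  lower <- stats::setNames(
    vapply(kin, function(nm) class_bounds[[nm]][1], numeric(1)), kin)
  upper <- stats::setNames(
    vapply(kin, function(nm) class_bounds[[nm]][2], numeric(1)), kin)
  fasting <- dplyr::summarise(
    dplyr::group_by(dataset[dataset$included, ], .data$species),
    fasting = mean(.data$value[.data$time_min == min(.data$time_min)]),
    .groups = "drop")
  fast_of <- function(sp) {
    v <- fasting$fasting[fasting$species == sp]
    if (length(v) == 0 || v <= 0) 1 else v
  }
  init_map <- c(GIP0 = "GIP", GLP10 = "GLP1", G0 = "G", I0 = "I",
                CP0 = "CP")
  for (nm in ini) {
    if (nm == "X0") {
      lower[nm] <- 0.1
      upper[nm] <- 10
    } else {
      f <- fast_of(init_map[[nm]])
      lower[nm] <- 0.1 * f
      upper[nm] <- 10 * f
    }
  }
  rbind(lower = lower, upper = upper)
}

#' Evolutionary-programming minimizer over a box (log scale)
#'
#' Classic self-adaptive EP: each parent carries a per-coordinate mutation
#' scale; a child perturbs the (log-transformed) coordinates with Gaussian
#' noise whose scale is itself log-normally perturbed; survivors among the
#' combined parents and children are chosen by stochastic q-tournament
#' (score = number of random opponents with larger objective), elitist by
#' construction of the score. No crossover.
#'
#' @param fn Objective: takes an `m x p` matrix of candidate rows on the
#'   natural scale, returns `m` values (lower is better).
#' @param lower,upper Named positive bounds (natural scale).
#' @param pop Population size.
#' @param generations Number of generations.
#' @param tournament Opponents per individual.
#' @param init Optional matrix of natural-scale individuals to seed into
#'   the initial population.
#' @param seed RNG seed (`NULL` leaves the RNG state alone).
#' @return List with `par` (best row, natural scale), `value`, `trace`
#'   (best-so-far per generation), `population`, `values`.
#' @examples
#' # 1-parameter quadratic: minimum at 3
#' res <- ep_minimize(function(X) (X[, 1] - 3)^2, c(p = 0.01), c(p = 100),
#'                    pop = 40, generations = 50, seed = 1)
#' res$par
#' @export
ep_minimize <- function(fn, lower, upper, pop = 200, generations = 200,
                        tournament = 10, init = NULL, seed = NULL) {
  stopifnot(length(lower) == length(upper), all(lower > 0),
            all(upper > lower))
  run <- function() {
    p <- length(lower)
    lz <- log(lower)
    uz <- log(upper)
    span <- uz - lz
    tau1 <- 1 / sqrt(2 * p)
    tau2 <- 1 / sqrt(2 * sqrt(p))

    Z <- matrix(stats::runif(pop * p, rep(lz, each = pop),
                             rep(uz, each = pop)), nrow = pop)
    colnames(Z) <- names(lower)
    if (!is.null(init)) {
      ni <- min(nrow(init), pop)
      Zi <- log(pmin(pmax(t(init[seq_len(ni), names(lower), drop = FALSE]),
                          lower), upper))
      Z[seq_len(ni), ] <- t(Zi)
    }
    S <- matrix(rep(span / 10, each = pop), nrow = pop)
    nat <- function(M) exp(M)
    J <- fn(nat(Z))
    best_i <- which.min(J)
    best <- list(par = nat(Z[best_i, , drop = FALSE])[1, ],
                 value = J[best_i])
    trace <- numeric(generations)

    for (g in seq_len(generations)) {
      Sc <- S * exp(tau1 * stats::rnorm(pop) +
                      tau2 * matrix(stats::rnorm(pop * p), nrow = pop))
      Sc <- pmin(pmax(Sc, matrix(rep(span * 1e-4, each = pop), nrow = pop)),
                 matrix(rep(span / 2, each = pop), nrow = pop))
      Zc <- Z + Sc * matrix(stats::rnorm(pop * p), nrow = pop)
      Zc <- pmin(pmax(Zc, rep(lz, each = pop)), rep(uz, each = pop))
      Jc <- fn(nat(Zc))
      ci <- which.min(Jc)
      if (Jc[ci] < best$value) {
        best <- list(par = nat(Zc[ci, , drop = FALSE])[1, ], value = Jc[ci])
      }
      Zall <- rbind(Z, Zc)
      Sall <- rbind(S, Sc)
      Jall <- c(J, Jc)
      score <- tournament_scores(Jall, tournament)
      keep <- order(-score, Jall)[seq_len(pop)]
      Z <- Zall[keep, , drop = FALSE]
      S <- Sall[keep, , drop = FALSE]
      J <- Jall[keep]
      trace[g] <- best$value
    }
    list(par = best$par, value = best$value, trace = trace,
         population = nat(Z), values = J)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' EP global search for the RSS objective
#'
#' Runs [ep_minimize()] on the free parameters of `structure` against the
#' normalized RSS of `dataset`, seeding one individual at the fasting
#' levels of the data (initial levels at the earliest measured values,
#' kinetic parameters at the geometric center of their bounds).
#'
#' @inheritParams rss_terms
#' @param structure The [model_structure()] being fitted.
#' @param settings A [fit_settings()].
#' @param seed Seed for this search (defaults to `settings$seed`).
#' @return As [ep_minimize()], plus `bounds` and `rss_data`.
#' @export
ep_global_search <- function(dataset, structure, settings = fit_settings(),
                             protocols = standard_protocols(),
                             seed = settings$seed) {
  bounds <- settings$bounds %||% default_fit_bounds(structure, dataset)
  rd <- make_rss_data(dataset, structure, protocols)
  fn <- function(X) rss_fast(X, structure, rd, step = settings$step)
  guess <- sqrt(bounds["lower", ] * bounds["upper", ])
  res <- ep_minimize(fn, bounds["lower", ], bounds["upper", ],
                     pop = settings$pop,
                     generations = settings$generations,
                     tournament = settings$tournament,
                     init = matrix(guess, nrow = 1,
                                   dimnames = list(NULL, names(guess))),
                     seed = seed)
  res$bounds <- bounds
  res$rss_data <- rd
  res
}

#' Simplex refinement of a candidate parameter vector
#'
#' Nelder--Mead (the `fminsearch` simplex) on the log-transformed
#' parameters, with candidates clipped into the search box and penalized
#' quadratically outside it. Optionally restarted from its own optimum.
#'
#' @param par Named free-parameter vector (natural scale) to refine.
#' @inheritParams ep_global_search
#' @param bounds Bounds matrix as in [fit_settings()].
#' @return List with refined `par`, `value`, and `start_value`.
#' @export
simplex_refine <- function(par, dataset, structure,
                           settings = fit_settings(),
                           protocols = standard_protocols(),
                           bounds = NULL) {
  bounds <- bounds %||% settings$bounds %||%
    default_fit_bounds(structure, dataset)
  rd <- make_rss_data(dataset, structure, protocols)
  lz <- log(bounds["lower", ])
  uz <- log(bounds["upper", ])
  nm <- colnames(bounds)
  fn1 <- function(z) {
    zc <- pmin(pmax(z, lz), uz)
    pen <- sum((z - zc)^2)
    X <- matrix(exp(zc), nrow = 1, dimnames = list(NULL, nm))
    val <- rss_fast(X, structure, rd, step = settings$step)
    if (!is.finite(val)) return(1e10 + pen)
    val + 100 * pen
  }
  z <- log(pmin(pmax(par[nm], bounds["lower", ]), bounds["upper", ]))
  start_value <- fn1(z)
  value <- start_value
  for (r in seq_len(1 + settings$simplex_restarts)) {
    opt <- stats::optim(z, fn1, method = "Nelder-Mead",
                        control = list(maxit = settings$simplex_maxit,
                                       reltol = 1e-10))
    if (opt$value <= value) {
      z <- opt$par
      value <- opt$value
    }
  }
  list(par = stats::setNames(exp(pmin(pmax(z, lz), uz)), nm),
       value = value, start_value = start_value)
}

#' Fit a subject model to a multi-condition dataset
#'
#' Runs `trials` independent EP global searches, refines each with the
#' simplex, and keeps the best refined solution. All conditions and species
#' share one parameter set (the subject's physiological state is assumed
#' constant across the protocol conditions).
#'
#' @inheritParams ep_global_search
#' @return An object of class `ogtt_fit`: fields `subject` (the fitted
#'   [ogtt_subject()]), `best_rss`, `trials` (tibble of per-trial RSS),
#'   `traces`, `n_obs`, `structure`, `settings`.
#' @seealso [tidy.ogtt_fit()], [glance.ogtt_fit()], [select_model()]
#' @export
fit_subject <- function(dataset, structure = model_structure(),
                        settings = fit_settings(),
                        protocols = standard_protocols()) {
  bounds <- settings$bounds %||% default_fit_bounds(structure, dataset)
  rd <- make_rss_data(dataset, structure, protocols)
  fn <- function(X) rss_fast(X, structure, rd, step = settings$step)
  nm <- colnames(bounds)
  lm1 <- function(par, maxiter) {
    lm_refine(par, dataset, structure, settings, protocols,
              bounds = bounds, maxiter = maxiter)
  }

  results <- purrr::map(seq_len(settings$trials), function(j) {
    sj <- settings$seed + j - 1
    g1 <- ceiling(settings$generations / 2)
    g2 <- settings$generations - g1
    guess <- sqrt(bounds["lower", ] * bounds["upper", ])
    ep <- ep_minimize(fn, bounds["lower", ], bounds["upper", ],
                      pop = settings$pop, generations = g1,
                      tournament = settings$tournament,
                      init = matrix(guess, nrow = 1,
                                    dimnames = list(NULL, nm)),
                      seed = sj)
    best_par <- ep$par[nm]
    best_rss <- ep$value
    take <- function(res, k) {
      ord <- order(res$values)
      unique(rbind(res$par[nm],
                   res$population[ord[seq_len(min(k, length(ord)))], nm,
                                  drop = FALSE]))
    }
    polish <- function(starts, maxiter) {
      for (i in seq_len(nrow(starts))) {
        ref <- lm1(starts[i, ], maxiter)
        if (ref$value < best_rss) {
          best_rss <<- ref$value
          best_par <<- ref$par
        }
      }
    }
    if (settings$lm_starts > 0) polish(take(ep, settings$lm_starts - 1),
                                       settings$lm_maxiter)
    if (g2 > 0) {
      # memetic second phase: re-seed the polished optimum plus the most
      # fit survivors and continue the EP from there
      reseed <- rbind(matrix(best_par, nrow = 1,
                             dimnames = list(NULL, nm)),
                      take(ep, max(2, settings$pop %/% 4)))
      ep2 <- ep_minimize(fn, bounds["lower", ], bounds["upper", ],
                         pop = settings$pop, generations = g2,
                         tournament = settings$tournament,
                         init = reseed, seed = sj + 10000L)
      if (ep2$value < best_rss) {
        best_rss <- ep2$value
        best_par <- ep2$par[nm]
      }
      if (settings$lm_starts > 0) polish(take(ep2, settings$lm_starts - 1),
                                         settings$lm_maxiter)
      ep <- ep2
    }
    # coordinate-subset basin hops: kick a few parameters hard and
    # re-polish, keeping any improvement
    if (settings$lm_hops > 0) {
      withr::with_seed(sj + 5000L, {
        for (hop in seq_len(settings$lm_hops)) {
          pert <- best_par
          idx <- sample(length(pert),
                        min(sample(2:6, 1), length(pert)))
          pert[idx] <- pert[idx] * exp(stats::rnorm(length(idx), 0, 1.2))
          ref <- lm1(pert, settings$lm_maxiter)
          if (ref$value < best_rss) {
            best_rss <- ref$value
            best_par <- ref$par
          }
        }
      })
    }
    # final simplex descent from the polished optimum
    ref <- simplex_refine(best_par, dataset, structure, settings,
                          protocols, bounds = bounds)
    if (ref$value < best_rss) {
      best_rss <- ref$value
      best_par <- ref$par
    }
    list(par = best_par, rss = best_rss, ep_rss = ep$value,
         trace = ep$trace)
  })
  rss_values <- purrr::map_dbl(results, "rss")
  best <- results[[which.min(rss_values)]]
  kin_nm <- kinetic_names(structure)
  ini_nm <- initial_names(structure)
  subject <- ogtt_subject(kinetics = best$par[kin_nm],
                          init = best$par[ini_nm],
                          structure = structure,
                          id = unique(dataset$subject_id)[1])
  rd <- make_rss_data(dataset, structure, protocols)
  out <- list(subject = subject, best_rss = min(rss_values),
              trials = tibble::tibble(
                trial = seq_along(rss_values),
                rss = rss_values,
                ep_rss = purrr::map_dbl(results, "ep_rss")),
              traces = purrr::map(results, "trace"),
              n_obs = rd$n_obs, structure = structure, settings = settings)
  class(out) <- "ogtt_fit"
  out
}

#' @export
print.ogtt_fit <- function(x, ...) {
  cat("<ogtt_fit> structure: ", structure_label(x$structure),
      "  best RSS: ", signif(x$best_rss, 5),
      "  (", nrow(x$trials), " trial(s), n = ", x$n_obs, ")\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted subject model
#'
#' @param x An `ogtt_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `type` (`"kinetic"`,
#'   `"initial"` or `"derived"`).
#' @export
tidy.ogtt_fit <- function(x, ...) {
  s <- x$subject
  dplyr::bind_rows(
    tibble::tibble(term = names(s$kinetics), estimate = unname(s$kinetics),
                   type = "kinetic"),
    tibble::tibble(term = names(s$init), estimate = unname(s$init),
                   type = "initial"),
    tibble::tibble(term = names(s$derived), estimate = unname(s$derived),
                   type = "derived")
  )
}

#' One-row summary of a fitted subject model
#'
#' @param x An `ogtt_fit`.
#' @param ... Unused.
#' @return A tibble with `rss`, `n_obs`, `k`, `aic`, `trials`.
#' @export
glance.ogtt_fit <- function(x, ...) {
  k <- n_free_parameters(x$structure)
  tibble::tibble(rss = x$best_rss, n_obs = x$n_obs, k = k,
                 aic = aic_score(x$best_rss, x$n_obs, k),
                 trials = nrow(x$trials))
}
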