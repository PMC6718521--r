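#' Per-series contributions to the normalized residual sum of squares
#'
#' The fitting objective is
#' \deqn{RSS = \sum_i \sum_k \sum_t \left[\frac{x^{sim}_{i,k}(t) -
#'   x^{exp}_{i,k}(t)}{\max_t x^{exp}_{i,k}(t) - \min_t x^{exp}_{i,k}(t)}
#'   \right]^2}
#' over conditions \eqn{i}, measured species \eqn{k} and sampling times
#' \eqn{t}. Each series is normalized by its own experimental range, so
#' species with very different absolute scales contribute comparably.
#' Conditions or rows flagged `included = FALSE` contribute nothing.
#'
#' @param dataset Long dataset tibble (see [generate_dataset()] /
#'   [read_dataset()]).
#' @param subject An [ogtt_subject()] supplying the simulated values.
#' @param settings [solver_settings()] for the simulation; the horizon is
#'   extended to cover the data if needed.
#' @param protocols Protocol table mapping condition labels to schedules.
#' @return A tibble with one row per (condition, species) series: `n` data
#'   points, experimental `range`, and the series' `contribution` to RSS.
#' @export
rss_terms <- function(dataset, subject,
                      settings = solver_settings("adaptive"),
                      protocols = standard_protocols()) {
  stopifnot(inherits(subject, "ogtt_subject"))
  dataset <- validate_dataset(dataset, protocols,
                              species_ok = .species_names)
  dataset <- dataset[dataset$included, , drop = FALSE]
  model_species <- intersect(.species_names, state_names(subject$structure))
  unseen <- setdiff(unique(dataset$species), model_species)
  if (length(unseen) > 0) {
    dataset <- dataset[dataset$species %in% model_species, , drop = FALSE]
  }
  check_series_ranges(dataset)

  purrr::map_dfr(unique(dataset$condition), function(cond) {
    d <- dataset[dataset$condition == cond, ]
    horizon <- max(settings$horizon, max(d$time_min))
    st <- settings
    st$horizon <- horizon
    traj <- simulate_subject(subject, condition_schedule(cond, protocols),
                             st, times = sort(unique(c(d$time_min,
                                                       horizon))))
    purrr::map_dfr(unique(d$species), function(sp) {
      ds <- d[d$species == sp, ]
      rng <- max(ds$value) - min(ds$value)
      sim <- sample_at(traj, ds$time_min, sp)
      tibble::tibble(condition = cond, species = sp, n = nrow(ds),
                     range = rng,
                     contribution = sum(((sim - ds$value) / rng)^2))
    })
  })
}

#' Normalized residual sum of squares of a subject model against data
#'
#' @inheritParams rss_terms
#' @return Numeric scalar, the sum of all series' contributions (see
#'   [rss_terms()]).
#' @examples
#' subj <- fixture_subject("A")
#' ds <- generate_dataset(subj, noise = 0, seed = 1)
#' rss(ds, subj, solver_settings("euler", step = 0.05, horizon = 240))
#' @export
rss <- function(dataset, subject, settings = solver_settings("adaptive"),
                protocols = standard_protocols()) {
  sum(rss_terms(dataset, subject, settings, protocols)$contribution)
}

check_series_ranges <- function(dataset) {
  rng <- dplyr::summarise(
    dplyr::group_by(dataset, .data$condition, .data$species),
    flat = max(.data$value) == min(.data$value), .groups = "drop")
  bad <- rng[rng$flat, ]
  if (nrow(bad) > 0) {
    stop("degenerate series (max = min), cannot normalize: ",
         paste(bad$condition, bad$species, sep = "/", collapse = ", "))
  }
  invisible(TRUE)
}

# Precompute the per-condition structures consumed by the compiled batch
# RSS evaluator: events, the union time grid, and an observation table in
# (state index, time index, value, 1/range^2) form.
make_rss_data <- function(dataset, structure,
                          protocols = standard_protocols()) {
  dataset <- validate_dataset(dataset, protocols,
                              species_ok = .species_names)
  dataset <- dataset[dataset$included, , drop = FALSE]
  model_species <- intersect(.species_names, state_names(structure))
  dataset <- dataset[dataset$species %in% model_species, , drop = FALSE]
  check_series_ranges(dataset)

  conds <- lapply(unique(dataset$condition), function(cond) {
    d <- dataset[dataset$condition == cond, ]
    times <- sort(unique(d$time_min))
    obs <- do.call(rbind, lapply(unique(d$species), function(sp) {
      ds <- d[d$species == sp, ]
      rng <- max(ds$value) - min(ds$value)
      cbind(match(sp, .state_names_8) - 1L,
            match(ds$time_min, times) - 1L,
            ds$value, 1 / rng^2)
    }))
    sched <- condition_schedule(cond, protocols)
    list(events = schedule_events(sched), times = times, obs = obs)
  })
  list(conds = conds, n_obs = nrow(dataset),
       species = sort(unique(dataset$species)))
}

# Vectorized steady-state closure: X is an n x p matrix of free parameters
# (columns named); returns list(P = n x 24 closed parameters, Y0 = n x 8).
build_candidate_matrices <- function(X, structure) {
  n <- nrow(X)
  col <- function(nm, default = 0) {
    if (nm %in% colnames(X)) X[, nm] else rep(default, n)
  }
  a <- if (structure$a_free) col("a") else rep(0, n)
  b <- if (structure$b_free) col("b") else rep(0, n)
  cc <- if (structure$c_free) col("c") else rep(0, n)
  d <- if (structure$d_free) col("d") else rep(0, n)
  GLP10 <- if (structure$include_glp1) col("GLP10") else rep(0, n)
  G0 <- col("G0"); I0 <- col("I0"); CP0 <- col("CP0")
  X0 <- col("X0"); GIP0 <- col("GIP0")
  k8 <- col("k8"); k10 <- col("k10"); L8 <- col("L8"); L11 <- col("L11")
  S0 <- G0 + a * GIP0 + b * G0 * GIP0 + cc * GLP10 + d * G0 * GLP10
  P <- cbind(col("k2"), col("k3"), col("k4"), col("k5"), col("k6"),
             col("k7"), k8,
             k8 / (G0 * X0 * (X0 + L8)),
             k10,
             k10 * (L11 + I0) / I0 * S0,
             k10 / CP0 * S0,
             I0 / ((I0 + L11) * X0),
             col("L2"), col("L4", default = 1), col("L6"), L8, L11,
             col("V"),
             a, b, cc, d, GIP0, GLP10)
  colnames(P) <- .full_param_names
  Y0 <- cbind(0, GIP0, GLP10, 0, G0, I0, CP0, X0)
  colnames(Y0) <- .state_names_8
  list(P = P, Y0 = Y0)
}

# Fast batch RSS: X rows are free-parameter vectors on the natural scale.
rss_fast <- function(X, structure, rss_data, step = 0.05,
                     floor_at_zero = FALSE) {
  m <- build_candidate_matrices(X, structure)
  cpp_rss_batch(m$P, m$Y0, rss_data$conds, step, floor_at_zero)
}
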