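#' Settings for ingestion-pattern optimization
#'
#' The inverse problem searches integer-gram patterns on the 5-min grid
#' over 0--60 min (13 slots, fixed total dose, at least 1 g at time zero)
#' minimizing the simulated peak of blood glucose or insulin over the
#' horizon T. The search is evolutionary programming without crossover:
#' mutation transfers single grams between random slots, selection is a
#' stochastic q-tournament over the combined parent+child population.
#'
#' Defaults are desk-scale (population 100, 100 generations, 2 trials,
#' search step 0.01 min); the full-scale configuration for this problem is
#' population 500, 500 generations, 5 trials with a 0.001-min step, and is
#' reachable through the same arguments. The per-mutation transfer count L
#' starts at `L_init` and decreases by `L_decrement` every `L_interval`
#' generations (never below 0), coarse-to-fine.
#'
#' @param pop Population size N.
#' @param generations Generations K (excluding initialization).
#' @param L_init,L_decrement,L_interval Transfer-count schedule.
#' @param tournament Opponents M per individual; default `pop / 5`.
#' @param trials Independent restarts; the best over trials is returned.
#' @param search_step Euler step (min) for objective evaluation during the
#'   search.
#' @param final_step Euler step (min) for the final reported objective.
#' @param horizon Simulation horizon T (min).
#' @param seed RNG seed; trial `j` uses `seed + j - 1`.
#' @param source_rule Transfer-source interpretation: `"at_least_1"`
#'   (a slot holding >= 1 g may donate, so slots can empty; default) or
#'   `"more_than_1"` (strict reading; donors keep at least 1 g).
#' @return A list of class `ogtt_pattern_settings`.
#' @export
pattern_settings <- function(pop = 100, generations = 100, L_init = 20,
                             L_decrement = 1, L_interval = 25,
                             tournament = NULL, trials = 2,
                             search_step = 0.01, final_step = 0.001,
                             horizon = 480, seed = 1,
                             source_rule = c("at_least_1", "more_than_1")) {
  source_rule <- match.arg(source_rule)
  tournament <- tournament %||% max(1L, as.integer(pop / 5))
  stopifnot(pop >= 2, generations >= 1, L_init >= 0, tournament >= 1,
            trials >= 1, search_step > 0, final_step > 0, horizon > 0)
  structure(list(pop = pop, generations = generations, L_init = L_init,
                 L_decrement = L_decrement, L_interval = L_interval,
                 tournament = tournament, trials = trials,
                 search_step = search_step, final_step = final_step,
                 horizon = horizon, seed = seed, source_rule = source_rule),
            class = "ogtt_pattern_settings")
}

transfer_count <- function(gen, settings) {
  max(0L, settings$L_init -
        settings$L_decrement * ((gen - 1) %/% settings$L_interval))
}

#' Initialize the optimizer population
#'
#' The population always contains the full bolus (all grams in the first
#' slot) and the endpoint split (1 g at the first slot, the rest in the
#' last); the remaining individuals place 1 g at the first slot and
#' distribute the other `total - 1` grams uniformly at random across all
#' slots.
#'
#' @param n Population size (>= 2).
#' @param total Total grams.
#' @param n_slots Number of slots.
#' @return An `n x n_slots` integer matrix; every row sums to `total` with
#'   first entry >= 1.
#' @export
init_population <- function(n, total = 50, n_slots = 13) {
  stopifnot(n >= 2, total >= 1, n_slots >= 1)
  U <- matrix(0L, nrow = n, ncol = n_slots)
  U[1, 1] <- as.integer(total)
  U[2, 1] <- 1L
  U[2, n_slots] <- as.integer(total - 1)
  if (n_slots == 1) U[2, 1] <- as.integer(total)
  if (n > 2) {
    for (r in 3:n) {
      u <- integer(n_slots)
      u[1] <- 1L
      if (total > 1) {
        draws <- sample.int(n_slots, total - 1, replace = TRUE)
        u <- u + tabulate(draws, nbins = n_slots)
      }
      U[r, ] <- u
    }
  }
  U
}

#' Mutate an ingestion pattern by random single-gram transfers
#'
#' Exactly: remove 1 g from the first slot; `L` times, pick a source and a
#' destination slot uniformly at random and move 1 g if the source holds
#' enough; finally add 1 g back at the first slot. Total grams and the
#' first-slot >= 1 constraint are preserved; with `L = 0` the pattern is
#' returned unchanged.
#'
#' @param u Integer vector of grams per slot (or an [ingestion_pattern()]).
#' @param L Number of transfer attempts.
#' @param source_rule See [pattern_settings()].
#' @return Mutated pattern, same type as the input.
#' @export
mutate_pattern <- function(u, L, source_rule = c("at_least_1",
                                                 "more_than_1")) {
  source_rule <- match.arg(source_rule)
  was_pattern <- inherits(u, "ogtt_pattern")
  slots <- attr(u, "slots")
  v <- as.integer(u)
  min_src <- if (source_rule == "at_least_1") 1L else 2L
  k <- length(v)
  v[1] <- v[1] - 1L
  if (L > 0) {
    src <- sample.int(k, L, replace = TRUE)
    dst <- sample.int(k, L, replace = TRUE)
    for (l in seq_len(L)) {
      if (v[src[l]] >= min_src) {
        v[src[l]] <- v[src[l]] - 1L
        v[dst[l]] <- v[dst[l]] + 1L
      }
    }
  }
  v[1] <- v[1] + 1L
  if (was_pattern) ingestion_pattern(v, slots) else v
}

#' Stochastic tournament evaluation scores
#'
#' Each individual meets `M` opponents drawn uniformly with replacement
#' from the other individuals; its score is the number of opponents with a
#' strictly larger objective value. Higher scores are better; a unique
#' minimum always scores `M`.
#'
#' @param J Numeric vector of objective values.
#' @param M Opponents per individual.
#' @return Integer vector of scores in `[0, M]`.
#' @export
tournament_scores <- function(J, M) {
  n <- length(J)
  stopifnot(n >= 2, M >= 1)
  vapply(seq_len(n), function(i) {
    opp <- sample.int(n - 1, M, replace = TRUE)
    opp <- opp + (opp >= i)
    sum(J[opp] > J[i])
  }, integer(1))
}

#' Objective value of one ingestion pattern
#'
#' Simulates the subject under the pattern (each slot a 0.5-min event) and
#' returns the peak blood glucose (`"glucose_peak"`, mg/dL) or peak insulin
#' (`"insulin_peak"`, pM) over the horizon.
#'
#' @param pattern An [ingestion_pattern()].
#' @param subject An [ogtt_subject()].
#' @param objective `"glucose_peak"` or `"insulin_peak"`.
#' @param step Euler step (min).
#' @param horizon Horizon T (min).
#' @return Numeric scalar J.
#' @export
evaluate_objective <- function(pattern, subject,
                               objective = c("glucose_peak",
                                             "insulin_peak"),
                               step = 0.001, horizon = 480) {
  objective <- match.arg(objective)
  stopifnot(inherits(pattern, "ogtt_pattern"),
            inherits(subject, "ogtt_subject"))
  sched <- pattern_to_schedule(pattern)
  check_event_alignment(schedule_events(sched), step)
  idx <- match(if (objective == "glucose_peak") "G" else "I",
               .state_names_8) - 1L
  cpp_peak(full_param_vector(subject), initial_state_vector(subject),
           schedule_events(sched), step, horizon, idx, FALSE)
}

peak_batch <- function(U, subject, objective, step, horizon, slots) {
  idx <- match(if (objective == "glucose_peak") "G" else "I",
               .state_names_8) - 1L
  cpp_peak_patterns(full_param_vector(subject),
                    initial_state_vector(subject),
                    U, slots, 0.5, step, horizon, idx, FALSE)
}

#' Optimize the ingestion pattern for one subject
#'
#' Evolutionary-programming search for the integer pattern minimizing the
#' peak of blood glucose or insulin, under the constraints: fixed total
#' grams on the slot grid, at least 1 g in the first slot. The incumbent
#' best pattern is tracked globally across mutation steps (elitist), so the
#' best-objective trace is non-increasing. The best pattern over all trials
#' is re-evaluated at `final_step` for the reported objective value.
#'
#' @param subject An [ogtt_subject()].
#' @param objective `"glucose_peak"` or `"insulin_peak"`.
#' @param settings A [pattern_settings()].
#' @param total Total grams to distribute (default 50).
#' @param slots Slot times in min (default `seq(0, 60, 5)`).
#' @return An object of class `ogtt_pattern_opt`: `best_pattern`
#'   (an [ingestion_pattern()]), `objective`, `J` (final-step value),
#'   `J_search` (search-step value), `trace` (tibble trial/generation/
#'   best_J), `trials` (per-trial best), `settings`.
#' @examples
#' \donttest{
#' subj <- fixture_subject("A")
#' st <- pattern_settings(pop = 30, generations = 20, trials = 1,
#'                        search_step = 0.05, final_step = 0.01)
#' opt <- optimize_pattern(subj, "glucose_peak", st)
#' opt$best_pattern
#' }
#' @export
optimize_pattern <- function(subject,
                             objective = c("glucose_peak", "insulin_peak"),
                             settings = pattern_settings(), total = 50,
                             slots = seq(0, 60, by = 5)) {
  objective <- match.arg(objective)
  stopifnot(inherits(subject, "ogtt_subject"),
            inherits(settings, "ogtt_pattern_settings"))
  n_slots <- length(slots)
  run_trial <- function(trial_seed) {
    withr::with_seed(trial_seed, {
      U <- init_population(settings$pop, total, n_slots)
      J <- peak_batch(U, subject, objective, settings$search_step,
                      settings$horizon, slots)
      bi <- which.min(J)
      best_u <- U[bi, ]
      best_J <- J[bi]
      trace <- numeric(settings$generations)
      for (g in seq_len(settings$generations)) {
        L <- transfer_count(g, settings)
        Uc <- U
        for (r in seq_len(settings$pop)) {
          Uc[r, ] <- mutate_pattern(U[r, ], L, settings$source_rule)
        }
        Jc <- peak_batch(Uc, subject, objective, settings$search_step,
                         settings$horizon, slots)
        ci <- which.min(Jc)
        if (Jc[ci] < best_J) {
          best_J <- Jc[ci]
          best_u <- Uc[ci, ]
        }
        Uall <- rbind(U, Uc)
        Jall <- c(J, Jc)
        score <- tournament_scores(Jall, settings$tournament)
        keep <- order(-score, Jall, seq_along(Jall))[seq_len(settings$pop)]
        U <- Uall[keep, , drop = FALSE]
        J <- Jall[keep]
        trace[g] <- best_J
      }
      list(best_u = best_u, best_J = best_J, trace = trace)
    })
  }
  trials <- purrr::map(seq_len(settings$trials),
                       function(j) run_trial(settings$seed + j - 1))
  tJ <- purrr::map_dbl(trials, "best_J")
  best <- trials[[which.min(tJ)]]
  pattern <- ingestion_pattern(best$best_u, slots)
  J_final <- evaluate_objective(pattern, subject, objective,
                                step = settings$final_step,
                                horizon = settings$horizon)
  out <- list(
    best_pattern = pattern, objective = objective, J = J_final,
    J_search = best$best_J,
    trace = purrr::map_dfr(seq_along(trials), function(j) {
      tibble::tibble(trial = j,
                     generation = seq_along(trials[[j]]$trace),
                     best_J = trials[[j]]$trace)
    }),
    trials = tibble::tibble(trial = seq_along(tJ), best_J = tJ),
    settings = settings
  )
  class(out) <- "ogtt_pattern_opt"
  out
}

#' @export
print.ogtt_pattern_opt <- function(x, ...) {
  cat("<ogtt_pattern_opt> objective: ", x$objective,
      "  J = ", signif(x$J, 6), "\n", sep = "")
  cat("  pattern [g]: ", paste(as.integer(x$best_pattern), collapse = " "),
      "\n  at [min]:    ",
      paste(attr(x$best_pattern, "slots"), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Tidy an optimization result
#'
#' @param x An `ogtt_pattern_opt`.
#' @param ... Unused.
#' @return A tibble with `time_min` and `grams` per slot.
#' @export
tidy.ogtt_pattern_opt <- function(x, ...) {
  tibble::tibble(time_min = attr(x$best_pattern, "slots"),
                 grams = as.integer(x$best_pattern))
}

#' @rdname tidy.ogtt_pattern_opt
#' @export
glance.ogtt_pattern_opt <- function(x, ...) {
  tibble::tibble(objective = x$objective, J = x$J,
                 J_search = x$J_search, trials = nrow(x$trials),
                 generations = x$settings$generations,
                 pop = x$settings$pop)
}

#' Plot an optimized ingestion pattern and its search trace
#'
#' @param object An `ogtt_pattern_opt`.
#' @param ... Unused.
#' @return A ggplot object (pattern bars; the per-generation trace is
#'   available via `x$trace`).
#' @export
autoplot.ogtt_pattern_opt <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_min, y = .data$grams)) +
    ggplot2::geom_col(fill = "#b2182b", width = 2) +
    ggplot2::labs(x = "ingestion time [min]", y = "dose [g]",
                  title = paste0(object$objective, ", J = ",
                                 signif(object$J, 5))) +
    ggplot2::theme_minimal()
}

#' Enumerate all feasible ingestion patterns (oracle)
#'
#' All nonnegative-integer slot assignments summing to `total` with at
#' least 1 g in the first slot, each exactly once. The count is the
#' stars-and-bars binomial `choose(total - 1 + n_slots - 1, n_slots - 1)`
#' (1 g is pinned to the first slot, the rest distributed freely). Intended
#' as a brute-force reference for small instances; guarded against large
#' ones.
#'
#' @param total Total grams.
#' @param n_slots Number of slots.
#' @param force Allow more than 1e6 patterns?
#' @return Integer matrix, one row per pattern.
#' @examples
#' enumerate_patterns(2, 2)   # (2,0) and (1,1)
#' @export
enumerate_patterns <- function(total, n_slots, force = FALSE) {
  stopifnot(total >= 1, n_slots >= 1)
  count <- pattern_count(total, n_slots)
  if (count > 1e6 && !force) {
    stop("instance too large (", format(count, big.mark = ","),
         " patterns); use force = TRUE if you mean it")
  }
  rest <- compositions(total - 1, n_slots)
  rest[, 1] <- rest[, 1] + 1L
  rest
}

# all weak compositions of `total` into `k` parts, one per row
compositions <- function(total, k) {
  if (k == 1) return(matrix(as.integer(total), nrow = 1))
  out <- vector("list", total + 1)
  for (first in 0:total) {
    sub <- compositions(total - first, k - 1)
    out[[first + 1]] <- cbind(as.integer(first), sub)
  }
  do.call(rbind, out)
}

#' Number of feasible ingestion patterns
#'
#' Computed by exact integer arithmetic (iterated multiply-then-divide, all
#' intermediates exact in double precision for the sizes involved). For the
#' standard instance (50 g over 13 slots, first slot >= 1) this is
#' `choose(61, 12)`; the closely related count `choose(62, 13)` =
#' 62!/(49!13!) arises when the 49 free grams are spread over 14 categories.
#'
#' @inheritParams enumerate_patterns
#' @return Numeric scalar (exact integer value).
#' @export
pattern_count <- function(total, n_slots) {
  exact_choose(total - 1 + n_slots - 1, n_slots - 1)
}

#' Exact binomial coefficient
#'
#' `choose(n, k)` by iterated exact multiply/divide: the partial products
#' are themselves binomial coefficients, so every intermediate is an exact
#' integer (valid while the result stays below 2^53).
#'
#' @param n,k Nonnegative integers, `k <= n`.
#' @return Numeric scalar holding the exact integer value.
#' @examples
#' exact_choose(62, 13)  # 8308281242850
#' @export
exact_choose <- function(n, k) {
  stopifnot(n >= 0, k >= 0, k <= n)
  k <- min(k, n - k)
  out <- 1
  for (i in seq_len(k)) {
    out <- out * (n - k + i) / i   # exact: out is C(n - k + i, i)
  }
  out
}
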