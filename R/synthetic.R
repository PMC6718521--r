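#' The six standard ingestion protocols
#'
#' Three doses (25, 50, 75 g) crossed with two delivery modes: bolus (a
#' single 0.5-min event) and 2-h continuous (a single 120-min event).
#' Conditions are labeled by dose and mode initial: `25B`, `25C`, `50B`,
#' `50C`, `75B`, `75C`.
#'
#' @return A tibble with columns `condition`, `dose` (g), `mode`,
#'   `duration` (min).
#' @export
standard_protocols <- function() {
  tibble::tibble(
    condition = c("25B", "25C", "50B", "50C", "75B", "75C"),
    dose = c(25, 25, 50, 50, 75, 75),
    mode = rep(c("bolus", "continuous"), 3),
    duration = rep(c(0.5, 120), 3)
  )
}

#' Schedule of one protocol condition
#'
#' @param condition Condition label, e.g. `"50B"`.
#' @param protocols A protocol table as from [standard_protocols()].
#' @return An [ingestion_schedule()].
#' @export
condition_schedule <- function(condition, protocols = standard_protocols()) {
  row <- protocols[protocols$condition == condition, ]
  if (nrow(row) != 1) stop("unknown condition: ", condition)
  ingestion_schedule(0, row$dose, row$duration)
}

#' Default sampling time grid for synthetic datasets
#'
#' Spans the 4-h post-ingestion window over which the measured species
#' return to baseline, denser early where dynamics are fast. A fixture
#' choice of this package, not a transcription of any clinical protocol.
#'
#' @return Numeric vector of times (min).
#' @export
default_sampling_grid <- function() {
  c(0, 10, 20, 30, 45, 60, 75, 90, 120, 150, 180, 240)
}

#' Bundled synthetic ground-truth subjects
#'
#' Three synthetic subjects with distinct incretin-coupling structures,
#' chosen to exercise the structure-selection machinery on realistic cases:
#' \describe{
#'   \item{`"A"`}{GLP-1-free with `a = 0` (insulin secretion depends on
#'     glucose and the glucose--GIP cooperative term only).}
#'   \item{`"B"`}{`b = c = 0` (independent GIP action plus
#'     glucose-cooperative GLP-1 action).}
#'   \item{`"C"`}{`a = c = d = 0` (glucose--GIP cooperative action only;
#'     GLP-1 circulates but does not drive secretion).}
#' }
#' Parameter values are fixture choices producing physiologically plausible
#' fasting levels and post-ingestion excursions (fasting glucose ~90 mg/dL
#' peaking ~150--170 under a 50-g bolus, insulin rising several-fold,
#' incretins peaking within ~30 min), not estimates from any real subject.
#'
#' @param id `"A"`, `"B"`, or `"C"` (or 1, 2, 3).
#' @return An [ogtt_subject()].
#' @export
fixture_subject <- function(id = c("A", "B", "C")) {
  if (is.numeric(id)) id <- c("A", "B", "C")[id]
  id <- match.arg(id)
  base_kin <- c(k2 = 5, k3 = 0.08, k4 = 1.2, k5 = 0.1, k6 = 1.1,
                k7 = 0.07, k8 = 6, k10 = 0.09, L2 = 10, L4 = 15, L6 = 8,
                L8 = 2, L11 = 600, V = 0.15)
  base_init <- c(GIP0 = 10, GLP10 = 5, G0 = 90, I0 = 40, CP0 = 500, X0 = 1)
  switch(
    id,
    A = ogtt_subject(
      kinetics = c(base_kin[setdiff(names(base_kin),
                                    c("k4", "k5", "L4"))], b = 0.03),
      init = base_init[setdiff(names(base_init), "GLP10")],
      structure = model_structure(a = FALSE, include_glp1 = FALSE),
      id = "A"
    ),
    B = ogtt_subject(
      kinetics = c(base_kin, a = 2, d = 0.05),
      init = base_init,
      structure = model_structure(b = FALSE, c = FALSE),
      id = "B"
    ),
    C = ogtt_subject(
      kinetics = c(base_kin, b = 0.025),
      init = base_init,
      structure = model_structure(a = FALSE, c = FALSE, d = FALSE),
      id = "C"
    )
  )
}

#' Generate a synthetic multi-protocol dataset for one subject
#'
#' Simulates every protocol condition from the subject's ground truth,
#' samples the five measured species at the time grid, and adds independent
#' Gaussian measurement noise with standard deviation
#' `noise * (max - min)` of each noise-free series, clipped at zero.
#' This emulates a six-condition ingestion study with normally distributed
#' residuals; it does not emulate assay-specific error structure, sensor
#' delays, or day-to-day physiological drift.
#'
#' @param subject An [ogtt_subject()] (the ground truth).
#' @param protocols Protocol table; default [standard_protocols()].
#' @param times Sampling grid (min); default [default_sampling_grid()].
#' @param noise Noise fraction of each series' range; scalar or named per
#'   species (`G`, `I`, `CP`, `GIP`, `GLP1`). Default 0.05.
#' @param seed RNG seed for reproducibility (`NULL` leaves the RNG state
#'   alone).
#' @param settings Solver settings used for the ground-truth simulation.
#' @return A long tibble with columns `subject_id`, `condition`, `species`,
#'   `time_min`, `value`, `included`.
#' @examples
#' ds <- generate_dataset(fixture_subject("A"), noise = 0, seed = 1)
#' dplyr::count(ds, condition)
#' @export
generate_dataset <- function(subject, protocols = standard_protocols(),
                             times = default_sampling_grid(), noise = 0.05,
                             seed = NULL,
                             settings = solver_settings("euler", step = 0.05,
                                                        horizon = max(times))) {
  stopifnot(inherits(subject, "ogtt_subject"), all(times >= 0),
            max(times) <= settings$horizon)
  species <- intersect(.species_names, state_names(subject$structure))
  if (any(noise < 0)) stop("noise fractions must be nonnegative")
  noise_of <- function(sp) {
    if (length(noise) == 1 && is.null(names(noise))) return(noise)
    if (!sp %in% names(noise)) stop("no noise fraction for species ", sp)
    noise[[sp]]
  }
  gen <- function() {
    purrr::map_dfr(protocols$condition, function(cond) {
      traj <- simulate_subject(subject, condition_schedule(cond, protocols),
                               settings, times = times)
      purrr::map_dfr(species, function(sp) {
        clean <- traj[[sp]]
        sd_sp <- noise_of(sp) * (max(clean) - min(clean))
        value <- pmax(0, clean + stats::rnorm(length(clean), 0, sd_sp))
        tibble::tibble(subject_id = subject$id %||% "subject",
                       condition = cond, species = sp, time_min = times,
                       value = value, included = TRUE)
      })
    })
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}
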