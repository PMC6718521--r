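#' Solver settings for trajectory simulation
#'
#' Two integrators are provided. `"euler"` is the fixed-step forward Euler
#' method used for objective evaluation in pattern optimization (default
#' step 0.01 min for search; 0.001 min is used for final reported values);
#' the step must divide every ingestion-event boundary so the integration
#' grid never straddles a flux discontinuity. `"adaptive"` is `deSolve`'s
#' `lsoda`, integrated segment-wise between event boundaries, used as an
#' independent cross-check and a faster fitting backend.
#'
#' @param method `"euler"` or `"adaptive"`.
#' @param step Euler step width (min).
#' @param horizon Simulation horizon T (min); default 480.
#' @param rtol,atol Tolerances for the adaptive solver.
#' @param floor_at_zero Clamp states at zero after each Euler step? Off by
#'   default so that stiffness artifacts are visible rather than hidden.
#' @return A list of class `ogtt_solver`.
#' @export
solver_settings <- function(method = c("euler", "adaptive"), step = 0.01,
                            horizon = 480, rtol = 1e-8, atol = 1e-8,
                            floor_at_zero = FALSE) {
  method <- match.arg(method)
  stopifnot(step > 0, horizon > 0)
  structure(list(method = method, step = step, horizon = horizon,
                 rtol = rtol, atol = atol, floor_at_zero = floor_at_zero),
            class = "ogtt_solver")
}

#' Simulate a subject's response to an ingestion schedule
#'
#' Integrates the ODE system from the subject's (steady-state-closed)
#' initial levels under the given schedule, and returns the trajectory as a
#' tibble, one row per output time and one column per state variable.
#'
#' @param subject An [ogtt_subject()].
#' @param schedule An [ingestion_schedule()] (may be empty:
#'   `ingestion_schedule(numeric(0), numeric(0))`).
#' @param settings A [solver_settings()].
#' @param times Output times (min); default a uniform grid of at most ~5000
#'   points over `[0, horizon]` aligned to the Euler step.
#' @return A tibble of class `ogtt_trajectory` with column `time` and one
#'   column per state, plus attributes `schedule`, `settings`, `subject_id`.
#' @examples
#' subj <- fixture_subject("B")
#' traj <- simulate_subject(subj, bolus_schedule(50),
#'                          solver_settings(step = 0.05, horizon = 240))
#' peak_value(traj, "G")
#' @export
simulate_subject <- function(subject, schedule,
                             settings = solver_settings(), times = NULL) {
  stopifnot(inherits(subject, "ogtt_subject"),
            inherits(schedule, "ogtt_schedule"),
            inherits(settings, "ogtt_solver"))
  if (is.null(times)) {
    by <- max(settings$step, settings$horizon / 4800)
    by <- settings$step * max(1, round(by / settings$step))
    times <- seq(0, settings$horizon, by = by)
    if (times[length(times)] < settings$horizon) {
      times <- c(times, settings$horizon)
    }
  }
  times <- sort(unique(as.numeric(times)))
  if (times[1] < 0 || times[length(times)] > settings$horizon + 1e-9) {
    stop("output times must lie within [0, horizon]")
  }
  p <- full_param_vector(subject)
  y0 <- initial_state_vector(subject)
  ev <- schedule_events(schedule)
  if (nrow(ev) > 0 && max(ev[, "end"]) > settings$horizon) {
    stop("schedule extends beyond the simulation horizon")
  }

  if (settings$method == "euler") {
    check_event_alignment(ev, settings$step)
    m <- cpp_euler_traj(p, y0, ev, settings$step, settings$horizon,
                        times, settings$floor_at_zero)
  } else {
    m <- lsoda_traj(p, y0, ev, times, settings)
  }
  colnames(m) <- .state_names_8
  keep <- state_names(subject$structure)
  out <- tibble::as_tibble(as.data.frame(m[, keep, drop = FALSE]))
  out <- dplyr::bind_cols(tibble::tibble(time = times), out)
  if (any(!is.finite(as.matrix(out)))) {
    stop("non-finite values in simulated trajectory")
  }
  attr(out, "schedule") <- schedule
  attr(out, "settings") <- settings
  attr(out, "subject_id") <- subject$id
  class(out) <- c("ogtt_trajectory", class(out))
  out
}

check_event_alignment <- function(ev, step) {
  if (nrow(ev) == 0) return(invisible(TRUE))
  b <- c(ev[, "start"], ev[, "end"]) / step
  if (any(abs(b - round(b)) > 1e-6)) {
    stop("Euler step must divide every ingestion event boundary ",
         "(step = ", step, ")")
  }
  invisible(TRUE)
}

# segment-wise lsoda between flux discontinuities
lsoda_traj <- function(p, y0, ev, times, settings) {
  bounds <- sort(unique(c(0, settings$horizon,
                          ev[, "start"], ev[, "end"])))
  bounds <- bounds[bounds <= settings$horizon + 1e-12]
  deriv <- function(t, y, parms) {
    dy <- numeric(8)
    IntestG <- y[1]; GIP <- y[2]; GLP1 <- y[3]; AG <- y[4]
    G <- y[5]; I <- y[6]; CP <- y[7]; X <- y[8]
    v2 <- p[["k2"]] * IntestG / (p[["L2"]] + IntestG)
    v3 <- p[["k3"]] * (p[["GIP_B"]] - GIP)
    v4 <- p[["k4"]] * IntestG / (p[["L4"]] + IntestG)
    v5 <- p[["k5"]] * (p[["GLP1_B"]] - GLP1)
    v6 <- p[["k6"]] * IntestG / (p[["L6"]] + IntestG)
    v7 <- p[["k7"]] * AG
    v8 <- p[["k8"]] / (p[["L8"]] + X)
    v9 <- p[["k9"]] * G * X
    v10 <- p[["k10"]] * (G + p[["a"]] * GIP + p[["b"]] * G * GIP +
                           p[["c"]] * GLP1 + p[["d"]] * G * GLP1)
    v11 <- p[["k11"]] * I / (p[["L11"]] + I)
    v12 <- p[["k12"]] * CP
    v13 <- p[["k13"]] * X
    dy[1] <- parms - v6
    dy[2] <- v2 + v3
    dy[3] <- v4 + v5
    dy[4] <- v6 - v7
    dy[5] <- v7 / p[["V"]] + v8 - v9
    dy[6] <- v10 - v11
    dy[7] <- v10 - v12
    dy[8] <- v11 / p[["k11"]] - v13
    list(dy)
  }
  out <- matrix(NA_real_, nrow = length(times), ncol = 8)
  y <- y0
  for (s in seq_len(length(bounds) - 1)) {
    t0 <- bounds[s]; t1 <- bounds[s + 1]
    flux <- 0
    hit <- ev[, "start"] <= t0 + 1e-12 & ev[, "end"] > t0 + 1e-12
    if (any(hit)) flux <- ev[hit, "rate"][1]
    inside <- which(times > t0 + 1e-12 & times <= t1 + 1e-12)
    seg_times <- sort(unique(c(t0, times[inside], t1)))
    sol <- deSolve::lsoda(y, seg_times, deriv, parms = flux,
                          rtol = settings$rtol, atol = settings$atol)
    if (length(inside) > 0) {
      idx <- match(round(times[inside], 10), round(sol[, 1], 10))
      out[inside, ] <- as.matrix(sol[idx, -1, drop = FALSE])
    }
    y <- as.numeric(sol[nrow(sol), -1])
  }
  at0 <- which(times <= 1e-12)
  if (length(at0) > 0) out[at0, ] <- matrix(rep(y0, each = length(at0)),
                                            nrow = length(at0))
  out
}

#' Sample a trajectory at arbitrary times
#'
#' Linear interpolation between stored grid points; exact at grid points.
#'
#' @param traj An `ogtt_trajectory`.
#' @param times Times (min) within the stored range.
#' @param species State name(s) to sample (see [state_names()]).
#' @return If one species, a numeric vector; otherwise a tibble with a
#'   `time` column and one column per species.
#' @export
sample_at <- function(traj, times, species = "G") {
  stopifnot(inherits(traj, "ogtt_trajectory"))
  bad <- setdiff(species, names(traj))
  if (length(bad) > 0) {
    stop("unknown species: ", paste(bad, collapse = ", "))
  }
  tr <- range(traj$time)
  if (any(times < tr[1] - 1e-9 | times > tr[2] + 1e-9)) {
    stop("sampling times outside the stored trajectory range [",
         tr[1], ", ", tr[2], "]")
  }
  vals <- lapply(species, function(sp) {
    stats::approx(traj$time, traj[[sp]], xout = times, rule = 1)$y
  })
  if (length(species) == 1) return(vals[[1]])
  out <- tibble::tibble(time = times)
  for (i in seq_along(species)) out[[species[i]]] <- vals[[i]]
  out
}

#' Peak value of a trajectory
#'
#' Maximum of the stored trajectory of blood glucose (`"G"`, mg/dL) or
#' insulin (`"I"`, pM) over the simulated horizon. These are the objective
#' values \eqn{G_{Max}} and \eqn{I_{Max}} of the pattern-design problem.
#'
#' @param traj An `ogtt_trajectory`.
#' @param species `"G"` or `"I"`.
#' @return Numeric scalar.
#' @export
peak_value <- function(traj, species = c("G", "I")) {
  species <- match.arg(species)
  stopifnot(inherits(traj, "ogtt_trajectory"))
  max(traj[[species]])
}

#' Export a trajectory to CSV
#'
#' Columns `time_min` then one column per state variable.
#'
#' @param traj An `ogtt_trajectory`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "ogtt_trajectory"))
  out <- as.data.frame(traj)
  names(out)[names(out) == "time"] <- "time_min"
  readr::write_csv(out, path)
  invisible(path)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a simulated trajectory
#'
#' One facet per state variable over time.
#'
#' @param object An `ogtt_trajectory`.
#' @param species Which states to show; default all measured species.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ogtt_trajectory <- function(object,
                                     species = intersect(.species_names,
                                                         names(object)),
                                     ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(object),
                  dplyr::all_of(c("time", species))),
    -"time", names_to = "species", values_to = "value")
  long$species <- factor(long$species, levels = species)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(color = "#2166ac") +
    ggplot2::facet_wrap(~species, scales = "free_y") +
    ggplot2::labs(x = "time [min]", y = NULL) +
    ggplot2::theme_minimal()
}
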