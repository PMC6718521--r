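#' Evaluate the thirteen model fluxes at a state
#'
#' Pure-R reference implementation of the flux layer, mirrored by the
#' compiled integrator. The fluxes are:
#' `v1` ingestion influx (g/min); `v2`, `v4` Michaelis--Menten incretin
#' secretion driven by intestinal glucose; `v3`, `v5` relaxation of GIP and
#' GLP-1 toward their basal levels (signed); `v6` Michaelis--Menten gut
#' absorption; `v7` appearance of absorbed glucose in blood; `v8` hepatic
#' glucose production, inhibited by effective insulin `X`; `v9` = `k9*G*X`
#' insulin-dependent glucose uptake; `v10` insulin/C-peptide secretion
#' `k10*(G + a*GIP + b*G*GIP + c*GLP1 + d*G*GLP1)`; `v11` Michaelis--Menten
#' insulin transfer to target organs; `v12` = `k12*CP` C-peptide clearance;
#' `v13` = `k13*X` effective-insulin turnover.
#'
#' @param state Named numeric vector of state values (see [state_names()];
#'   the `GLP1` entry may be absent for GLP-1-free subjects).
#' @param subject An [ogtt_subject()].
#' @param glucose_flux Ingestion flux `v1` (g/min).
#' @return Named numeric vector `v1` ... `v13`.
#' @export
flux_vector <- function(state, subject, glucose_flux = 0) {
  stopifnot(inherits(subject, "ogtt_subject"))
  p <- full_param_vector(subject)
  GLP1 <- if ("GLP1" %in% names(state)) state[["GLP1"]] else 0
  IntestG <- state[["Intest_G"]]; GIP <- state[["GIP"]]
  AG <- state[["A_GutG"]]; G <- state[["G"]]; I <- state[["I"]]
  CP <- state[["CP"]]; X <- state[["X"]]
  c(v1 = glucose_flux,
    v2 = p[["k2"]] * IntestG / (p[["L2"]] + IntestG),
    v3 = p[["k3"]] * (p[["GIP_B"]] - GIP),
    v4 = p[["k4"]] * IntestG / (p[["L4"]] + IntestG),
    v5 = p[["k5"]] * (p[["GLP1_B"]] - GLP1),
    v6 = p[["k6"]] * IntestG / (p[["L6"]] + IntestG),
    v7 = p[["k7"]] * AG,
    v8 = p[["k8"]] / (p[["L8"]] + X),
    v9 = p[["k9"]] * G * X,
    v10 = p[["k10"]] * (G + p[["a"]] * GIP + p[["b"]] * G * GIP +
                          p[["c"]] * GLP1 + p[["d"]] * G * GLP1),
    v11 = p[["k11"]] * I / (p[["L11"]] + I),
    v12 = p[["k12"]] * CP,
    v13 = p[["k13"]] * X)
}

#' Right-hand side of the glucose--insulin--incretin ODE system
#'
#' Assembles the state derivatives from the fluxes:
#' \deqn{dIntest_G/dt = v_1 - v_6,\quad dGIP/dt = v_2 + v_3,\quad
#'       dGLP1/dt = v_4 + v_5,}
#' \deqn{dA_{GutG}/dt = v_6 - v_7,\quad dG/dt = v_7/V + v_8 - v_9,}
#' \deqn{dI/dt = v_{10} - v_{11},\quad dCP/dt = v_{10} - v_{12},\quad
#'       dX/dt = v_{11}/k_{11} - v_{13}.}
#' For GLP-1-free subjects the GLP1 row is absent and the returned vector
#' has 7 components.
#'
#' @inheritParams flux_vector
#' @return Named numeric vector of derivatives, ordered as [state_names()].
#' @export
model_rhs <- function(state, subject, glucose_flux = 0) {
  v <- flux_vector(state, subject, glucose_flux)
  p <- full_param_vector(subject)
  out <- c(Intest_G = v[["v1"]] - v[["v6"]],
           GIP = v[["v2"]] + v[["v3"]],
           GLP1 = v[["v4"]] + v[["v5"]],
           A_GutG = v[["v6"]] - v[["v7"]],
           G = v[["v7"]] / p[["V"]] + v[["v8"]] - v[["v9"]],
           I = v[["v10"]] - v[["v11"]],
           CP = v[["v10"]] - v[["v12"]],
           X = v[["v11"]] / p[["k11"]] - v[["v13"]])
  out[state_names(subject$structure)]
}
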