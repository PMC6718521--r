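#' @keywords internal
"_PACKAGE"

#' @importFrom Rcpp sourceCpp
#' @useDynLib ogttdesign, .registration = TRUE
NULL

# state ordering used throughout (the compiled core always carries 8 slots;
# GLP-1-free subjects keep the GLP1 slot identically zero and hide it)
.state_names_8 <- c("Intest_G", "GIP", "GLP1", "A_GutG", "G", "I", "CP", "X")
.species_names <- c("G", "I", "CP", "GIP", "GLP1")
.full_param_names <- c("k2", "k3", "k4", "k5", "k6", "k7", "k8", "k9",
                       "k10", "k11", "k12", "k13", "L2", "L4", "L6", "L8",
                       "L11", "V", "a", "b", "c", "d", "GIP_B", "GLP1_B")

#' State variable names of a model structure
#'
#' @inheritParams structure_label
#' @return Character vector: 8 states for GLP-1-containing structures
#'   (`Intest_G`, `GIP`, `GLP1`, `A_GutG`, `G`, `I`, `CP`, `X`), 7 for
#'   GLP-1-free ones.
#' @export
state_names <- function(structure) {
  stopifnot(inherits(structure, "ogtt_structure"))
  if (structure$include_glp1) .state_names_8 else setdiff(.state_names_8, "GLP1")
}

#' Derive the steady-state-closed parameters
#'
#' The pre-ingestion state is assumed stationary: with zero ingestion flux
#' every state derivative vanishes at the initial levels. That constraint
#' determines four rate constants and the two basal incretin levels from the
#' free parameters:
#' \deqn{k_9 = k_8 / (G(0)\,X(0)\,(X(0)+L_8)),}
#' \deqn{k_{11} = k_{10}\,\frac{L_{11}+I(0)}{I(0)}\,S_0, \quad
#'       k_{12} = \frac{k_{10}}{CP(0)}\,S_0, \quad
#'       k_{13} = \frac{I(0)}{(I(0)+L_{11})\,X(0)},}
#' \deqn{GIP_B = GIP(0), \quad GLP1_B = GLP1(0),}
#' where \eqn{S_0 = G(0) + a\,GIP(0) + b\,G(0)GIP(0) + c\,GLP1(0) +
#' d\,G(0)GLP1(0)} is the basal secretion drive. For GLP-1-free structures
#' all GLP-1 contributions are zero.
#'
#' @param kinetics Named numeric vector of free kinetic parameters (see
#'   [kinetic_names()]); fixed coefficients may be omitted.
#' @param init Named numeric vector of initial levels (see
#'   [initial_names()]).
#' @inheritParams structure_label
#' @return Named numeric vector `k9`, `k11`, `k12`, `k13`, `GIP_B`, `GLP1_B`.
#' @examples
#' s <- model_structure(a = FALSE, b = FALSE, c = FALSE, d = FALSE)
#' kin <- c(k2 = 1, k3 = 1, k4 = 1, k5 = 1, k6 = 1, k7 = 1, k8 = 1,
#'          k10 = 1, L2 = 1, L4 = 1, L6 = 1, L8 = 3, L11 = 1, V = 1)
#' close_parameters(kin, c(GIP0 = 1, GLP10 = 1, G0 = 2, I0 = 1, CP0 = 1,
#'                         X0 = 1), s)["k9"]  # 1 / (2 * 1 * 4) = 0.125
#' @export
close_parameters <- function(kinetics, init, structure) {
  stopifnot(inherits(structure, "ogtt_structure"))
  need <- setdiff(kinetic_names(structure), c("a", "b", "c", "d"))
  missing_k <- setdiff(need, names(kinetics))
  if (length(missing_k) > 0) {
    stop("missing kinetic parameters: ", paste(missing_k, collapse = ", "))
  }
  missing_i <- setdiff(initial_names(structure), names(init))
  if (length(missing_i) > 0) {
    stop("missing initial levels: ", paste(missing_i, collapse = ", "))
  }
  for (nm in c("G0", "X0", "I0", "CP0", "GIP0",
               if (structure$include_glp1) "GLP10")) {
    if (!is.finite(init[[nm]]) || init[[nm]] <= 0) {
      stop("closure requires strictly positive ", nm,
           " (got ", init[[nm]], ")")
    }
  }
  bad <- need[!is.finite(kinetics[need]) | kinetics[need] <= 0]
  if (length(bad) > 0) {
    stop("kinetic parameters must be strictly positive: ",
         paste(bad, collapse = ", "))
  }

  cf <- coefficient_values(kinetics, structure)
  GLP10 <- if (structure$include_glp1) init[["GLP10"]] else 0
  G0 <- init[["G0"]]; I0 <- init[["I0"]]; CP0 <- init[["CP0"]]
  X0 <- init[["X0"]]; GIP0 <- init[["GIP0"]]
  S0 <- G0 + cf[["a"]] * GIP0 + cf[["b"]] * G0 * GIP0 +
    cf[["c"]] * GLP10 + cf[["d"]] * G0 * GLP10
  k8 <- kinetics[["k8"]]; k10 <- kinetics[["k10"]]
  L8 <- kinetics[["L8"]]; L11 <- kinetics[["L11"]]
  c(k9 = k8 / (G0 * X0 * (X0 + L8)),
    k11 = k10 * (L11 + I0) / I0 * S0,
    k12 = k10 / CP0 * S0,
    k13 = I0 / ((I0 + L11) * X0),
    GIP_B = GIP0,
    GLP1_B = GLP10)
}

# resolve a, b, c, d for a structure: free ones must be supplied (and
# positive); fixed ones are exactly 0 regardless of what was passed
coefficient_values <- function(kinetics, structure) {
  free <- c(a = structure$a_free, b = structure$b_free,
            c = structure$c_free, d = structure$d_free)
  out <- c(a = 0, b = 0, c = 0, d = 0)
  for (nm in names(free)[free]) {
    if (!nm %in% names(kinetics)) {
      stop("coefficient ", nm, " is free in this structure but not supplied")
    }
    if (!is.finite(kinetics[[nm]]) || kinetics[[nm]] <= 0) {
      stop("free coefficient ", nm, " must be strictly positive")
    }
    out[[nm]] <- kinetics[[nm]]
  }
  out
}

#' Construct a subject model (free parameters + steady-state closure)
#'
#' Bundles a model structure, its free kinetic parameters and initial levels,
#' and the derived (closed) parameters into one object ready for simulation.
#' Coefficients fixed at zero by the structure are forced to exactly zero,
#' so supplying a value for a masked coefficient has no effect.
#'
#' @inheritParams close_parameters
#' @param id Optional subject identifier (string).
#' @return An object of class `ogtt_subject` with fields `id`, `structure`,
#'   `kinetics`, `init`, `derived`.
#' @seealso [close_parameters()], [fixture_subject()], [simulate_subject()]
#' @export
ogtt_subject <- function(kinetics, init, structure = model_structure(),
                         id = NULL) {
  derived <- close_parameters(kinetics, init, structure)
  cf <- coefficient_values(kinetics, structure)
  keep_cf <- c("a", "b", "c", "d")[c(structure$a_free, structure$b_free,
                                     structure$c_free, structure$d_free)]
  kin <- c(kinetics[setdiff(kinetic_names(structure), c("a", "b", "c", "d"))],
           cf[keep_cf])
  init <- init[initial_names(structure)]
  out <- list(id = id, structure = structure, kinetics = kin, init = init,
              derived = derived)
  class(out) <- "ogtt_subject"
  out
}

#' @export
print.ogtt_subject <- function(x, ...) {
  cat("<ogtt_subject>", if (!is.null(x$id)) x$id else "",
      " structure: ", structure_label(x$structure), "\n", sep = "")
  cat("  kinetics: ", paste0(names(x$kinetics), "=",
                             signif(x$kinetics, 3), collapse = ", "), "\n")
  cat("  initial:  ", paste0(names(x$init), "=",
                             signif(x$init, 3), collapse = ", "), "\n")
  invisible(x)
}

# 24-slot closed parameter vector in the compiled core's ordering
full_param_vector <- function(subject) {
  stopifnot(inherits(subject, "ogtt_subject"))
  kin <- subject$kinetics
  drv <- subject$derived
  g <- function(nm) if (nm %in% names(kin)) kin[[nm]] else 0
  cf <- coefficient_values(kin, subject$structure)
  # L4 = 1 keeps the dormant GLP-1 Michaelis term well-defined (k4 = 0
  # already makes the flux vanish; 0/0 at Intest_G = 0 would not)
  L4 <- if ("L4" %in% names(kin)) kin[["L4"]] else 1
  out <- c(g("k2"), g("k3"), g("k4"), g("k5"), g("k6"), g("k7"), g("k8"),
           drv[["k9"]], g("k10"), drv[["k11"]], drv[["k12"]], drv[["k13"]],
           g("L2"), L4, g("L6"), g("L8"), g("L11"), g("V"),
           cf[["a"]], cf[["b"]], cf[["c"]], cf[["d"]],
           drv[["GIP_B"]], drv[["GLP1_B"]])
  names(out) <- .full_param_names
  out
}

# 8-slot initial state (Intest_G = A_GutG = 0; GLP1 slot 0 when absent)
initial_state_vector <- function(subject) {
  init <- subject$init
  GLP10 <- if (subject$structure$include_glp1) init[["GLP10"]] else 0
  out <- c(0, init[["GIP0"]], GLP10, 0, init[["G0"]], init[["I0"]],
           init[["CP0"]], init[["X0"]])
  names(out) <- .state_names_8
  out
}

#' Serialize a subject model to JSON
#'
#' Writes structure flags, free kinetic parameters, initial levels and the
#' derived parameters under their symbol names, so a subject can be stored
#' alongside fit outputs and re-loaded exactly.
#'
#' @param subject An [ogtt_subject()].
#' @param path File path to write.
#' @return `path`, invisibly.
#' @export
write_subject_json <- function(subject, path) {
  stopifnot(inherits(subject, "ogtt_subject"))
  doc <- list(
    id = subject$id,
    structure = subject$structure[c("a_free", "b_free", "c_free", "d_free",
                                    "include_glp1")],
    kinetics = as.list(subject$kinetics),
    init = as.list(subject$init),
    derived = as.list(subject$derived)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a subject model from JSON
#'
#' @param path File written by [write_subject_json()].
#' @return An [ogtt_subject()] (derived parameters are re-closed, not
#'   trusted from the file).
#' @export
read_subject_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  st <- model_structure(a = doc$structure$a_free, b = doc$structure$b_free,
                        c = doc$structure$c_free, d = doc$structure$d_free,
                        include_glp1 = doc$structure$include_glp1)
  ogtt_subject(kinetics = unlist(doc$kinetics), init = unlist(doc$init),
               structure = st, id = doc$id)
}
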