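#' Define an incretin-coupling model structure
#'
#' The insulin/C-peptide secretion flux is
#' \deqn{v_{10} = k_{10}(G + a\,GIP + b\,G\,GIP + c\,GLP1 + d\,G\,GLP1),}
#' where the four coupling coefficients encode independent (\eqn{a}, \eqn{c})
#' and glucose-cooperative (\eqn{b}, \eqn{d}) incretin actions. A model
#' structure declares which coefficients are estimated and which are fixed at
#' zero, and whether the GLP-1 state equation is present at all. Removing
#' GLP-1 removes the state structurally (a 7-state system) together with its
#' parameters \eqn{k_4}, \eqn{k_5}, \eqn{L_4}, the initial level
#' \eqn{GLP1(0)}, and forces \eqn{c = d = 0}.
#'
#' @param a,b,c,d Logical; is the coefficient free (estimated) or fixed at 0?
#' @param include_glp1 Logical; keep the GLP-1 state equation? When `FALSE`,
#'   `c` and `d` are forced to `FALSE`.
#' @return An object of class `ogtt_structure`, a named list with fields
#'   `a_free`, `b_free`, `c_free`, `d_free`, `include_glp1`.
#' @examples
#' model_structure()                       # full model
#' model_structure(c = FALSE, d = FALSE)   # GIP-only coupling, c = d = 0
#' model_structure(a = FALSE, include_glp1 = FALSE)
#' @export
model_structure <- function(a = TRUE, b = TRUE, c = TRUE, d = TRUE,
                            include_glp1 = TRUE) {
  stopifnot(is.logical(a), is.logical(b), is.logical(c), is.logical(d),
            is.logical(include_glp1))
  if (!include_glp1) {
    c <- FALSE
    d <- FALSE
  }
  structure(
    list(a_free = a, b_free = b, c_free = c, d_free = d,
         include_glp1 = include_glp1),
    class = "ogtt_structure"
  )
}

#' @export
print.ogtt_structure <- function(x, ...) {
  cat("<ogtt_structure> ", structure_label(x), "\n", sep = "")
  cat("  free kinetic parameters: ", length(kinetic_names(x)),
      "; free initial levels: ", length(initial_names(x)),
      "; K = ", n_free_parameters(x), "\n", sep = "")
  invisible(x)
}

#' Canonical label of a model structure
#'
#' Labels follow the convention of naming the zeroed coefficients, e.g.
#' `"b=c=0"`, with a `"GLP1-free"` prefix for structures without the GLP-1
#' state. The model with all four coefficients free is `"full"`.
#'
#' @param structure An [model_structure()] object.
#' @return A single string.
#' @export
structure_label <- function(structure) {
  stopifnot(inherits(structure, "ogtt_structure"))
  if (structure$include_glp1) {
    zeroed <- c("a", "b", "c", "d")[!c(structure$a_free, structure$b_free,
                                       structure$c_free, structure$d_free)]
    if (length(zeroed) == 0) return("full")
    paste0(paste(zeroed, collapse = "="), "=0")
  } else {
    zeroed <- c("a", "b")[!c(structure$a_free, structure$b_free)]
    if (length(zeroed) == 0) return("GLP1-free")
    paste0("GLP1-free, ", paste(zeroed, collapse = "="), "=0")
  }
}

#' Names of the free kinetic parameters of a structure
#'
#' The full model estimates 18 kinetic parameters: \eqn{k_2, k_3, k_4, k_5,
#' k_6, k_7, k_8, k_{10}}, \eqn{L_2, L_4, L_6, L_8, L_{11}}, \eqn{V}, and the
#' coefficients \eqn{a, b, c, d}. Fixing a coefficient removes it; removing
#' GLP-1 additionally removes \eqn{k_4, k_5, L_4}.
#'
#' @inheritParams structure_label
#' @return Character vector of parameter names.
#' @export
kinetic_names <- function(structure) {
  stopifnot(inherits(structure, "ogtt_structure"))
  base <- c("k2", "k3", "k4", "k5", "k6", "k7", "k8", "k10",
            "L2", "L4", "L6", "L8", "L11", "V")
  if (!structure$include_glp1) base <- setdiff(base, c("k4", "k5", "L4"))
  coefs <- c("a", "b", "c", "d")[c(structure$a_free, structure$b_free,
                                   structure$c_free, structure$d_free)]
  c(base, coefs)
}

#' Names of the free initial levels of a structure
#'
#' Six initial levels are estimated in the full model: \eqn{GIP(0)},
#' \eqn{GLP1(0)}, \eqn{G(0)}, \eqn{I(0)}, \eqn{CP(0)}, \eqn{X(0)}. GLP-1-free
#' structures drop \eqn{GLP1(0)}.
#'
#' @inheritParams structure_label
#' @return Character vector of initial-level names.
#' @export
initial_names <- function(structure) {
  stopifnot(inherits(structure, "ogtt_structure"))
  nm <- c("GIP0", "GLP10", "G0", "I0", "CP0", "X0")
  if (!structure$include_glp1) nm <- setdiff(nm, "GLP10")
  nm
}

#' Number of estimated quantities K of a structure
#'
#' Counts free kinetic parameters plus free initial levels; this is the K
#' entering the AIC penalty. The full model has 18 + 6 = 24.
#'
#' @inheritParams structure_label
#' @return Integer count.
#' @export
n_free_parameters <- function(structure) {
  length(kinetic_names(structure)) + length(initial_names(structure))
}

#' Enumerate candidate model structures for selection
#'
#' All \eqn{2^4 = 16} on/off combinations of the coupling coefficients
#' \eqn{a, b, c, d}, optionally extended with the four structurally
#' GLP-1-free variants (combinations of \eqn{a, b}). This enumeration is a
#' systematic reconstruction of the candidate family implied by the secretion
#' flux, not a transcription of any particular published candidate table.
#'
#' @param include_glp1_free Also enumerate the four GLP-1-free variants?
#' @return A tibble with columns `label`, `K`, and a list-column `structure`.
#' @examples
#' enumerate_candidates()          # 20 candidates
#' enumerate_candidates(FALSE)     # 16 candidates
#' @export
enumerate_candidates <- function(include_glp1_free = TRUE) {
  grid <- expand.grid(a = c(TRUE, FALSE), b = c(TRUE, FALSE),
                      c = c(TRUE, FALSE), d = c(TRUE, FALSE))
  structs <- purrr::pmap(grid, function(a, b, c, d) {
    model_structure(a = a, b = b, c = c, d = d, include_glp1 = TRUE)
  })
  if (include_glp1_free) {
    grid2 <- expand.grid(a = c(TRUE, FALSE), b = c(TRUE, FALSE))
    structs <- c(structs, purrr::pmap(grid2, function(a, b) {
      model_structure(a = a, b = b, include_glp1 = FALSE)
    }))
  }
  tibble::tibble(
    label = purrr::map_chr(structs, structure_label),
    K = purrr::map_int(structs, n_free_parameters),
    structure = structs
  )
}
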