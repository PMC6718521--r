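#' Akaike Information Criterion for a fitted candidate
#'
#' With normally distributed residuals and a common number of data points N
#' across the candidates, model fit can be compared by
#' \deqn{AIC = N \log(RSS) + 2K,} where K counts every estimated quantity
#' (free kinetic parameters plus free initial levels) and the logarithm is
#' natural.
#'
#' @param rss_value Normalized residual sum of squares (> 0).
#' @param n_data Total number of data points N.
#' @param k_params Number of estimated quantities K.
#' @return Numeric scalar. A zero RSS (an exact interpolation) yields
#'   `-Inf` with a warning.
#' @examples
#' aic_score(1, 100, 5)        # 10
#' aic_score(exp(2), 10, 0)    # 20
#' @export
aic_score <- function(rss_value, n_data, k_params) {
  stopifnot(length(rss_value) == 1, is.finite(n_data), n_data >= 0,
            is.finite(k_params), k_params >= 0,
            abs(n_data - round(n_data)) < 1e-9,
            abs(k_params - round(k_params)) < 1e-9)
  if (!is.finite(rss_value) || rss_value < 0) {
    stop("rss_value must be a nonnegative finite number")
  }
  if (rss_value == 0) {
    warning("RSS is exactly zero; AIC reported as -Inf")
    return(-Inf)
  }
  n_data * log(rss_value) + 2 * k_params
}

#' Fit candidate structures and select the best by AIC
#'
#' Every candidate is fitted to the identical dataset with the same
#' settings; AIC is computed with N equal to the number of included data
#' points the candidate's model can describe. Mixing GLP-1-containing and
#' GLP-1-free candidates on a dataset with GLP-1 measurements makes N
#' differ (GLP-1-free models cannot simulate the GLP-1 series), in which
#' case a warning is raised: AIC is then comparable only within each
#' family, matching the practice of running the GLP-1-free comparison as
#' its own selection round.
#'
#' Ties in AIC are broken by smaller K, then by candidate order; the
#' applied tie-break is recorded.
#'
#' @inheritParams ep_global_search
#' @param candidates Candidate tibble from [enumerate_candidates()] (or any
#'   tibble with `label` and list-column `structure`).
#' @param warm_start Use lattice warm-starting (default)? The richest
#'   structures (the full model, and the full GLP-1-free variant if
#'   present) are fitted with the complete global pipeline; every nested
#'   candidate is then refined by Levenberg--Marquardt from the solutions
#'   of its already-fitted supersets. For the candidates that matter in the
#'   AIC comparison -- those whose zeroed coefficients are near zero in the
#'   richer fit -- the warm start lands essentially at their optimum, which
#'   is exactly the accuracy AIC's 2-per-parameter penalty requires.
#'   `FALSE` fits every candidate independently with identical settings
#'   (much slower at equal quality).
#' @return An object of class `ogtt_selection`: `table` (per-candidate
#'   label, K, rss, n, aic, error), `selected` (label), `selected_fit`
#'   (the winning `ogtt_fit`), `tie_break` (string or `NA`).
#' @export
select_model <- function(dataset, candidates = enumerate_candidates(),
                         settings = fit_settings(),
                         protocols = standard_protocols(),
                         warm_start = TRUE) {
  stopifnot(all(c("label", "structure") %in% names(candidates)))
  fits <- if (warm_start) {
    lattice_fits(dataset, candidates, settings, protocols)
  } else {
    purrr::map(candidates$structure, function(st) {
      tryCatch(fit_subject(dataset, st, settings, protocols),
               error = function(e) e)
    })
  }
  table <- purrr::map2_dfr(candidates$label, fits, function(lab, f) {
    if (inherits(f, "error")) {
      return(tibble::tibble(label = lab, K = NA_integer_, rss = NA_real_,
                            n = NA_integer_, aic = NA_real_,
                            error = conditionMessage(f)))
    }
    k <- n_free_parameters(f$structure)
    tibble::tibble(label = lab, K = k, rss = f$best_rss, n = f$n_obs,
                   aic = suppressWarnings(aic_score(f$best_rss, f$n_obs, k)),
                   error = NA_character_)
  })
  if (all(is.na(table$aic))) stop("every candidate fit failed")
  if (length(unique(stats::na.omit(table$n))) > 1) {
    warning("candidates use different numbers of data points N; ",
            "AIC is only comparable within a family")
  }
  ord <- order(table$aic, table$K, seq_len(nrow(table)), na.last = TRUE)
  sel <- ord[1]
  tie <- NA_character_
  ties <- which(table$aic == table$aic[sel])
  if (length(ties) > 1) {
    tie <- paste0("AIC tie among {",
                  paste(table$label[ties], collapse = ", "),
                  "}; broke by smaller K, then order")
  }
  out <- list(table = table, selected = table$label[sel],
              selected_fit = fits[[sel]], tie_break = tie)
  class(out) <- "ogtt_selection"
  out
}

# free-coefficient signature of a structure (for the nesting lattice)
free_coefs <- function(st) {
  c("a", "b", "c", "d")[c(st$a_free, st$b_free, st$c_free, st$d_free)]
}

# Fit candidates over the nesting lattice: roots (maximal free sets per
# GLP-1 family) get the full global pipeline; children are LM-refined from
# every already-fitted superset's solution.
lattice_fits <- function(dataset, candidates, settings, protocols) {
  n <- nrow(candidates)
  fits <- vector("list", n)
  ok_struct <- vapply(candidates$structure,
                      function(s) inherits(s, "ogtt_structure"), logical(1))
  ord <- order(-vapply(seq_len(n), function(i) {
    if (ok_struct[i]) n_free_parameters(candidates$structure[[i]]) else 0L
  }, numeric(1)))
  for (i in ord) {
    fits[[i]] <- tryCatch({
      st <- candidates$structure[[i]]
      if (!inherits(st, "ogtt_structure")) stop("not a model structure")
      fc <- free_coefs(st)
      sup_idx <- Filter(function(j) {
        j != i && ok_struct[j] && !inherits(fits[[j]], "error") &&
          !is.null(fits[[j]]) &&
          candidates$structure[[j]]$include_glp1 == st$include_glp1 &&
          all(fc %in% free_coefs(candidates$structure[[j]]))
      }, seq_len(n))
      if (length(sup_idx) == 0) {
        fit_subject(dataset, st, settings, protocols)
      } else {
        sup_rss <- vapply(sup_idx, function(j) fits[[j]]$best_rss,
                          numeric(1))
        sup_idx <- sup_idx[order(sup_rss)]
        sup_idx <- sup_idx[seq_len(min(max(settings$lm_starts, 1),
                                       length(sup_idx)))]
        nm <- c(kinetic_names(st), initial_names(st))
        bounds <- settings$bounds %||% default_fit_bounds(st, dataset)
        best <- NULL
        for (j in sup_idx) {
          parent <- fits[[j]]$subject
          par <- c(parent$kinetics, parent$init)[nm]
          ref <- lm_refine(par, dataset, st, settings, protocols,
                           bounds = bounds)
          if (is.null(best) || ref$value < best$value) best <- ref
        }
        subj <- ogtt_subject(best$par[kinetic_names(st)],
                             best$par[initial_names(st)], st,
                             id = unique(dataset$subject_id)[1])
        rd <- make_rss_data(dataset, st, protocols)
        out <- list(subject = subj, best_rss = best$value,
                    trials = tibble::tibble(trial = 1L, rss = best$value,
                                            ep_rss = NA_real_),
                    traces = list(), n_obs = rd$n_obs, structure = st,
                    settings = settings)
        class(out) <- "ogtt_fit"
        out
      }
    }, error = function(e) e)
  }
  fits
}

#' @export
print.ogtt_selection <- function(x, ...) {
  cat("<ogtt_selection> selected: ", x$selected, "\n", sep = "")
  print(dplyr::arrange(x$table, .data$aic), n = 8)
  invisible(x)
}

#' Tidy a model-selection result
#'
#' @param x An `ogtt_selection`.
#' @param ... Unused.
#' @return The per-candidate table, sorted by AIC, with a logical
#'   `selected` column.
#' @export
tidy.ogtt_selection <- function(x, ...) {
  out <- dplyr::arrange(x$table, .data$aic)
  out$selected <- out$label == x$selected
  out
}

#' @rdname tidy.ogtt_selection
#' @export
glance.ogtt_selection <- function(x, ...) {
  row <- x$table[x$table$label == x$selected, ]
  tibble::tibble(selected = x$selected, K = row$K, rss = row$rss,
                 n = row$n, aic = row$aic,
                 n_candidates = nrow(x$table),
                 n_failed = sum(!is.na(x$table$error)))
}
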