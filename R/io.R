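#' @importFrom rlang .data %||%
NULL

# shared validation for long-format datasets
validate_dataset <- function(dataset, protocols = standard_protocols(),
                             species_ok = .species_names) {
  need <- c("subject_id", "condition", "species", "time_min", "value",
            "included")
  missing_cols <- setdiff(need, names(dataset))
  if (length(missing_cols) > 0) {
    stop("dataset is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  bad_cond <- setdiff(unique(dataset$condition), protocols$condition)
  if (length(bad_cond) > 0) {
    stop("unknown condition label(s): ", paste(bad_cond, collapse = ", "))
  }
  bad_sp <- setdiff(unique(dataset$species), species_ok)
  if (length(bad_sp) > 0) {
    stop("unknown species token(s): ", paste(bad_sp, collapse = ", "))
  }
  if (any(!is.finite(dataset$time_min)) || any(!is.finite(dataset$value))) {
    stop("non-finite time or value entries in dataset")
  }
  dup <- duplicated(dataset[, c("subject_id", "condition", "species",
                                "time_min")])
  if (any(dup)) {
    stop("duplicate (condition, species, time) rows at data row(s): ",
         paste(utils::head(which(dup), 5), collapse = ", "))
  }
  dataset$included <- as.logical(dataset$included)
  tibble::as_tibble(dataset)
}

#' Write a long-format dataset CSV
#'
#' Columns `subject_id`, `condition`, `species`, `time_min`, `value`,
#' `included`. The long format lets conditions carry different sampling
#' grids.
#'
#' @param dataset Dataset tibble.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  readr::write_csv(validate_dataset(dataset), path)
  invisible(path)
}

#' Read and validate a long-format dataset CSV
#'
#' Condition labels are checked against the protocol table and species
#' against `{G, I, CP, GIP, GLP1}`; duplicate (condition, species, time)
#' rows and non-finite entries are rejected with the offending rows named.
#'
#' @param path CSV file as written by [write_dataset()].
#' @param protocols Protocol table defining the admissible conditions.
#' @return A validated dataset tibble.
#' @export
read_dataset <- function(path, protocols = standard_protocols()) {
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           subject_id = readr::col_character(),
                           condition = readr::col_character(),
                           species = readr::col_character(),
                           time_min = readr::col_double(),
                           value = readr::col_double(),
                           included = readr::col_logical()))
  prob <- readr::problems(raw)
  if (nrow(prob) > 0) {
    stop("malformed dataset rows (first at line ", prob$row[1], "): ",
         prob$expected[1])
  }
  validate_dataset(raw, protocols)
}

#' Run the full analysis pipeline on one synthetic subject
#'
#' Generates a synthetic dataset from the ground-truth subject, fits the
#' model (optionally running AIC structure selection first), optimizes the
#' glucose- and insulin-minimization patterns for the fitted subject, and
#' tabulates the peak comparison against the 50-g bolus and 50-g 1-h
#' continuous schedules. With `out_dir` set, all artifacts are written
#' (dataset CSV, subject JSONs, AIC table CSV, pattern TSVs, trajectory
#' CSVs, and a `run_info.json` embedding the seed and a configuration
#' hash).
#'
#' @param truth Ground-truth [ogtt_subject()].
#' @param noise Noise fraction for the synthetic dataset.
#' @param seed Global seed; stage seeds are derived from it.
#' @param select Run AIC structure selection (slow) or fit the truth's
#'   structure directly?
#' @param candidates Candidate set if `select = TRUE`.
#' @param fit_settings_ A [fit_settings()].
#' @param pattern_settings_ A [pattern_settings()].
#' @param out_dir Optional output directory.
#' @return A list of class `ogtt_pipeline`: `dataset`, `fit`, `selection`
#'   (or `NULL`), `glucose_opt`, `insulin_opt`, `report` (peak-comparison
#'   tibble), `seed`.
#' @export
run_pipeline <- function(truth = fixture_subject("A"), noise = 0.05,
                         seed = 1, select = FALSE,
                         candidates = NULL,
                         fit_settings_ = fit_settings(seed = seed + 100),
                         pattern_settings_ = pattern_settings(seed = seed +
                                                                200),
                         out_dir = NULL) {
  dataset <- generate_dataset(truth, noise = noise, seed = seed)
  selection <- NULL
  if (select) {
    candidates <- candidates %||%
      enumerate_candidates(!truth$structure$include_glp1)
    selection <- select_model(dataset, candidates, fit_settings_)
    fit <- selection$selected_fit
  } else {
    fit <- fit_subject(dataset, truth$structure, fit_settings_)
  }
  gl <- optimize_pattern(fit$subject, "glucose_peak", pattern_settings_)
  ins <- optimize_pattern(fit$subject, "insulin_peak", pattern_settings_)

  peaks_for <- function(schedule) {
    st <- solver_settings("euler", step = pattern_settings_$final_step,
                          horizon = pattern_settings_$horizon)
    ev <- schedule_events(schedule)
    p <- full_param_vector(fit$subject)
    y0 <- initial_state_vector(fit$subject)
    c(G = cpp_peak(p, y0, ev, st$step, st$horizon,
                   match("G", .state_names_8) - 1L, FALSE),
      I = cpp_peak(p, y0, ev, st$step, st$horizon,
                   match("I", .state_names_8) - 1L, FALSE))
  }
  comparison <- list(
    bolus = peaks_for(bolus_schedule(50)),
    continuous_1h = peaks_for(continuous_schedule(50, 60)),
    glucose_min = peaks_for(pattern_to_schedule(gl$best_pattern)),
    insulin_min = peaks_for(pattern_to_schedule(ins$best_pattern))
  )
  report <- purrr::imap_dfr(comparison, function(pk, nm) {
    tibble::tibble(subject_id = truth$id %||% "subject", schedule = nm,
                   peak_G = pk[["G"]], peak_I = pk[["I"]])
  })

  out <- list(dataset = dataset, fit = fit, selection = selection,
              glucose_opt = gl, insulin_opt = ins, report = report,
              seed = seed)
  class(out) <- "ogtt_pipeline"

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_dataset(dataset, file.path(out_dir, "dataset.csv"))
    write_subject_json(truth, file.path(out_dir, "truth_subject.json"))
    write_subject_json(fit$subject,
                       file.path(out_dir, "fitted_subject.json"))
    if (!is.null(selection)) {
      readr::write_csv(tidy(selection), file.path(out_dir, "aic_table.csv"))
    }
    readr::write_csv(report, file.path(out_dir, "peak_comparison.csv"))
    readr::write_tsv(tidy(gl), file.path(out_dir, "glucose_min_pattern.tsv"))
    readr::write_tsv(ins |> tidy(),
                     file.path(out_dir, "insulin_min_pattern.tsv"))
    traj <- simulate_subject(fit$subject,
                             pattern_to_schedule(gl$best_pattern),
                             solver_settings("euler", step = 0.01,
                                             horizon = 480))
    write_trajectory_csv(traj, file.path(out_dir,
                                         "glucose_min_trajectory.csv"))
    info <- list(seed = seed, noise = noise,
                 config_hash = rlang::hash(list(noise, seed, select,
                                                fit_settings_,
                                                pattern_settings_)),
                 fitted_structure = structure_label(fit$structure),
                 generated = as.character(Sys.time()))
    jsonlite::write_json(info, file.path(out_dir, "run_info.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  out
}

#' @export
print.ogtt_pipeline <- function(x, ...) {
  cat("<ogtt_pipeline> seed ", x$seed, "\n", sep = "")
  print(x$report)
  invisible(x)
}
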