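## File I/O and pipeline drivers. Concentration data travel as long-format
## CSV with columns drug, matrix, time_h, conc; fit reports are written as
## CSV plus machine-readable JSON. The pipeline_* functions are the
## high-level entry points the analysis scripts drive.

.csv_cols <- c("drug", "matrix", "time_h", "conc")

#' Read concentration records from a long-format CSV
#'
#' Expects columns `drug`, `matrix`, `time_h`, `conc`; schema violations
#' name the offending column or row.
#'
#' @param path CSV file path.
#' @return Records `data.frame` with columns `drug`, `matrix`, `time`,
#'   `conc` (time in hours).
#' @export
read_concentration_records <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(.csv_cols, names(df))
  if (length(miss))
    stop("schema error: missing column '", miss[1], "' in ", path)
  bad <- which(!df$matrix %in% .matrices)
  if (length(bad))
    stop("schema error: row ", bad[1], ", column 'matrix': unknown value '",
         df$matrix[bad[1]], "'")
  if (any(!is.finite(df$time_h)) || any(df$time_h < 0))
    stop("schema error: column 'time_h' must be non-negative numbers")
  if (any(!is.finite(df$conc)) || any(df$conc < 0))
    stop("schema error: column 'conc' must be non-negative numbers")
  concentration_records(df$drug, df$matrix, df$time_h, df$conc)
}

#' Write concentration records or profiles to CSV
#'
#' @param records Records `data.frame` (columns `drug`, `matrix`, `time`,
#'   `conc`) or (list of) `simulated_profile`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_concentration_records <- function(records, path) {
  if (!is.data.frame(records)) records <- profiles_to_records(records)
  out <- data.frame(drug = records$drug, matrix = records$matrix,
                    time_h = records$time, conc = records$conc)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write a fit report as CSV and JSON
#'
#' @param fit A `fit_result`.
#' @param path_csv,path_json Output paths (either may be `NULL`).
#' @return The fit's parameter table, invisibly.
#' @export
write_fit_report <- function(fit, path_csv = NULL, path_json = NULL) {
  tab <- data.frame(parameter = names(fit$estimates),
                    estimate = unname(fit$estimates),
                    cv_percent = unname(fit$cv_percent))
  if (!is.null(path_csv)) utils::write.csv(tab, path_csv,
                                           row.names = FALSE)
  if (!is.null(path_json))
    jsonlite::write_json(list(estimates = as.list(fit$estimates),
                              cv_percent = as.list(fit$cv_percent),
                              objective = fit$objective,
                              n_obs = fit$n_obs,
                              convergence = fit$convergence),
                         path_json, auto_unbox = TRUE, digits = NA)
  invisible(tab)
}

#' Simulate fixture drugs and write profile CSVs
#'
#' @param config List with elements `drugs` (character vector of fixture
#'   names or `"all"`), optional `design` ([study_design()]), and
#'   `out_dir` (created if missing; `NULL` skips writing).
#' @return Long `data.frame` of all simulated profiles, invisibly.
#' @export
pipeline_simulate <- function(config) {
  fx <- default_fixtures(quiet = TRUE)
  sel <- config$drugs
  if (is.null(sel) || identical(sel, "all")) sel <- names(fx$drugs)
  unknown <- setdiff(sel, names(fx$drugs))
  if (length(unknown))
    stop("unknown drug '", unknown[1], "'; available fixtures: ",
         paste(names(fx$drugs), collapse = ", "))
  d <- if (is.null(config$design)) study_design() else config$design
  all <- do.call(rbind, lapply(sel, function(dg) {
    prof <- simulate_study(fx$drugs[[dg]], fx$physiology, d)
    prof$whole_lung <- tissue_profile(fx$drugs[[dg]], fx$physiology,
                                      "whole_lung", d, d$tissue_times)
    profiles_to_records(prof)
  }))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_concentration_records(
      all, file.path(config$out_dir, "simulated_profiles.csv"))
  }
  invisible(all)
}

#' Two-stage fit of a concentration dataset
#'
#' Stage 1 fits each drug's systemic disposition from its plasma records;
#' stage 2 fits tissue affinities plus shared blood flows (or, with
#' `whole_lung = TRUE`, the single-compartment lung comparator).
#'
#' @param config List with `input` (CSV path) or `records` (data frame),
#'   optional `n_cpt` (named vector, compartments per drug; defaults to 2,
#'   or 1 when the fixture drug is one-compartment), `whole_lung` flag,
#'   `design`, `phys_init` (defaults to packaged physiology), `out_dir`.
#' @return List with `systemic` (named list of `fit_result`) and `tissue`
#'   (`fit_result`), invisibly.
#' @export
pipeline_fit <- function(config) {
  rec <- if (!is.null(config$records)) config$records
         else read_concentration_records(config$input)
  d <- if (is.null(config$design)) study_design() else config$design
  fx <- default_fixtures(quiet = TRUE)
  phys <- if (is.null(config$phys_init)) fx$physiology
          else config$phys_init
  drugs <- unique(rec$drug)
  sys_fits <- list()
  sys_params <- list()
  for (dg in drugs) {
    n_cpt <- if (!is.null(config$n_cpt) && dg %in% names(config$n_cpt))
      config$n_cpt[[dg]]
    else if (dg %in% names(fx$drugs) && is.null(fx$drugs[[dg]]$q_ic)) 1
    else 2
    ft <- fit_systemic(rec[rec$drug == dg, , drop = FALSE], n_cpt, d)
    sys_fits[[dg]] <- ft
    e <- ft$estimates
    sys_params[[dg]] <- drug_parameters(
      name = dg, cl = e[["cl"]], v_c = e[["v_c"]],
      q_ic = if (n_cpt == 2) e[["q_ic"]] else NULL,
      v_p = if (n_cpt == 2) e[["v_p"]] else NULL,
      fu_plasma = if (dg %in% names(fx$drugs))
        fx$drugs[[dg]]$fu_plasma else 1,
      kp_t = 1, kp_b = 1, kp_a = 1)
  }
  tis_fit <- if (isTRUE(config$whole_lung))
    fit_whole_lung(rec, sys_params, phys, d)
  else
    fit_tissue_shared(rec, sys_params, phys, d)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_fit_report(tis_fit,
                     file.path(config$out_dir, "tissue_fit.csv"),
                     file.path(config$out_dir, "tissue_fit.json"))
  }
  invisible(list(systemic = sys_fits, tissue = tis_fit))
}

#' Report half-life and EC50-bias tables
#'
#' Writes (and returns) the rat/human absorption half-life table and, for
#' two-compartment drugs with a bronchial Kp, the EC50 fold-bias time
#' course.
#'
#' @param config List with optional `drugs` (named list of
#'   [drug_parameters()]; defaults to the packaged fixtures), `phys`,
#'   `bias_drug` (default `"salmeterol"`), `bw_human`, `design`,
#'   `out_dir`.
#' @return List with `half_lives` and `ec50_bias` data frames, invisibly.
#' @export
pipeline_report <- function(config = list()) {
  fx <- default_fixtures(quiet = TRUE)
  drugs <- if (is.null(config$drugs)) fx$drugs else config$drugs
  if (!length(drugs)) stop("empty parameter set: nothing to report")
  phys <- if (is.null(config$phys)) fx$physiology else config$phys
  bwh <- if (is.null(config$bw_human)) 70 else config$bw_human
  d <- if (is.null(config$design)) study_design() else config$design
  hl <- half_life_table(drugs, phys, bw_human = bwh)
  hl$t_half_rat <- format_half_life(hl$t_half_rat_h)
  hl$t_half_human <- format_half_life(hl$t_half_human_h)
  bias_drug <- if (is.null(config$bias_drug)) "salmeterol"
               else config$bias_drug
  bias <- if (bias_drug %in% names(drugs))
    ec50_bias_table(drugs[[bias_drug]], phys, d)
  else NULL
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(hl, file.path(config$out_dir, "half_lives.csv"),
                     row.names = FALSE)
    if (!is.null(bias))
      utils::write.csv(bias, file.path(config$out_dir, "ec50_bias.csv"),
                       row.names = FALSE)
  }
  invisible(list(half_lives = hl, ec50_bias = bias))
}
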