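#' @keywords internal
"_PACKAGE"

## Tissue labels used throughout; "whole_lung" is the single-compartment
## comparator, not a physical sub-tissue.
.tissues <- c("trachea", "bronchi", "alveolar")
.matrices <- c("plasma", .tissues, "whole_lung")

#' Tissue and matrix labels
#'
#' @return Character vectors of the lung tissue labels resolved by the model
#'   (`lung_tissues()`) and of all observation matrices including plasma and
#'   the whole-lung aggregate (`matrix_levels()`).
#' @export
lung_tissues <- function() .tissues

#' @rdname lung_tissues
#' @export
matrix_levels <- function() .matrices

#' Drug-specific model parameters
#'
#' Container for the systemic disposition of one drug (one- or
#' two-compartment, bodyweight-normalized), its fraction unbound in plasma,
#' and its tissue-to-plasma partition coefficients for trachea, bronchi and
#' alveolar parenchyma (optionally a whole-lung coefficient).
#'
#' @param name Drug identifier.
#' @param cl Clearance, L/h/kg.
#' @param v_c Central volume of distribution, L/kg.
#' @param q_ic Intercompartmental clearance, L/h/kg; `NULL` for
#'   one-compartment drugs.
#' @param v_p Peripheral volume, L/kg; `NULL` for one-compartment drugs.
#' @param fu_plasma Fraction unbound in plasma, in (0, 1].
#' @param kp_t,kp_b,kp_a Tissue-to-plasma partition coefficients (total
#'   tissue over total plasma concentration at distribution equilibrium).
#' @param kp_lung Optional whole-lung partition coefficient.
#' @return An object of class `drug_params`.
#' @export
drug_parameters <- function(name, cl, v_c, q_ic = NULL, v_p = NULL,
                            fu_plasma, kp_t, kp_b, kp_a, kp_lung = NULL) {
  p <- structure(list(name = name, cl = cl, v_c = v_c, q_ic = q_ic,
                      v_p = v_p, fu_plasma = fu_plasma, kp_t = kp_t,
                      kp_b = kp_b, kp_a = kp_a, kp_lung = kp_lung),
                 class = "drug_params")
  p
}

#' Lung physiology parameters
#'
#' Bodyweight-normalized tissue weights (taken as volumes of distribution of
#' the virtual tissue compartments) and regional blood flows. The three
#' tissue weights must sum exactly to the whole-lung weight.
#'
#' @param w_t,w_b,w_a Tissue weight fractions, kg tissue per kg bodyweight.
#' @param q_t,q_b,q_a Regional blood flows, L/h/kg.
#' @param w_lung,q_lung Whole-lung analogues.
#' @param bw Body weight, kg.
#' @return An object of class `lung_physiology`.
#' @export
physiology_parameters <- function(w_t, w_b, w_a, q_t, q_b, q_a,
                                  w_lung = w_t + w_b + w_a, q_lung = NULL,
                                  bw = 0.28) {
  structure(list(w_t = w_t, w_b = w_b, w_a = w_a, q_t = q_t, q_b = q_b,
                 q_a = q_a, w_lung = w_lung, q_lung = q_lung, bw = bw),
            class = "lung_physiology")
}

#' Study design for an intravenous infusion experiment
#'
#' @param infusion_duration Infusion length, h.
#' @param infusion_rate Zero-order infusion rate, amount/h/kg (the amount
#'   unit is arbitrary; all headline outputs are dose-invariant ratios).
#' @param plasma_times Plasma sampling times, h.
#' @param tissue_times Tissue sampling times, h.
#' @param tissue_replicates Animals sampled per tissue time point.
#' @param bw Body weight, kg.
#' @return An object of class `study_design`.
#' @export
study_design <- function(infusion_duration = 1, infusion_rate = 1,
                         plasma_times = default_plasma_times(),
                         tissue_times = c(0.25, 0.75, 2, 4),
                         tissue_replicates = 3, bw = 0.28) {
  if (any(plasma_times < 0) || any(tissue_times < 0))
    stop("sampling times must be non-negative")
  if (tissue_replicates < 1) stop("tissue_replicates must be >= 1")
  structure(list(infusion_duration = infusion_duration,
                 infusion_rate = infusion_rate,
                 plasma_times = sort(plasma_times),
                 tissue_times = sort(tissue_times),
                 tissue_replicates = tissue_replicates, bw = bw),
            class = "study_design")
}

#' Default plasma sampling template
#'
#' Dense sampling concentrated within the infusion hour (60 samples in
#' (0, 1] h) plus sparse follow-up, emulating a design with roughly 67
#' plasma samples per drug, most of them collected during the first hour.
#'
#' @return Numeric vector of sampling times in hours.
#' @export
default_plasma_times <- function() {
  c(seq(1 / 60, 1, length.out = 60), 1.25, 1.5, 2, 3, 4)
}

#' Validate a drug/physiology parameter pair
#'
#' Checks every structural invariant and stops with a message naming the
#' first violated one; returns the pair unchanged when all hold.
#'
#' @param p A [drug_parameters()] object.
#' @param phys A [physiology_parameters()] object.
#' @return `list(p, phys)` invisibly, unchanged.
#' @export
validate_parameters <- function(p, phys) {
  kin <- c(cl = p$cl, v_c = p$v_c, kp_t = p$kp_t, kp_b = p$kp_b,
           kp_a = p$kp_a)
  if (!is.null(p$kp_lung)) kin <- c(kin, kp_lung = p$kp_lung)
  bad <- names(kin)[!is.finite(kin) | kin <= 0]
  if (length(bad))
    stop("kinetic parameters must be strictly positive: ", bad[1])
  if (is.null(p$q_ic) != is.null(p$v_p))
    stop("q_ic and v_p must be both present or both absent")
  if (!is.null(p$q_ic) && (p$q_ic <= 0 || p$v_p <= 0))
    stop("kinetic parameters must be strictly positive: q_ic/v_p")
  if (!is.finite(p$fu_plasma) || p$fu_plasma <= 0 || p$fu_plasma > 1)
    stop("fraction unbound must be in (0,1]")
  pv <- c(w_t = phys$w_t, w_b = phys$w_b, w_a = phys$w_a,
          q_t = phys$q_t, q_b = phys$q_b, q_a = phys$q_a,
          w_lung = phys$w_lung, bw = phys$bw)
  badp <- names(pv)[!is.finite(pv) | pv <= 0]
  if (length(badp))
    stop("physiology parameters must be strictly positive: ", badp[1])
  if (abs(phys$w_t + phys$w_b + phys$w_a - phys$w_lung) >
      1e-10 * phys$w_lung)
    stop("tissue weights must sum to lung weight")
  invisible(list(p = p, phys = phys))
}

#' Reconstruct a fraction unbound from a published derived quantity
#'
#' The fraction unbound in plasma enters the tissue model only through the
#' product Q*fu and is rarely reported directly. Two inversions are
#' supported: from a free (unbound) EC50 together with the total-tissue EC50
#' it was scaled from, fu = ec50_free * Kp / ec50_total; and from a
#' pulmonary absorption half-life, fu = ln(2) * V * Kp / (Q * t_half).
#'
#' @param anchor A list with element `type` (`"free_ec50"`, `"half_life"`,
#'   or `"none"`) plus the fields used by that type (see the packaged
#'   configuration for examples).
#' @param kp Partition coefficient of the anchoring tissue.
#' @param q Blood flow of the anchoring tissue, L/h/kg.
#' @param v Weight (volume) of the anchoring tissue, L/kg.
#' @return Fraction unbound (dimensionless); `NA` for type `"none"`.
#' @export
derive_fu_plasma <- function(anchor, kp, q, v) {
  switch(anchor$type,
    free_ec50 = anchor$ec50_free_nM * kp / anchor$ec50_total_nM,
    half_life = {
      t_half <- if (!is.null(anchor$t_half_min)) anchor$t_half_min / 60
                else if (!is.null(anchor$t_half_s)) anchor$t_half_s / 3600
                else anchor$t_half_h
      log(2) * v * kp / (q * t_half)
    },
    none = NA_real_,
    stop("unknown fu anchor type: ", anchor$type)
  )
}

.anchor_tissue_fields <- function(tissue) {
  switch(tissue,
    trachea  = list(kp = "kp_t", q = "q_t", v = "w_t"),
    bronchi  = list(kp = "kp_b", q = "q_b", v = "w_b"),
    alveolar = list(kp = "kp_a", q = "q_a", v = "w_a"),
    stop("unknown tissue: ", tissue))
}

#' Packaged parameter fixtures for the four model drugs
#'
#' Loads the shipped configuration (salmeterol, fluticasone propionate,
#' linezolid, indomethacin plus rat lung physiology) and reconstructs each
#' drug's fraction unbound from its anchor via [derive_fu_plasma()].
#' Linezolid has no physically admissible anchor (the inversion yields
#' fu > 1); its fu defaults to 1 and a warning is raised unless `quiet`.
#'
#' @param quiet Suppress the linezolid fu warning.
#' @return A list with elements `drugs` (named list of [drug_parameters()])
#'   and `physiology` (a [physiology_parameters()]).
#' @export
default_fixtures <- function(quiet = FALSE) {
  path <- system.file("extdata", "model_parameters.yaml", package = "lungpk",
                      mustWork = TRUE)
  cfg <- yaml::read_yaml(path)
  ph <- cfg$physiology
  phys <- physiology_parameters(w_t = ph$w_t, w_b = ph$w_b, w_a = ph$w_a,
                                q_t = ph$q_t, q_b = ph$q_b, q_a = ph$q_a,
                                w_lung = ph$w_lung, q_lung = ph$q_lung,
                                bw = ph$bw)
  drugs <- lapply(names(cfg$drugs), function(nm) {
    dd <- cfg$drugs[[nm]]
    anchor <- dd$fu_anchor
    fu <- if (anchor$type == "none") {
      if (!quiet)
        warning("no admissible fraction-unbound anchor for ", nm,
                "; defaulting fu_plasma to 1.0", call. = FALSE)
      1.0
    } else {
      f <- .anchor_tissue_fields(anchor$tissue)
      derive_fu_plasma(anchor, kp = dd[[f$kp]], q = ph[[f$q]],
                       v = ph[[f$v]])
    }
    p <- drug_parameters(name = nm, cl = dd$cl, v_c = dd$v_c,
                         q_ic = dd$q_ic, v_p = dd$v_p, fu_plasma = fu,
                         kp_t = dd$kp_t, kp_b = dd$kp_b, kp_a = dd$kp_a,
                         kp_lung = dd$kp_lung)
    validate_parameters(p, phys)
    p
  })
  names(drugs) <- names(cfg$drugs)
  list(drugs = drugs, physiology = phys)
}

## Kp lookup for a tissue label.
.kp_for <- function(p, tissue) {
  switch(tissue,
    trachea = p$kp_t, bronchi = p$kp_b, alveolar = p$kp_a,
    whole_lung = p$kp_lung,
    stop("unknown tissue: ", tissue))
}

## (Q, V) lookup for a tissue label.
.qv_for <- function(phys, tissue) {
  switch(tissue,
    trachea  = list(q = phys$q_t, v = phys$w_t),
    bronchi  = list(q = phys$q_b, v = phys$w_b),
    alveolar = list(q = phys$q_a, v = phys$w_a),
    whole_lung = list(q = phys$q_lung, v = phys$w_lung),
    stop("unknown tissue: ", tissue))
}

#' Build a concentration record table
#'
#' Long-format observation container: one row per measured concentration.
#'
#' @param drug,matrix,time,conc Vectors (recycled to common length) giving
#'   drug identifier, observation matrix (one of [matrix_levels()]), time in
#'   hours and concentration in amount/L.
#' @return A `data.frame` with columns `drug`, `matrix`, `time`, `conc`.
#' @export
concentration_records <- function(drug, matrix, time, conc) {
  rec <- data.frame(drug = drug, matrix = matrix, time = time, conc = conc,
                    stringsAsFactors = FALSE)
  bad <- which(!rec$matrix %in% .matrices)
  if (length(bad))
    stop("row ", bad[1], ": unknown matrix '", rec$matrix[bad[1]], "'")
  if (any(rec$time < 0)) stop("times must be non-negative")
  if (any(rec$conc < 0)) stop("concentrations must be non-negative")
  rec
}

#' @export
print.drug_params <- function(x, ...) {
  cat("<drug_params>", x$name, "\n")
  cat(sprintf("  CL %.4g L/h/kg, Vc %.4g L/kg", x$cl, x$v_c))
  if (!is.null(x$q_ic))
    cat(sprintf(", Q %.4g L/h/kg, Vp %.4g L/kg", x$q_ic, x$v_p))
  cat(sprintf("\n  fu,plasma %.4g; Kp (T/B/A) %.4g / %.4g / %.4g",
              x$fu_plasma, x$kp_t, x$kp_b, x$kp_a))
  if (!is.null(x$kp_lung)) cat(sprintf("; Kp lung %.4g", x$kp_lung))
  cat("\n")
  invisible(x)
}
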