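## Two-stage parameter estimation.
##
## Stage 1 fits the systemic disposition (CL, Vc and, for two-compartment
## drugs, Q, Vp) to the plasma data alone. Stage 2 fixes the systemic
## parameters and fits the tissue partition coefficients per drug together
## with the three regional blood flows shared across all drugs.
##
## Residuals are computed on log concentrations (equivalent to a
## proportional error model; the data span more than two orders of
## magnitude) and parameters are fitted on the log scale, which enforces
## positivity without constrained optimization. CV% is 100 * SE of the log
## parameter (delta method), with the covariance taken from the scaled
## inverse Hessian of the sum-of-squares objective at the optimum.

## Generic weighted (log-scale) nonlinear least squares with multi-start.
## predict_log(theta_log) must return predictions on the log scale aligned
## with obs_log; non-finite predictions are penalized.
.wnls <- function(obs_log, predict_log, start_log, n_starts = 5,
                  seed = 20L, spread = 1.5) {
  objective <- function(th) {
    pl <- predict_log(th)
    if (any(!is.finite(pl))) return(1e12)
    sum((obs_log - pl)^2)
  }
  starts <- list(start_log)
  if (n_starts > 1) {
    ## Perturb in a private RNG stream so user-visible randomness is
    ## untouched.
    rs <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    for (i in seq_len(n_starts - 1))
      starts[[i + 1]] <- start_log +
        stats::runif(length(start_log), -spread, spread)
    if (!is.null(rs)) assign(".Random.seed", rs, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  }
  ctl <- list(eval.max = 5000, iter.max = 2000, rel.tol = 1e-12)
  best <- NULL
  for (st in starts) {
    fit <- stats::nlminb(st, objective, control = ctl)
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  if (!is.finite(best$objective))
    stop("estimation did not converge: non-finite objective")
  ## Polish from the incumbent; a near-singular tolerance stop at an
  ## optimum that a restart cannot improve counts as converged.
  polish <- stats::nlminb(best$par, objective, control = ctl)
  improved <- best$objective - polish$objective
  if (polish$objective <= best$objective) best <- polish
  if (best$convergence != 0 &&
      improved <= 1e-8 * (1 + best$objective))
    best$convergence <- 0L
  n <- length(obs_log)
  p <- length(start_log)
  sigma2 <- if (n > p) best$objective / (n - p) else 0
  hess <- stats::optimHess(best$par, objective)
  cov_log <- tryCatch(2 * sigma2 * solve(hess),
                      error = function(e) matrix(NA_real_, p, p))
  se_log <- sqrt(pmax(diag(cov_log), 0))
  list(par_log = best$par, objective = best$objective,
       convergence = best$convergence, message = best$message,
       cov_log = cov_log, cv_percent = 100 * se_log, n_obs = n)
}

.new_fit_result <- function(estimates, cv_percent, objective, covariance,
                            n_obs, convergence, message = NULL) {
  structure(list(estimates = estimates, cv_percent = cv_percent,
                 objective = objective, covariance = covariance,
                 n_obs = n_obs, convergence = convergence,
                 message = message),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result>", x$n_obs, "observations, objective",
      format(x$objective, digits = 6), "\n")
  tab <- data.frame(estimate = signif(x$estimates, 4),
                    cv_percent = signif(x$cv_percent, 3))
  print(tab)
  invisible(x)
}

#' Fit the systemic disposition model to plasma data
#'
#' Weighted nonlinear least squares on log plasma concentrations for a one-
#' or two-compartment constant-rate-infusion model; parameters are fitted
#' on the log scale with five log-uniform multi-starts (fixed seed).
#'
#' @param records Long-format records (columns `drug`, `matrix`, `time`,
#'   `conc`); only `matrix == "plasma"` rows are used.
#' @param n_cpt Number of disposition compartments, 1 or 2.
#' @param d [study_design()] providing the infusion specification.
#' @param n_starts,seed Multi-start control.
#' @return A `fit_result` with estimates `cl`, `v_c` (and `q_ic`, `v_p`).
#' @export
fit_systemic <- function(records, n_cpt = 2, d, n_starts = 5, seed = 20L) {
  stopifnot(n_cpt %in% c(1, 2))
  rec <- records[records$matrix == "plasma", , drop = FALSE]
  rec <- rec[order(rec$time, rec$conc), , drop = FALSE]
  nms <- if (n_cpt == 2) c("cl", "v_c", "q_ic", "v_p") else c("cl", "v_c")
  if (nrow(rec) < 2 * length(nms))
    stop("insufficient data: need at least ", 2 * length(nms),
         " plasma observations for ", length(nms), " parameters")
  if (any(rec$conc <= 0))
    stop("plasma concentrations must be positive for log-scale fitting")
  obs_log <- log(rec$conc)
  times <- rec$time
  make_p <- function(th) {
    v <- exp(th)
    drug_parameters(name = "fit", cl = v[1], v_c = v[2],
                    q_ic = if (n_cpt == 2) v[3] else NULL,
                    v_p = if (n_cpt == 2) v[4] else NULL,
                    fu_plasma = 1, kp_t = 1, kp_b = 1, kp_a = 1)
  }
  predict_log <- function(th)
    log(plasma_profile(make_p(th), d, times)$concs)
  ## Heuristic starts: near-steady-state concentration ~ rate/CL; a
  ## distribution volume on the scale of CL; peripheral pool larger.
  cl0 <- d$infusion_rate / max(rec$conc)
  st <- log(c(cl0, 0.25 * cl0, cl0, 2 * cl0))[seq_along(nms)]
  ft <- .wnls(obs_log, predict_log, st, n_starts = n_starts, seed = seed)
  if (ft$convergence != 0 && ft$objective > 1e-8 * length(obs_log))
    warning("possible non-convergence (code ", ft$convergence,
            "): final objective ", format(ft$objective, digits = 4))
  est <- stats::setNames(exp(ft$par_log), nms)
  dimnames(ft$cov_log) <- list(nms, nms)
  .new_fit_result(est, stats::setNames(ft$cv_percent, nms), ft$objective,
                  ft$cov_log, ft$n_obs, ft$convergence, ft$message)
}

## Build the stage-2 parameter vector layout: per-drug per-tissue Kp then
## shared flows for the tissues present.
.stage2_layout <- function(drugs, tissues) {
  kp_names <- as.vector(t(outer(drugs, tissues, function(dg, ts)
    paste0("kp_", substr(ts, 1, 1), ".", dg))))
  list(kp = kp_names,
       q = paste0("q_", substr(tissues, 1, 1)))
}

#' Fit tissue affinities and shared regional blood flows
#'
#' Stage-2 estimation: with each drug's systemic disposition fixed, fits
#' one partition coefficient per drug and tissue plus the regional blood
#' flows (trachea, bronchi, alveolar) shared across all drugs, by weighted
#' nonlinear least squares on log tissue concentrations.
#'
#' Initial blood flows come from `phys_init` (literature priors: alveolar
#' flow from cardiac output, tracheobronchial flow from a small percentage
#' of cardiac output split by tissue weight). Initial Kp values are taken
#' from the latest-time observed tissue-to-plasma ratio per drug/tissue.
#'
#' @param records Long-format tissue records for all drugs (matrix one of
#'   the lung tissues).
#' @param systemic Named list of fixed [drug_parameters()], one per drug in
#'   `records` (their `kp_*` slots are ignored).
#' @param phys_init [physiology_parameters()] carrying the fixed tissue
#'   weights and initial blood flows.
#' @param d [study_design()].
#' @param n_starts,seed Multi-start control.
#' @param fix_flows Hold the blood flows at their `phys_init` values and
#'   fit only the partition coefficients (stage separability check).
#' @return A `fit_result`; estimate names are `kp_<t|b|a>.<drug>` plus
#'   `q_t`, `q_b`, `q_a` (flows omitted when `fix_flows`).
#' @export
fit_tissue_shared <- function(records, systemic, phys_init, d,
                              n_starts = 3, seed = 21L,
                              fix_flows = FALSE) {
  rec <- records[records$matrix %in% .tissues, , drop = FALSE]
  if (!nrow(rec)) stop("no tissue observations supplied")
  ## canonical row order so the fit is invariant to record permutation
  rec <- rec[order(rec$drug, rec$matrix, rec$time, rec$conc), ,
             drop = FALSE]
  drugs <- unique(rec$drug)
  missing_sys <- setdiff(drugs, names(systemic))
  if (length(missing_sys))
    stop("no systemic parameters supplied for: ",
         paste(missing_sys, collapse = ", "))
  tissues <- .tissues[.tissues %in% unique(rec$matrix)]
  for (ts in tissues) {
    tms <- unique(rec$time[rec$matrix == ts])
    if (length(tms) < 2)
      stop("structurally non-identifiable: blood flow for ", ts,
           " requires observations at >= 2 distinct times ",
           "(Kp and Q trade off with a single time point)")
  }
  if (any(rec$conc <= 0))
    stop("tissue concentrations must be positive for log-scale fitting")

  lay <- .stage2_layout(drugs, tissues)
  nms <- if (fix_flows) lay$kp else c(lay$kp, lay$q)
  macs <- lapply(systemic[drugs], .systemic_macro)
  q_init <- vapply(tissues, function(ts) .qv_for(phys_init, ts)$q,
                   numeric(1))
  names(q_init) <- tissues
  v_tis <- vapply(tissues, function(ts) .qv_for(phys_init, ts)$v,
                  numeric(1))
  names(v_tis) <- tissues
  ## index bookkeeping: rows grouped by drug x tissue
  groups <- split(seq_len(nrow(rec)),
                  list(drug = rec$drug, tissue = rec$matrix), drop = TRUE)
  kp_index <- stats::setNames(seq_along(lay$kp), lay$kp)

  ## Order-invariant Kp starts: mean observed tissue-to-plasma ratio at
  ## the latest sampling time of each drug/tissue group.
  kp0 <- numeric(length(lay$kp))
  names(kp0) <- lay$kp
  for (g in names(groups)) {
    idx <- groups[[g]]
    dg <- rec$drug[idx[1]]
    ts <- rec$matrix[idx[1]]
    tmax <- max(rec$time[idx])
    clate <- mean(rec$conc[idx][rec$time[idx] == tmax])
    cp <- .finite_infusion(function(t)
      .plasma_on(macs[[dg]], d$infusion_rate, t),
      tmax, d$infusion_duration)
    kp0[paste0("kp_", substr(ts, 1, 1), ".", dg)] <-
      max(clate / cp, 1e-4)
  }
  start_log <- if (fix_flows) log(kp0) else log(c(kp0, q_init))

  obs_log <- log(rec$conc)
  predict_log <- function(th) {
    v <- exp(th)
    qs <- if (fix_flows) q_init
          else stats::setNames(v[length(lay$kp) + seq_along(tissues)],
                               tissues)
    out <- numeric(nrow(rec))
    for (g in names(groups)) {
      idx <- groups[[g]]
      dg <- rec$drug[idx[1]]
      ts <- rec$matrix[idx[1]]
      kp <- v[kp_index[paste0("kp_", substr(ts, 1, 1), ".", dg)]]
      fu <- systemic[[dg]]$fu_plasma
      k <- qs[ts] * fu / (v_tis[ts] * kp)
      out[idx] <- .finite_infusion(function(t)
        .tissue_on(macs[[dg]], d$infusion_rate, t, k, kp),
        rec$time[idx], d$infusion_duration)
    }
    log(out)
  }
  ft <- .wnls(obs_log, predict_log, start_log, n_starts = n_starts,
              seed = seed)
  est <- stats::setNames(exp(ft$par_log), nms)
  dimnames(ft$cov_log) <- list(nms, nms)
  .new_fit_result(est, stats::setNames(ft$cv_percent, nms), ft$objective,
                  ft$cov_log, ft$n_obs, ft$convergence, ft$message)
}

#' Fit the whole-lung single-compartment comparator
#'
#' Same machinery as [fit_tissue_shared()] but with a single lumped lung
#' compartment: one whole-lung Kp per drug and one whole-lung blood flow
#' shared across drugs.
#'
#' @param records Long-format records with `matrix == "whole_lung"`.
#' @inheritParams fit_tissue_shared
#' @return A `fit_result`; estimate names `kp_lung.<drug>` plus `q_lung`.
#' @export
fit_whole_lung <- function(records, systemic, phys_init, d,
                           n_starts = 3, seed = 22L) {
  rec <- records[records$matrix == "whole_lung", , drop = FALSE]
  if (!nrow(rec)) stop("no whole-lung observations supplied")
  rec <- rec[order(rec$drug, rec$time, rec$conc), , drop = FALSE]
  drugs <- unique(rec$drug)
  missing_sys <- setdiff(drugs, names(systemic))
  if (length(missing_sys))
    stop("no systemic parameters supplied for: ",
         paste(missing_sys, collapse = ", "))
  if (length(unique(rec$time)) < 2)
    stop("structurally non-identifiable: blood flow for whole_lung ",
         "requires observations at >= 2 distinct times")
  if (any(rec$conc <= 0))
    stop("concentrations must be positive for log-scale fitting")

  nms <- c(paste0("kp_lung.", drugs), "q_lung")
  macs <- lapply(systemic[drugs], .systemic_macro)
  v_lung <- phys_init$w_lung
  q0 <- if (!is.null(phys_init$q_lung)) phys_init$q_lung
        else phys_init$q_t + phys_init$q_b + phys_init$q_a
  groups <- split(seq_len(nrow(rec)), rec$drug)
  kp0 <- vapply(drugs, function(dg) {
    idx <- groups[[dg]]
    tmax <- max(rec$time[idx])
    clate <- mean(rec$conc[idx][rec$time[idx] == tmax])
    cp <- .finite_infusion(function(t)
      .plasma_on(macs[[dg]], d$infusion_rate, t),
      tmax, d$infusion_duration)
    max(clate / cp, 1e-4)
  }, numeric(1))
  start_log <- log(c(kp0, q0))

  obs_log <- log(rec$conc)
  predict_log <- function(th) {
    v <- exp(th)
    q <- v[length(drugs) + 1]
    out <- numeric(nrow(rec))
    for (i in seq_along(drugs)) {
      dg <- drugs[i]
      idx <- groups[[dg]]
      kp <- v[i]
      fu <- systemic[[dg]]$fu_plasma
      k <- q * fu / (v_lung * kp)
      out[idx] <- .finite_infusion(function(t)
        .tissue_on(macs[[dg]], d$infusion_rate, t, k, kp),
        rec$time[idx], d$infusion_duration)
    }
    log(out)
  }
  ft <- .wnls(obs_log, predict_log, start_log, n_starts = n_starts,
              seed = seed)
  est <- stats::setNames(exp(ft$par_log), nms)
  dimnames(ft$cov_log) <- list(nms, nms)
  .new_fit_result(est, stats::setNames(ft$cv_percent, nms), ft$objective,
                  ft$cov_log, ft$n_obs, ft$convergence, ft$message)
}

#' Goodness of fit: coefficient of determination and two-fold agreement
#'
#' R-squared is computed as 1 - SSR/SST on observed versus predicted
#' concentrations; by this definition a model can score below zero when it
#' predicts worse than the observed mean. The two-fold fraction is the
#' share of pairs with 0.5 <= pred/obs <= 2.
#'
#' @param obs,pred Paired positive numeric vectors (or record/prediction
#'   data frames with a `conc` column, matched by position).
#' @return A list with `r_squared`, `frac_within_twofold`, `n`.
#' @export
goodness_of_fit <- function(obs, pred) {
  if (is.data.frame(obs)) obs <- obs$conc
  if (is.data.frame(pred)) pred <- pred$conc
  if (!length(obs)) stop("empty input")
  if (length(obs) != length(pred))
    stop("obs and pred must have equal length")
  ssr <- sum((obs - pred)^2)
  sst <- sum((obs - mean(obs))^2)
  r2 <- if (sst == 0) ifelse(ssr == 0, 1, -Inf) else 1 - ssr / sst
  ratio <- pred / obs
  list(r_squared = r2,
       frac_within_twofold = mean(ratio >= 0.5 & ratio <= 2),
       n = length(obs))
}
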