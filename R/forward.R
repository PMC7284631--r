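## Forward simulation of plasma and virtual lung-tissue concentrations for a
## constant-rate IV infusion.
##
## The systemic model is an empirical one- or two-compartment disposition
## model. Each lung tissue is a "virtual" compartment: it is driven by the
## total plasma concentration but feeds no mass back (its weight is a
## negligible fraction of the systemic distribution volume), so
##
##   dC_tis/dt = (Q fu / V) * C_p(t) - (Q fu / (V Kp)) * C_tis .
##
## Everything is linear and time-invariant, so the closed-form backend
## computes the infusion-on step response as a sum of exponentials and
## handles the end of infusion by superposition, response(t) minus
## response(t - T_inf). This is exact and immune to the stiffness of the
## fast distribution phase (lambda_1 ~ 58 /h for salmeterol).

## Macro-exponential coefficients of the unit-bolus plasma response:
## C_p(t) = sum coef_i exp(-lambda_i t) for a unit dose per kg.
.systemic_macro <- function(p) {
  k10 <- p$cl / p$v_c
  if (is.null(p$q_ic)) {
    return(list(lambda = k10, coef = 1 / p$v_c))
  }
  k12 <- p$q_ic / p$v_c
  k21 <- p$q_ic / p$v_p
  s <- k10 + k12 + k21
  disc <- sqrt(s^2 - 4 * k10 * k21)
  l1 <- (s + disc) / 2
  l2 <- (s - disc) / 2
  list(lambda = c(l1, l2),
       coef = c((l1 - k21) / (l1 - l2), (k21 - l2) / (l1 - l2)) / p$v_c)
}

## Plasma response to an infusion switched on at t = 0 and never stopped.
.plasma_on <- function(mac, rate, t) {
  tp <- pmax(t, 0)
  out <- 0
  for (i in seq_along(mac$lambda))
    out <- out + mac$coef[i] / mac$lambda[i] * (1 - exp(-mac$lambda[i] * tp))
  rate * out
}

## Tissue response to the same switched-on infusion, obtained by passing the
## plasma step response through the first-order tissue filter with efflux
## rate k = Q fu / (V Kp) and influx k * Kp. The near-degenerate case
## k == lambda_i uses the limiting form t * exp(-k t).
.tissue_on <- function(mac, rate, t, k, kp) {
  tp <- pmax(t, 0)
  ek <- exp(-k * tp)
  out <- 0
  for (i in seq_along(mac$lambda)) {
    l <- mac$lambda[i]
    a <- rate * mac$coef[i] / l
    out <- out + a * kp * (1 - ek)
    if (abs(k - l) > 1e-9 * max(k, l)) {
      out <- out - a * k * kp * (exp(-l * tp) - ek) / (k - l)
    } else {
      out <- out - a * k * kp * tp * ek
    }
  }
  out
}

## Superposition for a finite infusion of duration tinf.
.finite_infusion <- function(on_fn, t, tinf) on_fn(t) - on_fn(t - tinf)

.new_profile <- function(drug, matrix, times, concs) {
  structure(list(drug = drug, matrix = matrix, times = times,
                 concs = concs),
            class = "simulated_profile")
}

#' Simulated concentration-time profile
#'
#' @param x A `simulated_profile`.
#' @param ... Ignored.
#' @export
print.simulated_profile <- function(x, ...) {
  cat("<simulated_profile>", x$drug, "/", x$matrix, ":",
      length(x$times), "points over",
      if (length(x$times)) paste0("[", min(x$times), ", ", max(x$times),
                                  "] h") else "(empty)", "\n")
  invisible(x)
}

#' Plasma concentration-time profile under constant-rate infusion
#'
#' Closed-form one/two-compartment solution for a zero-order infusion of
#' duration `d$infusion_duration`, with the post-infusion phase obtained by
#' superposition; the profile is continuous at the stop time.
#'
#' @param p [drug_parameters()].
#' @param d [study_design()].
#' @param times Evaluation times, h (non-negative).
#' @return A `simulated_profile` for matrix `"plasma"`.
#' @export
plasma_profile <- function(p, d, times = d$plasma_times) {
  if (any(times < 0)) stop("times must be non-negative")
  mac <- .systemic_macro(p)
  cc <- .finite_infusion(function(t) .plasma_on(mac, d$infusion_rate, t),
                         times, d$infusion_duration)
  .new_profile(p$name, "plasma", times, cc)
}

#' Virtual lung-tissue concentration-time profile
#'
#' First-order perfusion-limited uptake driven by the total plasma
#' concentration scaled by the fraction unbound: influx rate constant
#' Q*fu/V, efflux rate constant Q*fu/(V*Kp). At distribution equilibrium
#' with constant plasma concentration the tissue-to-plasma ratio equals Kp.
#' For `tissue = "whole_lung"` with no `kp_lung` on the drug, the profile is
#' the tissue-weight-weighted mean of the three regional profiles (what a
#' total-lung homogenate would measure); with `kp_lung` set it is a single
#' lumped compartment with the whole-lung weight and blood flow.
#'
#' @param p [drug_parameters()].
#' @param phys [physiology_parameters()].
#' @param tissue One of `"trachea"`, `"bronchi"`, `"alveolar"`,
#'   `"whole_lung"`.
#' @param d [study_design()].
#' @param times Evaluation times, h.
#' @return A `simulated_profile`.
#' @export
tissue_profile <- function(p, phys, tissue, d, times = d$tissue_times) {
  if (any(times < 0)) stop("times must be non-negative")
  if (!tissue %in% c(.tissues, "whole_lung"))
    stop("unknown tissue: ", tissue)
  if (tissue == "whole_lung" && is.null(p$kp_lung)) {
    w <- c(phys$w_t, phys$w_b, phys$w_a) / phys$w_lung
    parts <- lapply(.tissues, function(ts)
      tissue_profile(p, phys, ts, d, times)$concs)
    cc <- w[1] * parts[[1]] + w[2] * parts[[2]] + w[3] * parts[[3]]
    return(.new_profile(p$name, "whole_lung", times, cc))
  }
  qv <- .qv_for(phys, tissue)
  kp <- .kp_for(p, tissue)
  k <- qv$q * p$fu_plasma / (qv$v * kp)
  mac <- .systemic_macro(p)
  cc <- .finite_infusion(
    function(t) .tissue_on(mac, d$infusion_rate, t, k, kp),
    times, d$infusion_duration)
  .new_profile(p$name, tissue, times, cc)
}

#' Simulate a full study for one drug
#'
#' Plasma at the design's plasma sampling times and the three lung tissues
#' at the tissue sampling times.
#'
#' @inheritParams tissue_profile
#' @return Named list of `simulated_profile`s
#'   (`plasma`, `trachea`, `bronchi`, `alveolar`).
#' @export
simulate_study <- function(p, phys, d) {
  out <- c(list(plasma = plasma_profile(p, d)),
           lapply(stats::setNames(.tissues, .tissues), function(ts)
             tissue_profile(p, phys, ts, d, d$tissue_times)))
  out
}

#' Numerical-integration backend for the coupled system
#'
#' Integrates the full systemic + three-virtual-compartment ODE system with
#' a stiff solver, splitting the integration at the end of infusion so the
#' rate discontinuity is handled exactly. Used as an independent check of
#' the closed-form backend.
#'
#' @inheritParams tissue_profile
#' @param times Common evaluation times for all matrices, h.
#' @return Named list of `simulated_profile`s for plasma, the three
#'   tissues, and the weight-averaged `whole_lung`.
#' @export
ode_backend <- function(p, phys, d, times) {
  if (any(times < 0)) stop("times must be non-negative")
  two_cpt <- !is.null(p$q_ic)
  kin <- vapply(.tissues, function(ts) {
    qv <- .qv_for(phys, ts)
    qv$q * p$fu_plasma / qv$v
  }, numeric(1))
  kout <- kin / vapply(.tissues, function(ts) .kp_for(p, ts), numeric(1))

  deriv <- function(t, y, parms) {
    rate <- parms$rate
    cp <- y[1] / p$v_c
    dAc <- rate - p$cl * cp
    dAp <- 0
    if (two_cpt) {
      dAc <- dAc - p$q_ic * cp + p$q_ic * y[2] / p$v_p
      dAp <- p$q_ic * cp - p$q_ic * y[2] / p$v_p
    }
    dT <- kin * cp - kout * y[3:5]
    list(c(dAc, dAp, dT))
  }

  y0 <- numeric(5)
  tinf <- d$infusion_duration
  tt <- sort(unique(c(0, times)))
  seg1 <- tt[tt <= tinf]
  seg2 <- tt[tt > tinf]
  run <- function(y, span, rate) {
    if (length(span) < 2) return(NULL)
    out <- deSolve::lsoda(y, span, deriv, list(rate = rate),
                          rtol = 1e-11, atol = 1e-13)
    if (attr(out, "istate")[1] < 0) stop("ODE integration failed")
    out
  }
  res <- matrix(NA_real_, nrow = length(tt), ncol = 5)
  rownames(res) <- format(tt, digits = 15)
  o1 <- run(y0, unique(c(seg1, tinf)), d$infusion_rate)
  if (!is.null(o1)) {
    keep <- o1[, 1] %in% seg1
    res[match(o1[keep, 1], tt), ] <- o1[keep, -1, drop = FALSE]
    y_end <- o1[nrow(o1), -1]
  } else {
    y_end <- y0
  }
  if (length(seg2)) {
    o2 <- run(y_end, c(tinf, seg2), 0)
    res[match(seg2, tt), ] <- o2[-1, -1, drop = FALSE]
  }
  if (0 %in% tt) res[match(0, tt), ] <- 0
  idx <- match(times, tt)
  res <- unname(res)
  cp <- res[idx, 1] / p$v_c
  prof <- list(plasma = .new_profile(p$name, "plasma", times, cp))
  for (i in seq_along(.tissues))
    prof[[.tissues[i]]] <-
      .new_profile(p$name, .tissues[i], times, res[idx, 2 + i])
  wl <- (phys$w_t * prof$trachea$concs + phys$w_b * prof$bronchi$concs +
         phys$w_a * prof$alveolar$concs) / phys$w_lung
  prof$whole_lung <- .new_profile(p$name, "whole_lung", times, wl)
  prof
}

#' Convert simulated profiles to a long record table
#'
#' @param profiles A `simulated_profile` or list of them.
#' @return A long `data.frame` with columns `drug`, `matrix`, `time`,
#'   `conc`.
#' @export
profiles_to_records <- function(profiles) {
  if (inherits(profiles, "simulated_profile")) profiles <- list(profiles)
  do.call(rbind, lapply(profiles, function(pr)
    data.frame(drug = pr$drug, matrix = pr$matrix, time = pr$times,
               conc = pr$concs, stringsAsFactors = FALSE)))
}
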