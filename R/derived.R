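## Derived quantities: absorption rate constants and half-lives, tissue
## unbound fractions, allometric scaling to human, and the time course of
## the tissue-to-plasma ratio as a percentage of its steady-state value.

#' Pulmonary absorption rate constant
#'
#' Unidirectional tissue-to-plasma transfer rate constant
#' k_a = Q * fu / (V * Kp) for the named lung region.
#'
#' @param p [drug_parameters()].
#' @param phys [physiology_parameters()].
#' @param tissue One of `"trachea"`, `"bronchi"`, `"alveolar"`,
#'   `"whole_lung"`.
#' @return Rate constant in 1/h.
#' @export
absorption_rate_constant <- function(p, phys, tissue) {
  kp <- .kp_for(p, tissue)
  if (is.null(kp))
    stop("no whole-lung partition coefficient set for ", p$name)
  qv <- .qv_for(phys, tissue)
  if (is.null(qv$q))
    stop("no whole-lung blood flow set in physiology")
  qv$q * p$fu_plasma / (qv$v * kp)
}

#' Absorption half-life
#'
#' @param k_a Absorption rate constant, 1/h (positive).
#' @return Half-life ln(2)/k_a in hours.
#' @export
half_life <- function(k_a) {
  if (any(!is.finite(k_a) | k_a <= 0))
    stop("absorption rate constant must be positive")
  log(2) / k_a
}

#' Allometric scaling of lung physiology to another bodyweight
#'
#' Blood flows scale with bodyweight to the power 0.75 and volumes to the
#' power 1; on the per-kg scale used here the volumes are therefore
#' unchanged and the flows pick up a factor (BW_target/BW_source)^(0.75-1).
#' Partition coefficients are assumed conserved across species, so the
#' tissue half-life ratio between species is (BW_target/BW_source)^0.25 for
#' every drug and tissue.
#'
#' @param phys [physiology_parameters()] (source species, per-kg values).
#' @param bw_source,bw_target Body weights, kg.
#' @return A [physiology_parameters()] for the target species.
#' @export
scale_to_human <- function(phys, bw_source = phys$bw, bw_target = 70) {
  if (bw_source <= 0 || bw_target <= 0)
    stop("body weights must be positive")
  f <- (bw_target / bw_source)^(0.75 - 1)
  physiology_parameters(w_t = phys$w_t, w_b = phys$w_b, w_a = phys$w_a,
                        q_t = phys$q_t * f, q_b = phys$q_b * f,
                        q_a = phys$q_a * f, w_lung = phys$w_lung,
                        q_lung = if (is.null(phys$q_lung)) NULL
                                 else phys$q_lung * f,
                        bw = bw_target)
}

#' Tissue unbound fraction
#'
#' Under the equilibrium assumption that unbound concentrations in plasma
#' and tissue are equal, the fraction unbound in tissue is
#' fu_plasma / Kp.
#'
#' @param fu_plasma Plasma fraction unbound (positive).
#' @param kp Tissue-to-plasma partition coefficient (positive).
#' @return Tissue unbound fraction (dimensionless).
#' @export
tissue_fu <- function(fu_plasma, kp) {
  if (fu_plasma <= 0 || kp <= 0) stop("inputs must be positive")
  fu_plasma / kp
}

#' Table of rat and human absorption half-lives
#'
#' One row per drug and lung region (including the whole-lung comparator
#' where a whole-lung Kp is available), with the rat half-life and the
#' allometrically scaled human half-life in hours.
#'
#' @param drugs Named list of [drug_parameters()].
#' @param phys Rat [physiology_parameters()].
#' @param bw_human Human bodyweight, kg.
#' @return `data.frame` with columns `drug`, `tissue`, `t_half_rat_h`,
#'   `t_half_human_h`.
#' @export
half_life_table <- function(drugs, phys, bw_human = 70) {
  phys_h <- scale_to_human(phys, phys$bw, bw_human)
  rows <- list()
  for (dg in names(drugs)) {
    p <- drugs[[dg]]
    tset <- c(.tissues, if (!is.null(p$kp_lung) &&
                            !is.null(phys$q_lung)) "whole_lung")
    for (ts in tset) {
      rows[[length(rows) + 1]] <- data.frame(
        drug = dg, tissue = ts,
        t_half_rat_h = half_life(absorption_rate_constant(p, phys, ts)),
        t_half_human_h =
          half_life(absorption_rate_constant(p, phys_h, ts)),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Format a half-life with a magnitude-appropriate unit
#'
#' Presentation helper choosing hours, minutes or seconds; internal values
#' stay in hours everywhere.
#'
#' @param t_half_h Half-life in hours.
#' @param digits Significant digits.
#' @return Character, e.g. `"1.2 h"`, `"57 min"`, `"2.7 s"`.
#' @export
format_half_life <- function(t_half_h, digits = 3) {
  vapply(t_half_h, function(h) {
    if (h >= 1) paste(signif(h, digits), "h")
    else if (h >= 1 / 60) paste(signif(h * 60, digits), "min")
    else paste(signif(h * 3600, digits), "s")
  }, character(1))
}

#' Tissue-to-plasma ratio as a percentage of its steady-state value
#'
#' For each tissue sampling time, each replicate tissue concentration is
#' divided by the plasma concentration at that time (mean of plasma
#' replicates if several) and by Kp, times 100; replicate-level percentages
#' are then aggregated to mean and standard deviation. 100% means the
#' tissue-to-plasma ratio has reached the model's steady-state value Kp.
#'
#' @param records Long-format records containing plasma rows and rows for
#'   `tissue`, with common times.
#' @param tissue Which lung tissue to evaluate.
#' @param kp Partition coefficient for that tissue.
#' @return `data.frame` with columns `time`, `mean_pct`, `sd_pct`, `n`.
#' @export
percent_of_steady_state <- function(records, tissue, kp) {
  tis <- records[records$matrix == tissue, , drop = FALSE]
  pla <- records[records$matrix == "plasma", , drop = FALSE]
  if (!nrow(tis)) stop("no records for tissue ", tissue)
  out <- lapply(split(tis, tis$time), function(chunk) {
    tm <- chunk$time[1]
    cp <- pla$conc[pla$time == tm]
    if (!length(cp))
      stop("no plasma observation at time ", tm, " h")
    cp <- mean(cp)
    if (cp <= 0) stop("zero plasma concentration at time ", tm, " h")
    pct <- 100 * (chunk$conc / cp) / kp
    data.frame(time = tm, mean_pct = mean(pct),
               sd_pct = if (length(pct) > 1) stats::sd(pct) else NA_real_,
               n = length(pct))
  })
  res <- do.call(rbind, out)
  res[order(res$time), , drop = FALSE]
}
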