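test_that("systemic fit recovers two-compartment truth from noise-free plasma data", {
  sal <- fx$drugs$salmeterol
  rec <- generate_study_data(sal, phys_rat, design_default,
                             error_model(0, 0, 1))
  ft <- fit_systemic(rec, n_cpt = 2, d = design_default)
  truth <- c(cl = 3.86, v_c = 0.123, q_ic = 3.24, v_p = 3.77)
  expect_lt(max(abs(ft$estimates - truth) / truth), 1e-3)
  expect_named(ft$cv_percent, names(truth))
  expect_true(is.finite(ft$objective))
  expect_equal(ft$n_obs, 65)
})

test_that("one-compartment data fitted with one compartment leaves machine-precision residuals", {
  ind <- fx$drugs$indomethacin
  rec <- generate_study_data(ind, phys_rat, design_default,
                             error_model(0, 0, 1))
  ft <- fit_systemic(rec, n_cpt = 1, d = design_default)
  expect_lt(ft$objective, 1e-12)
  expect_lt(max(abs(ft$estimates - c(cl = 0.0691, v_c = 0.154)) /
                  c(0.0691, 0.154)), 1e-4)
})

test_that("systemic fit demands more observations than parameters", {
  rec <- concentration_records("x", "plasma", c(0.5, 1, 2),
                               c(0.1, 0.2, 0.1))
  expect_error(fit_systemic(rec, n_cpt = 2, d = design_default),
               "insufficient data")
})

test_that("shared tissue fit recovers Kp and blood flows on noise-free data", {
  drugs <- fx$drugs[c("salmeterol", "indomethacin")]
  rec <- noise_free_records(drugs, phys_rat, design_default)
  tis <- rec[rec$matrix %in% lung_tissues(), ]
  ft <- fit_tissue_shared(tis, drugs, phys_rat, design_default,
                          n_starts = 1)
  truth <- truth_stage2(drugs, phys_rat)
  expect_lt(max(abs(ft$estimates - truth[names(ft$estimates)]) /
                  truth[names(ft$estimates)]), 0.01)
})

test_that("literature-prior and random multi-starts reach the same optimum on noise-free data", {
  drugs <- fx$drugs[c("salmeterol", "indomethacin")]
  rec <- noise_free_records(drugs, phys_rat, design_default)
  tis <- rec[rec$matrix %in% lung_tissues(), ]
  # priors: alveolar flow from literature cardiac output, airway flows
  # from ~2% of cardiac output split by tissue weight
  phys_lit <- phys_rat
  phys_lit$q_a <- 15.1
  phys_lit$q_t <- 0.02 * 15.1 * phys_rat$w_t / (phys_rat$w_t + phys_rat$w_b)
  phys_lit$q_b <- 0.02 * 15.1 * phys_rat$w_b / (phys_rat$w_t + phys_rat$w_b)
  f_lit <- fit_tissue_shared(tis, drugs, phys_lit, design_default,
                             n_starts = 1)
  f_rand <- fit_tissue_shared(tis, drugs, phys_rat, design_default,
                              n_starts = 5, seed = 99L)
  expect_equal(f_lit$estimates, f_rand$estimates, tolerance = 1e-4)
})

test_that("a tissue observed at a single time point is flagged structurally non-identifiable", {
  sal <- fx$drugs$salmeterol
  d1 <- study_design(tissue_times = 2)
  rec <- noise_free_records(list(salmeterol = sal), phys_rat, d1)
  tis <- rec[rec$matrix %in% lung_tissues(), ]
  expect_error(
    fit_tissue_shared(tis, list(salmeterol = sal), phys_rat, d1),
    "non-identifiable.*trachea")
})

test_that("estimates are invariant to record order", {
  drugs <- fx$drugs[c("salmeterol", "indomethacin")]
  rec <- do.call(rbind, lapply(drugs, function(p)
    generate_study_data(p, phys_rat, design_default,
                        error_model(0.15, 0.25, 7))))
  tis <- rec[rec$matrix %in% lung_tissues(), ]
  perm <- tis[rev(seq_len(nrow(tis))), ]
  f1 <- fit_tissue_shared(tis, drugs, phys_rat, design_default,
                          n_starts = 1)
  f2 <- fit_tissue_shared(perm, drugs, phys_rat, design_default,
                          n_starts = 1)
  expect_identical(f1$estimates, f2$estimates)
  expect_identical(f1$objective, f2$objective)
})

test_that("with blood flows fixed at truth, refitting Kp alone reproduces Kp truth", {
  drugs <- fx$drugs[c("salmeterol", "fluticasone")]
  rec <- noise_free_records(drugs, phys_rat, design_default)
  tis <- rec[rec$matrix %in% lung_tissues(), ]
  ft <- fit_tissue_shared(tis, drugs, phys_rat, design_default,
                          n_starts = 1, fix_flows = TRUE)
  truth <- truth_stage2(drugs, phys_rat)
  expect_false(any(grepl("^q_", names(ft$estimates))))
  expect_lt(max(abs(ft$estimates - truth[names(ft$estimates)]) /
                  truth[names(ft$estimates)]), 0.001)
})

test_that("whole-lung comparator fits lumped data but describes regional data worse", {
  sal <- fx$drugs$salmeterol
  d <- design_default
  wl <- profiles_to_records(
    tissue_profile(sal, phys_rat, "whole_lung", d, d$tissue_times))
  ft <- fit_whole_lung(wl, list(salmeterol = sal), phys_rat, d,
                       n_starts = 1)
  # lumped Kp lands near the late-time mass-weighted tissue ratio,
  # which is dominated by the alveolar compartment
  expect_gt(ft$estimates[["kp_lung.salmeterol"]], sal$kp_b)
  expect_lt(ft$estimates[["kp_lung.salmeterol"]], sal$kp_a * 1.3)

  # whole-lung predictions scored against the regional observations
  tis_obs <- do.call(rbind, lapply(lung_tissues(), function(ts)
    profiles_to_records(tissue_profile(sal, phys_rat, ts, d,
                                       d$tissue_times))))
  p_wl <- sal
  p_wl$kp_lung <- ft$estimates[["kp_lung.salmeterol"]]
  phys_wl <- phys_rat
  phys_wl$q_lung <- ft$estimates[["q_lung"]]
  pred_wl <- rep(tissue_profile(p_wl, phys_wl, "whole_lung", d,
                                d$tissue_times)$concs,
                 times = length(lung_tissues()))
  gof_wl <- goodness_of_fit(tis_obs$conc, pred_wl)
  gof_regional <- goodness_of_fit(tis_obs$conc, tis_obs$conc)
  expect_lt(gof_wl$r_squared, gof_regional$r_squared)
})

test_that("goodness of fit follows its definition at the boundary cases", {
  obs <- c(1, 2, 4, 8)
  expect_equal(goodness_of_fit(obs, obs),
               list(r_squared = 1, frac_within_twofold = 1, n = 4))
  expect_equal(goodness_of_fit(obs, rep(mean(obs), 4))$r_squared, 0)
  g3 <- goodness_of_fit(obs, 3 * obs)
  expect_equal(g3$frac_within_twofold, 0)
  expect_lt(g3$r_squared, 0)  # negative R-squared is admissible
  expect_error(goodness_of_fit(numeric(0), numeric(0)), "empty")
})
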