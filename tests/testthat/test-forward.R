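test_that("plasma profile matches textbook closed forms and initial/steady-state limits", {
  d <- design_default
  # one-compartment drug during infusion: C(t) = (R/CL)(1 - e^(-CL t / Vc))
  ind <- fx$drugs$indomethacin
  tt <- c(0.1, 0.5, 0.9)
  expect_equal(plasma_profile(ind, d, tt)$concs,
               d$infusion_rate / ind$cl *
                 (1 - exp(-ind$cl * tt / ind$v_c)),
               tolerance = 1e-12)
  # steady state under a very long infusion -> rate/CL
  d_long <- study_design(infusion_duration = 5000)
  expect_equal(plasma_profile(ind, d_long, 4000)$concs,
               d_long$infusion_rate / ind$cl, tolerance = 1e-9)
  sal <- fx$drugs$salmeterol
  expect_equal(plasma_profile(sal, d_long, 4000)$concs,
               d_long$infusion_rate / sal$cl, tolerance = 1e-9)
  # initial condition and continuity at the infusion stop
  expect_equal(plasma_profile(sal, d, 0)$concs, 0)
  eps <- 1e-9
  expect_equal(plasma_profile(sal, d, 1 - eps)$concs,
               plasma_profile(sal, d, 1 + eps)$concs, tolerance = 1e-6)
  expect_error(plasma_profile(sal, d, c(-0.1, 1)), "non-negative")
})

test_that("closed-form and ODE backends agree below 1e-6 relative for all drugs and matrices", {
  d <- design_default
  tt <- seq(0.05, 4, by = 0.05)
  for (dg in names(fx$drugs)) {
    p <- fx$drugs[[dg]]
    ode <- ode_backend(p, phys_rat, d, tt)
    cf <- c(list(plasma = plasma_profile(p, d, tt)),
            lapply(stats::setNames(lung_tissues(), lung_tissues()),
                   function(ts) tissue_profile(p, phys_rat, ts, d, tt)))
    for (m in names(cf)) {
      rel <- abs(cf[[m]]$concs - ode[[m]]$concs) / ode[[m]]$concs
      expect_lt(max(rel), 1e-6, label = paste(dg, m))
    }
  }
})

test_that("tissue compartments are virtual: plasma is untouched and zero infusion gives zero everywhere", {
  d <- design_default
  sal <- fx$drugs$salmeterol
  tt <- c(0.25, 1, 3)
  # ODE system with tissue compartments attached reproduces the
  # tissue-free closed-form plasma solution
  expect_equal(ode_backend(sal, phys_rat, d, tt)$plasma$concs,
               plasma_profile(sal, d, tt)$concs, tolerance = 1e-7)
  d0 <- study_design(infusion_rate = 0)
  out <- ode_backend(sal, phys_rat, d0, tt)
  for (m in names(out)) expect_equal(out[[m]]$concs, rep(0, 3))
  expect_equal(tissue_profile(sal, phys_rat, "bronchi", d0, tt)$concs,
               rep(0, 3))
})

test_that("linearity: scaling the infusion rate scales every concentration and fixes all ratios", {
  sal <- fx$drugs$salmeterol
  d1 <- study_design(infusion_rate = 1)
  d3 <- study_design(infusion_rate = 3.7)
  tt <- c(0.25, 0.75, 2, 4)
  expect_equal(plasma_profile(sal, d3, tt)$concs,
               3.7 * plasma_profile(sal, d1, tt)$concs,
               tolerance = 1e-12)
  for (ts in lung_tissues())
    expect_equal(tissue_profile(sal, phys_rat, ts, d3, tt)$concs,
                 3.7 * tissue_profile(sal, phys_rat, ts, d1, tt)$concs,
                 tolerance = 1e-12)
})

test_that("tissue-to-plasma ratio rises monotonically to Kp under constant infusion", {
  d_on <- study_design(infusion_duration = 100)
  tt <- seq(0.1, 50, by = 0.1)
  for (dg in c("salmeterol", "fluticasone")) {
    p <- fx$drugs[[dg]]
    cp <- plasma_profile(p, d_on, tt)$concs
    for (ts in lung_tissues()) {
      ratio <- tissue_profile(p, phys_rat, ts, d_on, tt)$concs / cp
      kp <- kp_of(p, ts)
      expect_true(all(diff(ratio) > -1e-10), label = paste(dg, ts))
      expect_true(all(ratio <= kp * (1 + 1e-9)), label = paste(dg, ts))
      expect_equal(ratio[length(ratio)], kp, tolerance = 0.05)
    }
  }
})

test_that("fast-equilibrating tissue with Kp = 1 tracks plasma", {
  sal <- fx$drugs$salmeterol
  fast <- sal
  fast$kp_t <- 1
  # inflate tracheal flow so Q*fu/V is huge relative to plasma dynamics
  phys_fast <- phys_rat
  phys_fast$q_t <- 1e5
  tt <- c(0.25, 0.75, 2, 4)
  expect_equal(tissue_profile(fast, phys_fast, "trachea", design_default,
                              tt)$concs,
               plasma_profile(fast, design_default, tt)$concs,
               tolerance = 1e-3)
})

test_that("whole-lung profile is the tissue-weight-weighted mean of regional profiles when Kp_lung is unset", {
  sal_nolung <- fx$drugs$salmeterol
  sal_nolung$kp_lung <- NULL
  tt <- c(0.25, 0.75, 2, 4)
  parts <- sapply(lung_tissues(), function(ts)
    tissue_profile(sal_nolung, phys_rat, ts, design_default, tt)$concs)
  w <- c(phys_rat$w_t, phys_rat$w_b, phys_rat$w_a) / phys_rat$w_lung
  expect_equal(tissue_profile(sal_nolung, phys_rat, "whole_lung",
                              design_default, tt)$concs,
               as.numeric(parts %*% w), tolerance = 1e-12)
})

test_that("simulate_study returns the study's four profiles at the design times", {
  prof <- simulate_study(fx$drugs$salmeterol, phys_rat, design_default)
  expect_setequal(names(prof), c("plasma", lung_tissues()))
  for (ts in lung_tissues())
    expect_equal(prof[[ts]]$times, c(0.25, 0.75, 2, 4))
  # empty tissue schedule -> empty tissue profiles
  d_empty <- study_design(tissue_times = numeric(0))
  prof0 <- simulate_study(fx$drugs$salmeterol, phys_rat, d_empty)
  expect_length(prof0$trachea$times, 0)
  expect_error(tissue_profile(fx$drugs$salmeterol, phys_rat, "liver",
                              design_default, 1),
               "unknown tissue")
})
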