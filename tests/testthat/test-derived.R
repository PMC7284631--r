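test_that("absorption rate constant follows Q*fu/(V*Kp) and its proportionalities", {
  sal <- fx$drugs$salmeterol
  ka <- absorption_rate_constant(sal, phys_rat, "trachea")
  expect_equal(ka, phys_rat$q_t * sal$fu_plasma /
                 (phys_rat$w_t * sal$kp_t), tolerance = 1e-12)
  expect_equal(ka, 0.580, tolerance = 0.005)

  # Kp = 1, Q*fu = V  ->  k_a = 1/h
  unit <- drug_parameters("unit", cl = 1, v_c = 1, fu_plasma = 0.5,
                          kp_t = 1, kp_b = 1, kp_a = 1)
  phys_unit <- physiology_parameters(w_t = 0.5, w_b = 0.5, w_a = 0.5,
                                     q_t = 1, q_b = 1, q_a = 1)
  expect_equal(absorption_rate_constant(unit, phys_unit, "trachea"), 1)

  doubled <- sal
  doubled$kp_t <- 2 * sal$kp_t
  expect_equal(absorption_rate_constant(doubled, phys_rat, "trachea"),
               ka / 2, tolerance = 1e-12)
  expect_error(absorption_rate_constant(sal, phys_rat, "pleura"),
               "unknown tissue")
})

test_that("half-life is ln(2)/k_a and rejects non-positive rates", {
  expect_equal(half_life(log(2)), 1)
  expect_error(half_life(0), "positive")
  expect_error(half_life(-1), "positive")
})

test_that("rat half-lives match the published table within 5%", {
  for (dg in names(printed_t_half_rat)) {
    p <- fx$drugs[[dg]]
    for (ts in names(printed_t_half_rat[[dg]])) {
      expect_equal(half_life(absorption_rate_constant(p, phys_rat, ts)),
                   printed_t_half_rat[[dg]][[ts]], tolerance = 0.05,
                   label = paste(dg, ts))
    }
  }
  # whole-lung comparator values
  expect_equal(half_life(absorption_rate_constant(fx$drugs$salmeterol,
                                                  phys_rat, "whole_lung")),
               48.3 / 60, tolerance = 0.05)
})

test_that("allometric scaling multiplies every half-life by (BW_h/BW_r)^0.25 and is identity at equal weight", {
  tab <- half_life_table(fx$drugs, phys_rat, bw_human = 70)
  expect_equal(tab$t_half_human_h / tab$t_half_rat_h,
               rep((70 / 0.28)^0.25, nrow(tab)), tolerance = 1e-10)
  same <- scale_to_human(phys_rat, 0.28, 0.28)
  expect_equal(same$q_t, phys_rat$q_t)
  expect_equal(same$w_a, phys_rat$w_a)
  expect_error(scale_to_human(phys_rat, -1, 70), "positive")
})

test_that("half-life ordering is alveolar < bronchi < trachea, with whole lung between alveolar and bronchi", {
  tab <- half_life_table(fx$drugs, phys_rat)
  for (dg in names(fx$drugs)) {
    t_of <- function(ts) tab$t_half_rat_h[tab$drug == dg &
                                            tab$tissue == ts]
    expect_lt(t_of("alveolar"), t_of("bronchi"))
    expect_lt(t_of("bronchi"), t_of("trachea"))
    expect_gt(t_of("whole_lung"), t_of("alveolar"))
    expect_lt(t_of("whole_lung"), t_of("bronchi"))
  }
})

test_that("tissue unbound fraction is fu/Kp and anchors the free EC50", {
  sal <- fx$drugs$salmeterol
  expect_equal(tissue_fu(sal$fu_plasma, sal$kp_b), 7.53e-4,
               tolerance = 0.001)
  expect_equal(tissue_fu(0.3, 1), 0.3)
  expect_equal(36 * tissue_fu(sal$fu_plasma, sal$kp_b), 0.0271,
               tolerance = 1e-6)
  expect_error(tissue_fu(0, 2), "positive")
})

test_that("percent of steady state is 100 at equilibrium and separates slow from fast drugs", {
  sal <- fx$drugs$salmeterol
  # exact equilibrium records: C_tis = Kp * C_p
  rec <- rbind(
    concentration_records("salmeterol", "plasma", c(1, 2), c(5, 3)),
    concentration_records("salmeterol", "trachea", c(1, 2),
                          sal$kp_t * c(5, 3)))
  pss <- percent_of_steady_state(rec, "trachea", sal$kp_t)
  expect_equal(pss$mean_pct, c(100, 100))

  # sustained infusion covering the observation window: salmeterol
  # trachea is far from equilibrium at 4 h, linezolid and indomethacin
  # equilibrate within the first samples
  d_on <- study_design(infusion_duration = 6)
  sim_pct <- function(p, ts, tm) {
    kp <- kp_of(p, ts)
    rec <- rbind(
      profiles_to_records(plasma_profile(p, d_on, tm)),
      profiles_to_records(tissue_profile(p, phys_rat, ts, d_on, tm)))
    percent_of_steady_state(rec, ts, kp)$mean_pct
  }
  expect_lt(sim_pct(sal, "trachea", 4), 100)
  expect_gt(sim_pct(fx$drugs$linezolid, "alveolar", 0.25), 95)
  expect_gt(sim_pct(fx$drugs$indomethacin, "alveolar", 0.75), 95)

  zero <- concentration_records("x", "plasma", 1, 0)
  one <- concentration_records("x", "trachea", 1, 1)
  expect_error(percent_of_steady_state(rbind(zero, one), "trachea", 2),
               "zero plasma")
})

test_that("half-life formatting picks hours, minutes or seconds by magnitude", {
  expect_equal(format_half_life(c(1.1954, 57 / 60, 2.7 / 3600)),
               c("1.2 h", "57 min", "2.7 s"))
})
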