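# Shared fixtures and small oracles used across test files.

fx <- default_fixtures(quiet = TRUE)
phys_rat <- fx$physiology
design_default <- study_design()

# Published rat absorption half-lives (hours) used as external anchors.
printed_t_half_rat <- list(
  salmeterol   = c(trachea = 1.2, bronchi = 57 / 60, alveolar = 45 / 60),
  fluticasone  = c(trachea = 52.4 / 60, bronchi = 18.6 / 60,
                   alveolar = 5.99 / 60),
  indomethacin = c(trachea = 14 / 3600, bronchi = 2.7 / 3600,
                   alveolar = 1.5 / 3600))

kp_of <- function(p, tissue) {
  switch(tissue, trachea = p$kp_t, bronchi = p$kp_b, alveolar = p$kp_a,
         whole_lung = p$kp_lung)
}

truth_stage2 <- function(drugs, phys) {
  kp <- unlist(lapply(names(drugs), function(dg) {
    p <- drugs[[dg]]
    stats::setNames(c(p$kp_t, p$kp_b, p$kp_a),
                    paste0("kp_", c("t", "b", "a"), ".", dg))
  }))
  c(kp, q_t = phys$q_t, q_b = phys$q_b, q_a = phys$q_a)
}

noise_free_records <- function(drugs, phys, d) {
  do.call(rbind, lapply(drugs, function(p)
    generate_study_data(p, phys, d, error_model(0, 0, 1))))
}
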