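# Systemic disposition, tissue affinity and lung physiology for the four
# model drugs (all kinetic parameters normalized to bodyweight).
#
# Fractions unbound in plasma are not stored directly: each drug carries an
# "fu_anchor" describing the published derived quantity from which fu is
# reconstructed at load time (see derive_fu_plasma()).  Linezolid has no
# self-consistent anchor and defaults to fu = 1 with a warning.
drugs:
  salmeterol:
    cl: 3.86        # L/h/kg
    v_c: 0.123      # L/kg
    q_ic: 3.24      # L/h/kg
    v_p: 3.77       # L/kg
    kp_t: 6.52
    kp_b: 18.6
    kp_a: 39.3
    kp_lung: 37.7
    fu_anchor:
      type: free_ec50          # fu = ec50_free * Kp_B / ec50_total
      tissue: bronchi
      ec50_total_nM: 36.0
      ec50_free_nM: 0.0271
  fluticasone:
    cl: 3.37
    v_c: 0.223
    q_ic: 4.72
    v_p: 2.41
    kp_t: 5.21
    kp_b: 6.64
    kp_a: 5.84
    kp_lung: 6.21
    fu_anchor:
      type: half_life          # fu = ln(2) * V * Kp / (Q * t_half)
      tissue: trachea
      t_half_min: 52.4
  linezolid:
    cl: 0.279
    v_c: 0.320
    q_ic: 2.79
    v_p: 0.628
    kp_t: 0.404
    kp_b: 0.534
    kp_a: 0.785
    kp_lung: 0.781
    fu_anchor:
      type: none               # published half-lives imply fu > 1; left at 1.0
  indomethacin:
    cl: 0.0691
    v_c: 0.154
    kp_t: 0.356
    kp_b: 0.249
    kp_a: 0.384
    kp_lung: 0.347
    fu_anchor:
      type: half_life
      tissue: trachea
      t_half_s: 14.0
physiology:
  w_t: 0.0002      # kg tissue / kg bodyweight
  w_b: 0.0008
  w_a: 0.004
  w_lung: 0.005
  q_t: 0.054       # L/h/kg
  q_b: 0.777
  q_a: 10.6
  q_lung: 11.6
  bw: 0.28         # kg, mean rat bodyweight
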