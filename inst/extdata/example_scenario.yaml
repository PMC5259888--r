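# Synthetic open-population scenario: adult CVD-like conditions, two sexes by
# five age bands, constant per-stratum incidence hazards, two-year surveys.
T_years: 2
n_waves: 4
mode: expected_value
n_per_stratum: 5000
seed: 1
m_substeps: 100
start_year: 2000
strata:
  - {sex: male, age_lo: 35, age_hi: 45, hazard: 0.003, p_init: 0.030, SP: 0.95, SN: 0.996}
  - {sex: male, age_lo: 45, age_hi: 55, hazard: 0.006, p_init: 0.060, SP: 0.93, SN: 0.993}
  - {sex: male, age_lo: 55, age_hi: 65, hazard: 0.010, p_init: 0.100, SP: 0.90, SN: 0.985}
  - {sex: male, age_lo: 65, age_hi: 75, hazard: 0.016, p_init: 0.150, SP: 0.85, SN: 0.965}
  - {sex: male, age_lo: 75, hazard: 0.024, p_init: 0.200, SP: 0.78, SN: 0.900}
  - {sex: female, age_lo: 35, age_hi: 45, hazard: 0.0015, p_init: 0.015, SP: 0.96, SN: 0.997}
  - {sex: female, age_lo: 45, age_hi: 55, hazard: 0.003, p_init: 0.030, SP: 0.94, SN: 0.995}
  - {sex: female, age_lo: 55, age_hi: 65, hazard: 0.006, p_init: 0.060, SP: 0.91, SN: 0.988}
  - {sex: female, age_lo: 65, age_hi: 75, hazard: 0.011, p_init: 0.100, SP: 0.86, SN: 0.972}
  - {sex: female, age_lo: 75, hazard: 0.018, p_init: 0.160, SP: 0.79, SN: 0.920}
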