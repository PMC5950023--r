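# Contemporary 30-y base-case parameter bundle.
#
# Values marked "approx" are documented approximations: the primary source
# reports them only in supplementary tables, so plausible contemporary
# values are used instead.  Acceptance checks on this bundle are
# directional or structural and do not depend on their exact values.
metadata:
  name: naaasp-basecase
  notes:
    discounting: "costs and QALYs both at 3.5%/y"
    waits: "discovery-to-consultation 71 d, consultation-to-surgery 59 d"
    ct_offset: "CT measures outer-to-outer, on average 0.24 cm above ultrasound"
    horizon: "30-y fixed horizon for men entering at 65"
    baseline_diameter: "approx; mixture with exact AAA prevalence 0.016 (contemporary screening prevalence); lognormal body near 1.9 cm below 3.0 cm, gamma excess above it (contemporary AAAs skew smaller than trial-era ones)"
    growth_rate: "approx; band-dependent relative growth on the log scale: ~1.5%/y (SD 1.5%) for 2.0-2.9 cm baselines (extrapolated below the diagnosis range) and ~5.5%/y (SD 2.5%) for AAA baselines, surveillance-meta-analysis scale; zero below 2.0 cm"
    rupture_hazard: "approx; ~3.5%/y at the 5.5 cm referral threshold, log-hazard slope 1.28 per cm (meta-analysis-style diameter dependence)"
    measurement_error: "approx; contemporary standardized-protocol repeatability: 0.1 cm SD ultrasound, 0.15 cm SD CT"
    incidental_detection: "approx; constant 0.03/y once past the diagnosis threshold (opportunistic abdominal imaging)"
    dropout: "approx; contemporary recall systems retain nearly all men under surveillance; ~0.1% permanent loss per scheduled rescan"
    life_table: "approx; Gompertz fit 0.012*exp(0.095*(age-65)) to contemporary national male mortality"
    costs: "approx; contemporary unit costs (2010-11 GBP) including EVAR"
    evar: "approx; ~64% of elective repairs endovascular"
    attendance: "approx; 75% first-screen attendance"
    utilities: "population-norm utility weights by age band applied to life-years"
global_fixed:
  invitation_age: 65
  time_horizon_years: 30
  censoring:
    type: fixed
  discount_rate_cost: 0.035
  discount_rate_effect: 0.035
  wait_discovery_to_consultation_days: 71
  wait_consultation_to_surgery_days: 59
  ct_offset_cm: 0.24
  ultrasound_sd_cm: 0.1
  ct_sd_cm: 0.15
  zero_growth_cutoff_cm: 2.0
  baseline_diameter:
    family: aaa_mixture
    prevalence: 0.016
    meanlog: 0.641854
    sdlog: 0.213
    aaa_from: 3.0
    excess_shape: 1.5
    excess_rate: 2.4
  growth_rate:
    band_from: [2.0, 3.0]
    mean: [0.015, 0.055]
    sd: [0.015, 0.025]
  rupture_hazard:
    intercept: -3.352
    slope: 1.28
    reference_cm: 5.5
  incidental_detection_rate: 0.03
  oversampling_multiplier: 31.25
  policy: current
  life_table:
    start_age: 65
    rates: [0.01200, 0.01320, 0.01451, 0.01596, 0.01755, 0.01930, 0.02122,
            0.02333, 0.02566, 0.02822, 0.03103, 0.03412, 0.03752, 0.04126,
            0.04537, 0.04989, 0.05487, 0.06033, 0.06635, 0.07296, 0.08023,
            0.08823, 0.09702, 0.10669, 0.11732, 0.12901, 0.14187, 0.15601,
            0.17156, 0.18865, 0.20745, 0.22813, 0.25086, 0.27586, 0.30336,
            0.33359, 0.36683, 0.40339, 0.44359, 0.48780]
  utilities:
    age_from: [65, 75, 85]
    weight: [0.78, 0.75, 0.71]
  costs:
    invitation: 1.70
    scan: 32.20
    consultation: 300.0
    elective_open: 9946.0
    elective_evar: 12432.0
    emergency_open: 14837.0
    emergency_evar: 14184.0
global_uncertain:
  attendance_prob:
    family: beta
    shape1: 75.0
    shape2: 25.0
  dropout_prob:
    family: beta
    shape1: 0.2
    shape2: 199.8
  contraindication_prob:
    family: beta
    shape1: 12.0
    shape2: 88.0
  elective_mortality_open:
    family: beta
    shape1: 26.0
    shape2: 974.0
  elective_mortality_evar:
    family: beta
    shape1: 6.0
    shape2: 994.0
  emergency_mortality:
    family: beta
    shape1: 342.0
    shape2: 658.0
  emergency_surgery_prob:
    family: beta
    shape1: 368.0
    shape2: 632.0
  evar_proportion:
    family: beta
    shape1: 64.0
    shape2: 36.0
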