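# Trial-era (4-y validation) parameter bundle.
#
# Values marked "approx" are documented approximations: the primary source
# reports them only in supplementary tables, so plausible trial-era values
# are used instead.  Validation-style acceptance checks in this package do
# not depend on their exact values.
metadata:
  name: mass-validation
  notes:
    discounting: "life-years at 1.5%/y and costs at 6%/y, the original 4-y follow-up analysis rates"
    waits: "discovery-to-consultation 71 d, consultation-to-surgery 59 d"
    ct_offset: "CT measures outer-to-outer, on average 0.24 cm above ultrasound"
    censoring: "4-y follow-up censoring close to Uniform(3, 5.25) years, shared within pairs"
    baseline_diameter: "approx; mixture with exact AAA prevalence 0.049 (trial screening prevalence); lognormal body near 1.9 cm below 3.0 cm, gamma excess above it sized so detected AAAs split roughly 85/11/4 percent over 3.0-4.4 / 4.5-5.4 / >=5.5 cm"
    growth_rate: "approx; band-dependent relative growth on the log scale: ~2%/y (SD 1.5%) for 2.0-2.9 cm baselines (extrapolated below the diagnosis range) and ~6%/y (SD 3%) for AAA baselines, in line with screen-detected surveillance growth; zero below 2.0 cm"
    rupture_hazard: "approx; ~4%/y at the 5.5 cm referral threshold, log-hazard slope 1.3 per cm"
    measurement_error: "approx; 0.2 cm SD for both modalities"
    incidental_detection: "approx; constant 0.05/y once past the diagnosis threshold (not directly observed in the trial)"
    life_table: "approx; Gompertz fit 0.025*exp(0.075*(age-65)) matching ~11% non-AAA mortality over the 4.125-y mean follow-up in men aged 65-74"
    costs: "approx; trial-era unit costs (2000-01 GBP); no EVAR in that era"
    attendance: "trial reattendance ~80%"
    emergency_surgery_prob: "approx; ~45% of ruptures reach emergency surgery (62 operations / 138 ruptures in the unscreened arm)"
    utilities: "validation reports life-years, not QALYs; weights fixed at 1"
global_fixed:
  invitation_age: 65
  time_horizon_years: 5.25
  censoring:
    type: uniform
    min: 3.0
    max: 5.25
  discount_rate_cost: 0.06
  discount_rate_effect: 0.015
  wait_discovery_to_consultation_days: 71
  wait_consultation_to_surgery_days: 59
  ct_offset_cm: 0.24
  ultrasound_sd_cm: 0.2
  ct_sd_cm: 0.2
  zero_growth_cutoff_cm: 2.0
  baseline_diameter:
    family: aaa_mixture
    prevalence: 0.049
    meanlog: 0.641854
    sdlog: 0.276049
    aaa_from: 3.0
    excess_shape: 1.5
    excess_rate: 1.875
  growth_rate:
    band_from: [2.0, 3.0]
    mean: [0.02, 0.06]
    sd: [0.015, 0.03]
  rupture_hazard:
    intercept: -3.22
    slope: 1.3
    reference_cm: 5.5
  incidental_detection_rate: 0.05
  oversampling_multiplier: 10.2
  policy: current
  life_table:
    start_age: 65
    rates: [0.02500, 0.02695, 0.02905, 0.03131, 0.03375, 0.03637, 0.03921,
            0.04226, 0.04555, 0.04910, 0.05293, 0.05705, 0.06149, 0.06628,
            0.07144, 0.07701, 0.08300, 0.08947, 0.09644, 0.10395, 0.11204,
            0.12077, 0.13017, 0.14031, 0.15124, 0.16302, 0.17572, 0.18940,
            0.20415, 0.22005, 0.23719, 0.25567, 0.27558, 0.29704, 0.32018,
            0.34511, 0.37199, 0.40097, 0.43219, 0.46586]
  utilities:
    age_from: [65]
    weight: [1.0]
  costs:
    invitation: 1.64
    scan: 21.78
    consultation: 300.0
    elective_open: 6909.0
    elective_evar: 6909.0
    emergency_open: 11176.0
    emergency_evar: 11176.0
global_uncertain:
  attendance_prob:
    family: beta
    shape1: 80.3
    shape2: 19.7
  dropout_prob:
    family: beta
    shape1: 7.0
    shape2: 93.0
  contraindication_prob:
    family: beta
    shape1: 10.0
    shape2: 90.0
  elective_mortality_open:
    family: beta
    shape1: 14.0
    shape2: 236.0
  elective_mortality_evar:
    family: beta
    shape1: 14.0
    shape2: 236.0
  emergency_mortality:
    family: beta
    shape1: 37.0
    shape2: 63.0
  emergency_surgery_prob:
    family: beta
    shape1: 45.0
    shape2: 55.0
  evar_proportion:
    family: fixed
    value: 0.0
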