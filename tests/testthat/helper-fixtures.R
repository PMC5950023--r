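# Shared helpers: small bundles, random model pieces, and independent
# numerical oracles used to cross-check the closed-form implementations.

quick_bundle <- function(name = "naaasp-basecase") builtin_bundle(name)

# a trajectory with randomized but well-behaved parameters
rand_traj <- function() {
  aorta_trajectory(
    baseline_diameter = runif(1, 2.1, 6.5),
    log_growth_rate = runif(1, 0.005, 0.09),
    zero_growth_cutoff = 2.0
  )
}

rand_hazard <- function() {
  rupture_hazard_params(
    intercept = runif(1, -5, -2.5),
    slope = runif(1, 0.3, 1.6),
    reference_diameter = 5.5
  )
}

# Brute-force rupture-time oracle: numerically integrates the hazard along
# the trajectory (adaptive quadrature) and bisects H(t) = -log(u).
# Independent of the closed-form exponential-integral path used by
# sample_rupture_time().
oracle_rupture_time <- function(traj, hz, u, cap = 85) {
  target <- -log(u)
  # integrand clamped to avoid overflow at biologically absurd diameters
  # far beyond the root (H there is astronomically above any target)
  H <- function(t) {
    if (t == 0) return(0)
    stats::integrate(function(s) pmin(rupture_hazard(hz, diameter_at_time(traj, s)), 1e10),
                     0, t, rel.tol = 1e-12, abs.tol = 1e-13,
                     subdivisions = 400L)$value
  }
  if (H(cap) < target) return(Inf)
  lo <- 0; hi <- cap
  while (hi - lo > 1e-9) {
    mid <- (lo + hi) / 2
    if (H(mid) < target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# draw with every probability fixed (handy for forcing pathways)
forced_draw <- function(attendance = 1, dropout = 0, contraindication = 0,
                        m_open = 0, m_evar = 0, m_emerg = 0,
                        p_emerg = 1, evar = 0) {
  structure(list(attendance_prob = attendance,
                 contraindication_prob = contraindication,
                 dropout_prob = dropout,
                 elective_mortality_evar = m_evar,
                 elective_mortality_open = m_open,
                 emergency_mortality = m_emerg,
                 emergency_surgery_prob = p_emerg,
                 evar_proportion = evar),
            class = "aaa_draw", seed = NA_integer_, draw_index = 0L)
}

# construct a twin pair from explicit shared latent values
manual_pair <- function(baseline, slope, t_nd = 100, t_rupture = Inf,
                        contraindicated = FALSE, gets_evar = FALSE,
                        survives_elective = TRUE, survives_emergency = TRUE,
                        gets_emergency_surgery = TRUE,
                        would_attend = TRUE, t_censor = 30,
                        inc_wait = Inf, weight = 1, diag = 3.0) {
  traj <- aorta_trajectory(baseline, slope)
  structure(list(
    shared = list(trajectory = traj,
                  baseline_diameter = baseline,
                  t_cross = time_to_threshold(traj, diag),
                  non_aaa_death_time = t_nd,
                  rupture_time = t_rupture,
                  contraindicated = contraindicated,
                  gets_evar = gets_evar,
                  survives_elective_surgery = survives_elective,
                  survives_emergency_surgery = survives_emergency,
                  gets_emergency_surgery = gets_emergency_surgery,
                  would_attend = would_attend,
                  censor_time = t_censor,
                  incidental_wait = inc_wait,
                  weight = weight),
    invited = NULL, non_invited = NULL), class = "twin_pair")
}

DAYS <- 365.25
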