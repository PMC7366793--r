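# Shared fixture builders. Everything is generated in code at test time;
# sizes are kept small so each solver call runs in well under a second.

make_fixture <- function(m = 8, d = 2, f = 21, n_true = 2, seed = 1,
                         dt = 0.01, passive_enabled = TRUE) {
  plant <- generate_plant(m = m, d = d, f = f, dt = dt, seed = seed)
  params <- synthetic_muscle_params(plant, seed = seed + 1,
                                    passive_enabled = passive_enabled)
  gt <- generate_ground_truth(n_true, f, m, seed = seed + 2)
  trial <- forward_consistent_trial(plant, gt, params)
  list(plant = plant, params = params, gt = gt, trial = trial)
}

# single-muscle-type analytic setup: fiber exactly at optimal length,
# zero velocity, no pennation, so gain = f_max under unit curves
analytic_params <- function(m, f_max = 1000, passive_enabled = FALSE) {
  muscle_params(sprintf("m%d", seq_len(m)), f_max = rep(f_max, m),
                l0 = 0.1, lts = 0.2, alpha0 = 0, vmax = 10,
                passive_enabled = passive_enabled)
}

analytic_kinematics <- function(f, m, lmt_value = 0.3) {
  list(lmt = matrix(lmt_value, f, m), vmt = matrix(0, f, m))
}
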