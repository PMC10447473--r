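# Model declaration schema for read_model_config():
#   low_level:  kind (poisson | ddm), optional n_drifts, sim_dt, t_max
#   transition: kind (static | random_walk | var | gp | regime_switch | itv),
#               optional p (VAR order), switch_times
#   priors:     optional theta0 / eta maps of distribution descriptors
#               {family: normal|truncnorm|gamma|exponential|beta|uniform,
#                <family parameters>, lower, upper}
# Omitted priors fall back to the model defaults documented in
# ?low_level_spec and ?transition_spec.
low_level:
  kind: ddm
  n_drifts: 1
  sim_dt: 0.001
  t_max: 10
transition:
  kind: random_walk
priors:
  theta0:
    v:   {family: normal, mean: 0, sd: 2.5}
    a:   {family: gamma, shape: 4, rate: 3}
    tau: {family: gamma, shape: 1.5, rate: 5}
  eta:
    sigma_v:   {family: beta, shape1: 1, shape2: 25}
    sigma_a:   {family: beta, shape1: 1, shape2: 25}
    sigma_tau: {family: beta, shape1: 1, shape2: 25}
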