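# Example pipeline configuration. Any field omitted falls back to the
# package default (see default_config()). Group sizes use n_participants
# (a bare `n` key is a YAML 1.1 boolean).
seed: 7
task:
  n_trials: 50
  kappa_good: 0.7
  kappa_bad: 0.3
  beta: 6
learner:
  grid_size: 101
  lam: 0.02
  lapse: 0.02
fit:
  n_restarts: 4
  fit_beta: false
  prior_scheme: per_agent
  use_ratings: true
stats:
  reference_group: BPD
profiles:
  BPD:
    n_participants: 20
  non-BPD:
    n_participants: 106
    sigma0:
      bad: 0.30
      good: 0.15
  DTC:
    n_participants: 23
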