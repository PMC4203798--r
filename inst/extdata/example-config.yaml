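# Example model configuration. Every key is optional; anything omitted
# keeps its built-in base-case default. Probabilities are fractions,
# costs are 2011 CNY.
markov:
  recur_rate: 0.1181
  horizon_years: 30
costs:
  cost_tpa_addon: 10830
discounting:
  disc_cost: 0.03
  disc_outcome: 0.03
psa:
  divisor: 3.92          # printed ranges read as central 95% intervals
  window_model: beta     # beta | dirichlet | fixed
  n_source: 1128         # effective sample size behind the window outcomes
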