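# Example scenario document for upfsim (mirrors scenario_config()).
# Omitted sections and fields fall back to the package defaults.
population:
  n_agents: 1000
  scenario: pre_transition
network:
  target_mean_degree: 5.47
  homophily_weight: 5
dynamics:
  perception_threshold: 50
  adjustment_fraction: 0.10
policy:
  tax_rate: 0.20
  label_active: false
  advertising_change: 0
  activation_step: 52
burn_in_steps: 100
total_steps: 208
n_replicates: 25
master_seed: 2026
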