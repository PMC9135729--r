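# Example synthetic-cohort configuration for `igsig simulate --config`.
# Keys are sim_config() arguments; omitted keys keep their defaults.
n_subjects = 400
n_genes = 600
n_blocks = 10
block_size = 15
rho = 0.5
n_causal_blocks = 5
activation_rate = 0.15
coactivation = 0.8
expr_shift = 3.0
effect_size = 1.5
noise_sd = 0.10
base_act_area = 0.05
mutation_rate = 0.004
n_reference = 200
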