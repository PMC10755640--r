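# Example cohort specification: a null cohort (no genotype effect) at the
# scale of a typical study -- 24 subjects per genotype, trained on the
# deterministic 0/100 task and then tested on the 15/60 probabilistic task.
n_per_cell: 12
sessions_per_subject: 1
curriculum: [training_single_port, training_0_100, full_15_60]
agent_spec:
  type: q_softmax
  params: {alpha: 0.2, beta: 3}
effect_size: 0
latency: {median_rewarded_s: 1.8, median_unrewarded_s: 1.1, dispersion: 0.4}
seizure_rate: 0.16
master_seed: 20231208
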