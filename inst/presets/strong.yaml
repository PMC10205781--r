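# Strong confounding: measured C1 = 2.5, unmeasured C2 = 3.0.
name: strong
n_subjects: 10000
n_reps: 1000
true_hr: [1, 2, 3]
strength_c1: 2.5
strength_c2: 3.0
confounder_corr: 0.1
iv_prevalence: 0.40
target_treat_prev: 0.22
target_outcome_incidence: [0.10, 0.12, 0.10]
target_iv_or: 4.05
censoring_rate: 0.03
followup_horizon: 5
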