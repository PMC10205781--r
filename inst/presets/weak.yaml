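# Weak confounding: measured C1 = 0.5, unmeasured C2 = 1.0.
# Marginal targets follow the moderate preset (no separate values published).
name: weak
n_subjects: 10000
n_reps: 1000
true_hr: [1, 2, 3]
strength_c1: 0.5
strength_c2: 1.0
confounder_corr: 0.1
iv_prevalence: 0.40
target_treat_prev: 0.24
target_outcome_incidence: [0.09, 0.11, 0.13]
target_iv_or: 4.55
censoring_rate: 0.03
followup_horizon: 5
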