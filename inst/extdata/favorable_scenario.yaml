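# Desk-scale power-simulation scenario: the favorable setting where
# participation is predictable (correlations 0.30 / 0.80 / 0.80) and 40% of
# subjects respond / enroll. Replicates are reduced to 200 for a fast run;
# raise `reps` to 2000 for publication-quality Monte-Carlo error.
taumax: [0.0, -0.1, -0.2, -0.3, -0.4, -0.5]
responder_fraction: 0.40
enroll_fraction: 0.40
rho_te_part: 0.30
rho_te_pred: 0.80
rho_part_pred: 0.80
n_per_arm: 9000
alpha: 0.05
retention_grid: [1.00, 0.80, 0.60, 0.40, 0.25]
reps: 200
seed: 20160315
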