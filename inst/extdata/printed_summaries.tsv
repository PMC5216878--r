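quantity	printed	digits
L_pi_whole	0.50	2
L_theta_whole	0.50	2
L_pi_coding	0.49	2
L_theta_coding	0.43	2
L_pi_noncoding	0.55	2
L_theta_noncoding	0.57	2
fold_pi_whole	2.0	1
fold_pi_coding	1.95	2
fold_pi_noncoding	2.22	2
mean_fst_whole	0.16	2
mean_fst_coding	0.14	2
mean_fst_noncoding	0.17	2
n_significant_whole	26	0
SM_total_whole	205	0
PMW_total_whole	213	0
PMD_total_whole	14	0
SM_total_coding	70	0
PMW_total_coding	64	0
PMD_total_coding	8	0
PMD_total_noncoding	4	0
pct_syn_shared	49.4	1
pct_syn_private_MW	47.1	1
pct_syn_private_MD	3.5	1
pct_rep_shared	49.1	1
pct_rep_private_MW	41.8	1
pct_rep_private_MD	9.1	1
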