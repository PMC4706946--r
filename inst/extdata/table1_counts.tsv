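rule_id	category	charge_n	adjusted_n
call_freq_band	clustering_error	2841	2841
cluster_sep_low	clustering_error	693	693
ab_freq_high	clustering_error	1	1
ab_r_mean_low	clustering_error	645	645
het_excess_high	clustering_error	13	13
het_excess_low	clustering_error	17	17
maf_low_callfreq	clustering_error	119896	2171
aa_t_mean_band	aa_cluster_error	759	759
aa_t_dev_high	aa_cluster_error	2195	2195
aa_only_callfreq	aa_cluster_error	43012	561
ab_t_mean_low_band	ab_cluster_error	847	847
ab_t_mean_high_band	ab_cluster_error	2685	2685
ab_t_dev_high	ab_cluster_error	272	272
no_het_maf	ab_cluster_error	70597	11572
bb_t_mean_band	bb_cluster_error	690	690
bb_t_dev_high	bb_cluster_error	2742	2742
bb_only_callfreq	bb_cluster_error	16352	92
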