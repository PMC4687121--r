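comparison	n_list1	n_list2	n_overlap	pct1	pct2
age_6_12_wt_vs_mut	2469	1266	241	9.8	19.0
age_12_18_wt_vs_mut	2579	3019	522	20.2	17.3
genotype_6m_vs_12m	1287	885	148	11.5	NA
genotype_12m_vs_18m	885	2484	223	25.2	9.0
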