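subject_id,n_vessels,n_associated,pct_reported,mean_distance_um
old_male,190,8,4.07,0.8
middle_aged_female,202,9,4.5,54.4
old_female,260,60,23.1,41.0
cte_human,94,58,61.7,29.9
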