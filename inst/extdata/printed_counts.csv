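quantity,value
cohort_n,616
aki_patients,112
cluster1_n,30
cluster2_n,13
cluster3_n,30
cluster4_n,39
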