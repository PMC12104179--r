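batch,total_prescriptions,selected_prescriptions,unique_cmms,total_cmm_occurrences,unique_pccmms,total_pccmm_occurrences
first,103,93,155,655,156,2985
second,93,85,136,511,158,2243
overall,196,178,196,1166,176,4026
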