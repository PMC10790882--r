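measure,condition,k,K_condition,K_pooled
buffer_blind,LHH,14,42,84
buffer_blind,RHH,11,42,84
buffer_seeing,LHH,5,42,84
buffer_seeing,RHH,14,42,84
missing_scan_left,NV,5,NA,132
missing_scan_left,LHH,14,NA,132
missing_scan_left,RHH,7,NA,132
missing_scan_right,NV,11,NA,132
missing_scan_right,LHH,19,NA,132
missing_scan_right,RHH,13,NA,132
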