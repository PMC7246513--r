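source,outcome,total_cost_aud
WHS,all_cause_mortality,2928657309
WHS,asthma_ed,52508
WHS,cvd_admission,1937594
WHS,rsp_admission,3149178
LFS,all_cause_mortality,159294240
LFS,asthma_ed,55949
LFS,cvd_admission,521552
LFS,rsp_admission,845972
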