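source,outcome,cases,cases_lo,cases_hi
LFS,all_cause_mortality,36,13,58
LFS,asthma_ed,76,39,121
LFS,cvd_admission,70,13,128
LFS,rsp_admission,112,0,240
WHS,all_cause_mortality,653,420,874
WHS,asthma_ed,72,36,108
WHS,cvd_admission,259,49,474
WHS,rsp_admission,416,0,882
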