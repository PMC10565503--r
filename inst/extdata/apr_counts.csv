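dose_mg,apr_count,total_count,study
1,11,27,study_01
4,6,12,study_11
5,27,20,study_09
5,109,157,study_12
5,69,127,study_13
5,146,227,study_07a
5,158,231,study_07b
5,6,12,study_11b
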