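design,label,n_subjects,baseline_bmd,dose_mg,n_doses,interval_month,followup_month,note
1,study_01,180,1.03,1,1,12,24,single dose; trial studied 1/2.5/5 mg arms - 1 mg allocated here
2,study_02,180,1.03,5,1,12,24,single dose; trial studied 1/2.5/5 mg arms - 5 mg allocated here
3,study_03,616,0.81,5,6,12,72,annual 5 mg for 6 years
4,study_04,3875,0.79,5,3,12,36,annual 5 mg for 3 years
5,study_05,175,0.64,5,2,12,24,annual 5 mg for 2 years
6,study_06,89,0.93,5,1,12,12,single 5 mg dose
7,study_07,458,0.75,5,1,12,24,single 5 mg dose
8,study_08,330,0.66,5,2,12,24,annual 5 mg for 2 years
9,study_09,20,1.06,5,1,12,12,single 5 mg dose
10,study_10,91,1.03,2.5,1,12,24,single dose; trial studied 1/2.5/5 mg arms - 2.5 mg allocated here
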