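experiment,condition,n,n_events,trial_time_s,modality,t,d,bf01_reported
exp1,simultaneous,45,15,4,pictures+spoken,4.67,0.70,0.001
exp1,separated,45,15,3,pictures+spoken,-0.37,-0.06,5.80
exp2,original_6s,45,15,6,pictures+spoken,1.41,0.21,2.47
exp2,constrained_3s,45,15,3,pictures+spoken,1.89,0.28,1.23
exp3a,all_30_events,45,30,6,pictures+spoken,1.65,0.25,1.76
exp3b,written_words,20,30,6,written,3.28,0.73,0.09
exp4a,pictures,20,30,6,pictures,2.00,0.45,0.83
exp4a,spoken_words,20,30,6,spoken,0.30,0.07,4.13
exp4b,pictures,20,30,6,pictures,1.73,0.39,0.82
exp4b,spoken_words,20,30,6,spoken,0.00,0.00,4.30
combined_4a_4b,pictures,40,30,6,pictures,2.60,0.41,0.31
combined_4a_4b,spoken_words,40,30,6,spoken,0.23,0.04,5.72
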