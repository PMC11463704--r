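contrast,group,mean,sd,n
speed_illusion_vs_catch_error,illusion,10.39,10.07,45
speed_illusion_vs_catch_error,catch_error,3.27,4.49,45
opacity_illusion_vs_catch_error,illusion,11.16,10.16,45
opacity_illusion_vs_catch_error,catch_error,3.24,3.96,45
attention_illusion_vs_omission_error,illusion,12.36,15.43,85
attention_illusion_vs_omission_error,omission_error,1.24,1.77,85
motion_onset_illusion_vs_omission_error,illusion,11.97,16.83,85
motion_onset_illusion_vs_omission_error,omission_error,4.13,6.74,85
attention_vs_motion_onset_illusion,attention,12.36,15.43,85
attention_vs_motion_onset_illusion,motion_onset,11.97,16.83,85
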