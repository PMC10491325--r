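type,control_mean_pct,control_sd_pct,ad_mean_pct,ad_sd_pct,significant
I,43.52,16.42,54.14,17.38,FALSE
II,0.26,0.08,0.33,0.17,FALSE
III,26.98,4.43,24.10,4.35,FALSE
IV,23.11,10.47,16.32,15.59,FALSE
V,0.07,0.01,0.10,0.03,TRUE
VI,4.52,1.77,3.51,3.02,FALSE
VIII,0.76,0.30,0.81,0.58,FALSE
XII,0.01,0.00,0.02,0.02,FALSE
XIV,0.20,0.10,0.10,0.09,FALSE
XVI,0.22,0.05,0.24,0.15,FALSE
XVIII,0.30,0.14,0.30,0.26,FALSE
XXI,0.03,0.01,0.04,0.03,FALSE
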