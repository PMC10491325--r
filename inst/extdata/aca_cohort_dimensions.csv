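group,donor,age,sex,stage,thickness_mm,inner_diameter_mm,outer_diameter_mm
early,e1,66,male,I-II,0.35,2.09,2.79
early,e1,66,male,I-II,0.25,2.00,2.50
early,e2,61,female,I-II,0.21,1.63,2.05
early,e2,61,female,I-II,0.27,1.69,2.22
early,e3,80,female,II-III,0.24,1.52,2.00
early,e4,72,male,II-III,0.31,1.85,2.46
intermediate,i1,77,female,III-IV,0.22,1.49,1.92
intermediate,i2,79,female,III-IV,0.32,2.07,2.72
intermediate,i3,69,male,IV,0.33,1.87,2.54
intermediate,i3,69,male,IV,0.34,1.78,2.47
advanced,a1,63,male,V,0.35,1.89,2.59
advanced,a2,78,female,V,0.24,1.88,2.35
advanced,a2,78,female,V,0.22,1.49,1.93
advanced,a3,61,male,V,0.28,1.92,2.48
advanced,a3,61,male,V,0.24,1.87,2.35
advanced,a4,62,male,VI,0.25,1.90,2.40
advanced,a5,63,female,V-VI,0.31,1.77,2.38
advanced,a6,95,female,V-VI,0.39,1.90,2.68
advanced,a7,83,male,V,0.32,2.07,2.70
advanced,a8,79,male,V-VI,0.30,1.98,2.57
control,c1,59,female,none,0.27,1.85,2.40
control,c1,59,female,none,0.33,1.83,2.50
control,c2,72,female,none,0.28,1.63,2.20
control,c2,72,female,none,0.29,2.26,2.84
control,c3,83,male,none,0.35,2.07,2.78
control,c3,83,male,none,0.33,2.07,2.70
control,c4,72,male,none,0.31,2.00,2.61
control,c4,72,male,none,0.31,2.11,2.73
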