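variable,type,bam_n,bam_mean,bam_sd,bam_lo,bam_hi,wem_n,wem_mean,wem_sd,wem_lo,wem_hi,printed_contrast,printed_ci_lo,printed_ci_hi,printed_p
vat_kg,mean_sd,17,3.72,1.07,,,14,5.68,2.43,,,-1.96,-3.30,0.62,0.01
muscle_kg,mean_sd,17,20.7,2.5,,,14,18.5,3.0,,,,,,0.03
m_value,mean_sd,18,4.52,2.07,,,15,4.00,1.70,,,0.52,-0.82,1.89,0.44
clamp_glucose_rd,mean_sd,18,26.8,10.4,,,15,24.2,8.5,,,2.60,-4.22,9.41,0.44
basal_glucose_ra,mean_sd,15,8.82,1.49,,,12,9.25,1.66,,,-0.43,-1.69,0.81,0.48
clamp_glucose_ra,mean_sd,18,5.76,1.73,,,15,6.50,2.34,,,-0.74,-2.18,0.71,0.31
basal_glycerol_ra,geomean_ci,15,1.51,,1.31,1.75,12,1.82,,1.55,2.15,0.83,0.67,1.02,0.08
clamp_glycerol_ra,mean_sd,18,1.06,0.47,,,13,1.18,0.33,,,-0.12,-0.43,0.19,0.43
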