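beam,phi_epi_1e9,ratio_th_epi,fast_dose_1e13,gamma_dose_1e13,j_over_phi_epi
BSA #1,2.58,0.019,9.16,3.96,0.59
BSA #2,2.56,0.054,6.70,6.66,0.60
BSA #3,1.73,0.004,7.71,2.70,0.62
BSA #4,2.79,0.018,9.09,3.78,0.59
BSA #5,1.08,0.009,9.50,4.17,0.74
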