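beam,t_irr_min,utcp,tcp,ntcp,d_gy,pct_boron,pct_thermal_n,pct_fast_n,pct_gamma
BSA #1,10,0.41,0.50,0.19,5.79,61,6,6,27
BSA #2,12.5,0.40,0.52,0.23,6.15,59,5,6,30
BSA #3,20,0.44,0.57,0.23,5.81,62,7,6,25
BSA #4,9.5,0.40,0.54,0.26,5.98,61,6,6,27
BSA #5,24.5,0.47,0.58,0.18,5.59,62,9,6,23
FiR 1,33,0.45,0.54,0.17,4.80,78,2,8,12
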