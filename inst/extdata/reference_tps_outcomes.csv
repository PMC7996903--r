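beam,t_irr_min,utcp,tcp,ntcp,d_gy
BSA #5,95,0.45,0.56,0.19,6.0
FiR 1,101,0.38,0.49,0.22,5.4
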