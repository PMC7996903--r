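tissue,rbe_gamma,rbe_neutron,cbe_boron,boron_ppm
brain,1,3.2,1.3,15
skin,1,2.5,2.5,22.5
liver,1,3.2,4.2,15
lung,1,3.2,1.3,15
kidney,1,3.2,1.3,75
bladder,1,3.2,1.3,15
tumor,1,2.2,5.3,52.5
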