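phase,dipole_label,theta_deg,multiplicity,d_A,density_g_cm3
synthetic-ordered-ice,t1,30,2,1.01,0.93
synthetic-ordered-ice,t2,75,2,1.01,0.93
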