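condition_id,theta_i_deg,theta_e_deg,theta_c_deg,sigma_ce,delta_epsilon
synthetic_A,120,150,90,0.5,-30
synthetic_B,140,110,110,0.8,-12
synthetic_C,100,135,125,1.2,4
synthetic_D,110,145,105,0.6,-20
synthetic_bad,120,150,110,0.5,-25
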