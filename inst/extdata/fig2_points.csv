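run_id,k_IA,C_IA_mol_L,T_C,t_min,R_SL_frac,E_FPU_g,C_Glc_g_L,C_Phe_g_L
HCl_0.05,1,0.05,160,60,0.10,20,22.8,1.13
HCl_0.1,1,0.1,160,60,0.10,20,,1.64
HCl_0.2,1,0.2,160,60,0.10,20,,
HCl_0.4,1,0.4,160,60,0.10,20,,
HCl_0.6,1,0.6,160,60,0.10,20,,
H2SO4_0.05,2,0.05,160,60,0.10,20,25.6,1.34
H2SO4_0.1,2,0.1,160,60,0.10,20,,
H2SO4_0.2,2,0.2,160,60,0.10,20,,
H2SO4_0.4,2,0.4,160,60,0.10,20,,
H2SO4_0.6,2,0.6,160,60,0.10,20,,
H3PO4_0.05,3,0.05,160,60,0.10,20,20.3,1.97
H3PO4_0.1,3,0.1,160,60,0.10,20,,
H3PO4_0.2,3,0.2,160,60,0.10,20,,
H3PO4_0.4,3,0.4,160,60,0.10,20,,
H3PO4_0.6,3,0.6,160,60,0.10,20,,
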