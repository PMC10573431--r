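adduct_id,protein,site,r1,r2,stereo,hydration_waters,mean_dist_P_F,delta_e_el
Ad12,HSA,Tyr150,C2H5,O-C2H5,,3,3.805,39.698
Ad13,HSA,Tyr150,C2H5,N-(CH3)2,R,3,3.920,39.659
Ad14,HSA,Tyr150,C2H5,N-(CH3)2,S,4,4.879,43.281
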