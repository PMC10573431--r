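adduct_id,protein,site,r1,r2,stereo
Ad1,BChE,Ser198,C2H5,N-(CH3)2,
Ad2,BChE,Ser198,C2H5,O-C2H5,
Ad3,BChE,Ser198,C2H5,C2H5,
Ad4,BChE,Ser198,C2H5,CH3,
Ad5,BChE,Ser198,CH(CH3)2,CH3,
Ad6,BChE,Ser198,CH2-CH(CH3)2,CH3,
Ad7,BChE,Ser198,nC4H9,CH3,
Ad8,BChE,Ser198,cC6H11,CH3,
Ad9,BChE,Ser198,C*H(CH3)-C(CH3)3,CH3,S
Ad10,BChE,Ser198,C*H(CH3)-C(CH3)3,CH3,R
Ad11,BChE,Ser198,C6H4-CH3,O-CH2-C6H4-OH,
Ad12,HSA,Tyr411,C2H5,O-C2H5,
Ad13,HSA,Tyr150,C2H5,N-(CH3)2,R
Ad14,HSA,Tyr150,C2H5,N-(CH3)2,S
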