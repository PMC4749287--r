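cohort,trait,icc_mz,icc_dz,full_model
danish,TC,0.50,0.18,ADE
danish,TG,0.29,0.26,ACE
danish,HDL,0.47,0.12,ADE
danish,LDL,0.51,0.20,ADE
danish,GLU,0.42,0.12,ADE
danish,WT,0.40,0.17,ADE
danish,BMI,0.41,0.16,ADE
danish,WAIST,0.41,0.13,ADE
danish,HIP,0.44,0.41,ACE
danish,WHR,0.48,0.13,ADE
danish,SBP,0.36,0.20,ACE
danish,DBP,0.49,0.17,ADE
chinese,TC,0.54,0.29,ACE
chinese,TG,0.58,0.37,ACE
chinese,HDL,0.68,0.63,ACE
chinese,LDL,0.53,0.34,ACE
chinese,GLU,0.56,0.41,ACE
chinese,WT,0.38,0.35,ACE
chinese,BMI,0.27,0.35,ACE
chinese,WAIST,0.37,0.46,ACE
chinese,HIP,0.36,0.42,ACE
chinese,WHR,0.49,0.43,ACE
chinese,SBP,0.30,0.10,ADE
chinese,DBP,0.32,0.23,ACE
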