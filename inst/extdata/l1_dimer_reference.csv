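cluster,E_LE_cm1,E_LE_ci95,E_CT_cm1,E_CT_ci95,V_cm1,V_ci95
CL2,15582,255,20656,326,292,61
CL5,15689,193,20887,463,199,46
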