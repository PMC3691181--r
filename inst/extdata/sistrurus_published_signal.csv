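trait,K,p_value,group
DISI,0.052,0.70,venom
LAO,0.26,0.06,venom
CRISP,0.04,0.83,venom
PLA2,0.08,0.37,venom
SP,0.07,0.50,venom
SVMP,0.11,0.37,venom
PEP,0.15,0.20,venom
PC1_venom,0.09,0.37,venom
PC2_venom,0.12,0.23,venom
mam,0.16,0.11,diet
liz,0.08,0.44,diet
PC1_diet,0.11,0.22,diet
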