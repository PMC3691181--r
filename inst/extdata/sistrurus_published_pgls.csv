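trait,slope,p_value
DISI,-0.12,0.16
LAO,0.01,0.84
CRISP,0.26,0.003
PLA2,-0.26,0.026
SP,0.03,0.50
SVMP,0.12,0.32
PEP,-0.01,0.67
PC1_venom,0.31,0.047
PC2_venom,0.18,0.12
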