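taxon,mam,liz
Sms,0.20,0.20
Smm,0.17,0.50
Smb,0.17,0.32
Sca,0.85,0.00
Sct,0.73,0.14
Sce,0.32,0.60
Catrox,0.87,0.05
Agc,0.37,0.06
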