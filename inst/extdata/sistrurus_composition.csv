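taxon,DISI,LAO,CRISP,PLA2,SP,SVMP,svNGF,CTL,MYO,DC,PEP,Kunitz
Sms,1.4,0,1.6,21.3,17.8,51.1,0.7,1.8,0,0,4.3,0
Smm,1.8,0,1.6,18.1,13.1,62.7,0,0,0,0,2.7,0
Smb,7.5,2.0,2.8,31.8,16.8,35.3,0.1,0.1,0,1.3,2.1,0.1
Sca,2.4,4.0,0.6,28.9,17.5,42.2,0.1,0.1,0.4,0.1,3.7,0
Sct,4.1,1.4,1.2,30.3,19.6,38.9,0.1,0.1,0.1,0.1,4.1,0
Sce,0.8,2.4,10.1,13.1,23.3,45.6,0.1,0.1,0,0.1,4.2,0.1
Catrox,6.2,8.0,4.3,7.3,19.8,49.8,0.0,1.6,0.0,0.0,3.0,0.0
Agc,1.3,0.4,3.7,31.7,14.3,32.5,0.3,2.4,0.0,0.0,0.7,0.0
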