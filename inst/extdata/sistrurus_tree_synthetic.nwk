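((((Sca:2,(Sct:1,Sce:1):1):5,(Smb:0.77,(Sms:0.49,Smm:0.49):0.28):6.23):5,Catrox:12):6,Agc:18);
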