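layer,thickness_cm,ll,dul,sat
1,15,0.18,0.32,0.42
2,15,0.19,0.33,0.43
3,30,0.20,0.33,0.43
4,30,0.20,0.32,0.42
5,30,0.19,0.30,0.41
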