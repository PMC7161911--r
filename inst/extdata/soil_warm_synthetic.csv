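layer,thickness_cm,ll,dul,sat
1,15,0.10,0.22,0.38
2,15,0.11,0.23,0.39
3,30,0.12,0.24,0.40
4,30,0.12,0.23,0.39
5,30,0.11,0.22,0.38
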