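index,weight
K1,0.0658
K2,0.0916
K3,0.1163
K4,0.1706
K5,0.1996
K6,0.0755
K7,0.0716
K8,0.0456
K9,0.1191
K10,0.0443
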