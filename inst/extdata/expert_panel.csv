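index,Expert1,Expert2,Expert3,Expert4,Expert5,Expert6,Expert7,Expert8,Expert9,Expert10
K1,6,10,7,9,10,8,6,7,10,7
K2,10,9,10,8,10,8,7,9,7,9
K3,10,8,6,9,8,5,6,8,9,8
K4,8,6,5,6,8,5,6,7,9,5
K5,8,8,8,7,9,5,5,7,7,8
K6,9,9,9,9,8,5,7,7,9,7
K7,8,9,8,9,7,5,8,8,9,7
K8,7,8,5,7,7,4,8,6,9,7
K9,8,7,5,5,7,4,7,6,7,5
K10,5,5,5,6,6,5,7,7,7,6
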