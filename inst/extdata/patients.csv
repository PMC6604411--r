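"index","Cheng-ming Luan","Di-he Gu","Hong-Liu"
"K1","1","6","35"
"K2","0.5","0.3","0.4"
"K3","Transparent","Transparent","Red"
"K4","3","7","11"
"K5","0","0","10"
"K6","Bright red","Red","Bright red"
"K7","24","0","42"
"K8","Normal","Normal","Slightly hot"
"K9","Normal","Bright red","Red"
"K10","3","5","7"
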