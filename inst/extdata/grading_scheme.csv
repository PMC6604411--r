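"index","kind","units","I","II","III","IV","V"
"K1","range","cm^2","0","1-4","4-9","9-16",">16"
"K2","range","cm","0-1","1-2","2-3","3-4",">4"
"K3","categorical","","Transparent","Red","Yellow","Green","Black"
"K4","integer","layers of gauze wetted","0-4","5-8","9-12","13-16",">16"
"K5","range","%","0-20","21-40","41-60","61-80","81-100"
"K6","categorical","","Bright red","Red","Light red","Pink","Pale"
"K7","range","%","81-100","61-80","41-60","21-40","0-20"
"K8","categorical","","Normal","Slightly hot","Hot","Pretty hot","Scorching hot"
"K9","categorical","","Normal","Reddish","Red","Bright red","Dark red"
"K10","integer","VAS","0-2","3-4","5-6","7-8","9-10"
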