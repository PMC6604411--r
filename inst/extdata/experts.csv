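"expert","position","education","years"
"Expert1","Student","Bachelor",2
"Expert2","Student","Master",4
"Expert3","Doctor-in-charge","Master",10
"Expert4","Doctor-in-charge","Master",10
"Expert5","Doctor-in-charge","PhD",15
"Expert6","Associate Professor","Master",22
"Expert7","Associate Professor","PhD",25
"Expert8","Professor","PhD",29
"Expert9","Professor","PhD",35
"Expert10","Professor","PhD",40
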