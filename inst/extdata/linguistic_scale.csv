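"level","lo","hi"
"Very important",8,10
"Important",6,8
"Middle important",4,6
"Unimportant",2,4
"Very unimportant",0,2
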