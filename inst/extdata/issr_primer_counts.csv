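"primer","polymorphic","total","loci"
"ISSR-815",81,101,8
"ISSR-818",94,94,8
"ISSR-822",57,97,7
"ISSR-827",63,83,7
"ISSR-825",19,39,5
"ISSR-841",40,80,6
"ISSR-857",71,71,6
"UBC-810",112,112,9
"UBC-820",33,53,5
"UBC-826",68,68,5
"UBC-858",38,38,3
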