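"component","value","df","SS"
"var_among",0.859,3,39.752
"var_within",2.876,36,92.048
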