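"primer","polymorphic","total","loci"
"OPC-08",61,61,6
"OPA-10",66,66,7
"OPA-11",57,57,5
"OPA-12",61,61,6
"OPA-13",94,114,8
"OPA-17",64,64,7
"OPA-18",38,58,5
"OPD-15",35,55,5
"OPD-20",79,79,8
"OPD-18",99,99,10
"OPN-02",71,91,8
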