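"genotype","population","genome_group","ploidy"
"Namarai","AA","AA",2
"Ankur","ABB","ABB",3
"Safed Velchi","AB","AB",2
"Bhurkel","ABB","ABB",3
"Bluggoe","ABB","ABB",3
"Borkal Baista","ABB","ABB",3
"Karpuravalli","ABB","ABB",3
"Birbutia","ABB","ABB",3
"Karimbontha","ABB","ABB",3
"Karpura Chakrakeli","AAB","AAB",3
"Rajeli","AAB","AAB",3
"Ardhapuri","AAA","AAA",3
"Grand Nain","AAA","AAA",3
"NRCB-3","AAAB","AAAB",4
"Elavazhai","BB","BB",2
"Lamby","ABB","ABB",3
"Ney Poovan","AB","AB",2
"Nendran","AAB","AAB",3
"Rasthali","AAB","AAB",3
"Neyvazhai","AAB","AAB",3
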