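"sr","chemical_class","rt_min","compound","reference_ri","experimental_ri","Rajeli","Borkal Baista","Ankur","Bhurkel","Karpuravalli","Bluggoe","Birbutia","Ardhapuri","Grand Nain","ambiguous"
1,"ester","4.624","Acetic acid, butyl ester","781","785",0,0,0,1,1,0,0,0,0,""
2,"ester","4.672","Butanoic acid, ethyl ester","782","785",0,1,0,0,0,0,0,0,0,""
3,"ester","6.557","1-Butanol,3-methyl-,acetate","865","855",0,1,1,1,1,0,0,0,0,""
4,"ester","6.931","n-Butyl ether","881","880.2",0,0,0,0,0,0,1,0,0,""
5,"ester","8.108","2-Buten-1-ol, 3-methyl-, acetate","916","905",1,0,0,0,0,0,0,0,0,""
6,"ester","9.617","Butanoic acid, 2-methylpropylester","949","953",1,1,1,0,1,0,0,1,0,""
7,"ester","11.637","Butanoic acid, butyl ester","994","995",1,1,1,1,1,0,0,0,0,""
8,"ester","12.146","Butanoic acid, 3-methyl-, 2-methylpropylester","1004","990",0,1,0,0,0,0,0,0,0,""
9,"ester","12.539","Acetic acid, hexyl ester","1011","1008",0,0,1,1,1,0,0,0,0,""
10,"ester","12.547","Propanoic acid, 2-methyl-, pentyl ester","1011","1019",1,1,0,0,0,0,0,0,0,""
11,"ester","12.86","4-Hexen-1-ol, (4E)-, acetate","1016","1013",0,0,1,1,0,0,0,0,0,""
12,"ester","13.183","Butanoic acid, 1-methylbutyl ester","1022","1019",0,1,0,0,1,0,0,1,1,""
13,"ester","14.442","Butanoic acid, 3-methyl-,butylester","1043","1044",1,1,1,0,1,0,1,1,1,""
14,"ester","15.18","Butanoic acid, pentyl ester","1056","1055",1,1,1,1,1,0,1,0,0,""
15,"ester","17.592","Butanoic acid, 2-pentenyl ester,(Z)-","1098","1091",0,0,1,0,1,0,0,0,0,""
16,"ester","18.072","Pentanoic acid, 3-methylbutyl ester","1105","1104",1,1,1,0,1,0,1,0,0,""
17,"ester","19.39","Hexanoic acid, 3-hydroxy-, ethyl ester","1126","1124",0,0,1,1,1,0,0,0,0,""
18,"ester","21.037","Pentanoic acid, pentyl ester","1199","1183",0,1,1,0,1,0,0,0,0,""
19,"ester","23.494","Hexanoic acid, butyl ester","1190","1183",0,0,1,1,1,0,0,0,0,""
20,"ester","23.524","Butanoic acid, hexyl ester","1190","1183",0,1,0,0,0,0,0,0,1,""
21,"ester","23.8","2-Butenoic acid, hexyl ester","1194","1191",1,0,0,0,0,0,0,0,0,""
22,"ester","24.1","Butanoic acid, 4-hexen-1-yl ester","1199","1191",0,1,1,0,1,0,0,0,0,""
23,"ester","24.973","Isopentyl hexanoate","1212","1218",0,1,1,0,1,0,0,0,0,""
24,"ester","26.476","Benzene, 1,4-dimethoxy-2-methyl","1235","1229",1,0,0,0,0,0,0,0,0,""
25,"ester","26.895","Hexyl n-valerate","1242","1235",0,1,1,0,0,0,0,1,1,""
26,"ester","27.309","Isopentyl hexanoate","1248","1253",1,1,1,1,1,1,1,1,1,""
27,"ester","33.291","2(3H)-Furanone, dihydro-5-pentyl-","1341","1341",0,1,0,0,0,0,0,0,0,""
28,"ester","36.05","5-Dodecen-1-ol, acetate, (z)-","1386","1389",0,0,0,0,0,0,0,1,1,""
29,"ester","36.58","Decanoic acid, ethyl ester","1394","1393",1,0,0,0,0,0,0,0,0,""
30,"ester","58.383","Phthalic acid, isobutyl 2-pentyl ester","2069","2008",1,1,1,1,1,1,1,1,1,""
31,"aromatic aldehyde","5.913","2-Hexenal","846","838",1,1,1,1,0,1,0,0,0,""
32,"aromatic aldehyde","26.334","Propanal, 3-cyclohexylidene-2-methyl-","1233","1227",0,1,0,0,0,0,0,0,0,""
33,"alcohol","18.018","2-Nonen-1-ol","1102","1105",0,0,0,1,0,1,0,0,0,""
34,"alcohol","24.501","3-Decan-1-ol, (E)-","1205","1233",0,0,0,1,0,0,1,0,0,""
35,"alcohol","31.8","1-Decanol, 2-ethyl-","1317","1350",1,0,0,0,0,0,0,0,0,""
36,"alcohol","36.833","1-Octanol, 2-butyl-","1398","1393",0,1,0,0,1,0,1,0,0,""
37,"alcohol","42.895","1-Decanol, 2-hexyl-","1496","1504",1,1,1,1,0,1,1,0,0,""
38,"alcohol","44.713","2-Hexyl-1-octanol","1590","1591",1,0,0,1,0,0,1,0,0,""
39,"alcohol","53.536","1-Hexadecanol, 2-methyl","1899","1890",1,1,0,1,1,1,1,0,0,""
40,"hydrocarbon","4.165","1,3,5-Cycloheptatriene","765","771",0,0,0,0,0,0,1,0,0,""
41,"hydrocarbon","31.769","Decane,2,4,6-trimethyl-","1316","1318",0,1,0,0,0,0,1,0,0,""
42,"hydrocarbon","33.325","Tridecane, 5-methyl-","1342","1349",1,0,1,0,0,0,0,0,0,""
43,"ketone","38.733","2-Butanone, 4-(2,6,6-trimethyl-1-cyclohexen-1-yl)-","1429","1427.8",1,0,0,1,1,0,1,0,0,""
44,"ketone","39.722","5,9-Undecadien-2-one, 6,10-dimethyl-,(E)-","1445","1453",1,1,0,1,0,0,1,0,0,""
45,"ether","26.476","Benzene, 1,4-dimethoxy-2-methyl","1235","1229",1,0,0,0,0,0,0,0,0,""
46,"ether","36.929","Benzene, 1,2-dimethoxy-4-(2-propenyl)-","1400","1402",0,0,0,0,0,1,0,0,0,""
47,"ether","45.776","Benzene, 1,2,4-trimethoxy-5-(1-propenyl)-,(Z)-","1622","1640",1,1,1,1,1,1,1,1,1,""
48,"carboxylic acid","33.442","2,2-Dimethylglutaric acid","1344","1345",0,0,0,0,1,0,0,0,0,""
49,"diverse functional group","30.263","2H-Pyran-2,3-diol, tetrahydro-, diacetate, cis-","1293","1364",0,1,1,0,0,0,0,0,0,""
50,"diverse functional group","33.783","Eugenol","1349","1337",0,0,0,0,0,0,0,1,1,""
51,"diverse functional group","35.877","Carbonic acid, dipentyl ester","1383","1358",0,1,0,0,0,0,0,0,0,"Ardhapuri;Grand Nain"
52,"diverse functional group","38.389","Chloroacetic acid, 2-ethylcyclohexyl ester","1423","1433",0,0,0,0,0,0,0,1,0,"Rajeli;Borkal Baista;Ankur;Bhurkel;Karpuravalli;Bluggoe;Birbutia;Ardhapuri;Grand Nain"
53,"diverse functional group","51.206","2-Propenoic acid, 3-(3,4-dimethoxyphenyl)-,(E)-","1774","1735",1,1,0,0,1,1,0,0,0,"Ardhapuri;Grand Nain"
54,"chlorine-containing","56.803","Octadecane, 1-chloro-","2037","2036",0,0,1,1,0,0,0,0,0,"Birbutia"
NA,"",NA,"Total",NA,NA,23,29,23,20,23,9,16,10,9,""
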