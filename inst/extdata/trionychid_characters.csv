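index,name,n_states,ordered,ontogeny_controlled,active,bin_edges,margin,unit,alt_bin_edges
1,Carapacial disk size,10,TRUE,FALSE,TRUE,10;20;30;40;50;60;70;80;90,,cm,20;40;60;80
2,Carapacial disk outline,2,FALSE,FALSE,TRUE,,,,
3,Carapacial Sculpturing 1,3,TRUE,FALSE,TRUE,,,,
4,Carapacial Sculpturing 2,2,FALSE,TRUE,TRUE,,,,
5,Carapacial sculpturing 3,3,TRUE,FALSE,TRUE,,,,
6,Carapacial sculpturing 4,3,TRUE,FALSE,TRUE,,,,
7,Carapacial kinesis,2,FALSE,FALSE,TRUE,,,,
8,Prenuchal,3,TRUE,FALSE,TRUE,,,,
9,Neomorphic peripherals,2,FALSE,FALSE,TRUE,,,,
10,Nuchal callosity 1,4,TRUE,TRUE,TRUE,30;50;70,3,%,
11,Nuchal callosity 2,3,TRUE,TRUE,TRUE,60;100,5,%,
12,Nuchal callosity 3,2,FALSE,TRUE,TRUE,,,,
13,Nuchal callosity 4,3,FALSE,TRUE,TRUE,,,,
14,Nuchal callosity 5,2,FALSE,TRUE,TRUE,,,,
15,Nuchal callosity 6,2,FALSE,FALSE,TRUE,,,,
16,Suprascapular fontanelles 1,3,FALSE,FALSE,TRUE,,,,
17,Suprascapular fontanelles 2,5,TRUE,FALSE,TRUE,,,,
18,Nuchal processes 1,8,TRUE,TRUE,TRUE,40;50;60;70,2,%,
19,Nuchal processes 2,2,FALSE,FALSE,TRUE,,,,
20,Nuchal processes 3,2,FALSE,FALSE,TRUE,,,,
21,Nuchal processes 4,3,TRUE,FALSE,TRUE,,,,
22,Dorsal vertebra,3,TRUE,FALSE,TRUE,,,,
23,Preneural,2,FALSE,FALSE,TRUE,,,,
24,Neurals 1,10,TRUE,FALSE,TRUE,,,,
25,Neurals 2,2,FALSE,FALSE,TRUE,,,,
26,Neural 3,10,TRUE,FALSE,TRUE,,,,
27,Neural 4,2,FALSE,FALSE,TRUE,,,,
28,Neural 5,2,FALSE,FALSE,TRUE,,,,
29,Neural 6,2,FALSE,FALSE,TRUE,,,,
30,Costal 1,2,FALSE,TRUE,TRUE,,,,
31,Costal 2,3,TRUE,FALSE,TRUE,,,,
32,Costal 3,10,FALSE,FALSE,TRUE,,,,
33,Costal 4,2,FALSE,TRUE,TRUE,,,,
34,Costal 5,5,TRUE,TRUE,TRUE,,,,
35,Costal 6,5,TRUE,TRUE,TRUE,,,,
36,Costal 7,2,FALSE,FALSE,TRUE,,,,
37,Costal ribs 1,3,FALSE,TRUE,TRUE,,,,
38,Costal ribs 2,2,FALSE,FALSE,TRUE,,,,
39,Costal ribs 3,3,TRUE,TRUE,TRUE,,,,
40,Neomorphic plastral callosities,2,FALSE,FALSE,TRUE,,,,
41,Epiplastral callosity,4,TRUE,FALSE,TRUE,,,,
42,Entoplastral callosity 1,4,TRUE,TRUE,TRUE,,,,
43,Entoplastral callosity 2,3,TRUE,TRUE,TRUE,,,,
44,Hyo/hypoplastral callosity 1,5,TRUE,TRUE,TRUE,,,,
45,Hyo/hypoplastral callosity 2,3,FALSE,FALSE,TRUE,,,,
46,Hyo/hypoplastral callosity 3,2,FALSE,TRUE,TRUE,,,,
47,Hyo/hypoplastral callosity 4,4,TRUE,TRUE,TRUE,,,,
48,Hyo/hypoplastral callosity 5,4,TRUE,TRUE,TRUE,,,,
49,Hyo/Hypoplastral callosity 6,2,FALSE,TRUE,TRUE,,,,
50,Hyo/hypoplastral callosity 7,2,FALSE,TRUE,TRUE,,,,
51,Xiphiplastral callosity I,4,TRUE,TRUE,TRUE,,,,
52,Xiphiplastral callosity II,4,TRUE,TRUE,TRUE,,,,
53,Xiphiplastral callosity III,3,TRUE,TRUE,TRUE,,,,
54,Epiplastral processes I,2,TRUE,FALSE,TRUE,,,,
55,Epiplastral processes II,2,FALSE,FALSE,TRUE,,,,
56,Epiplastral processes III,3,TRUE,FALSE,TRUE,0.5;1.5,,ratio,
57,Entoplastral processes I,4,FALSE,FALSE,TRUE,,,,
58,Entoplastral processes II,3,TRUE,FALSE,TRUE,80;100,3,deg,
59,Entoplastral processes III,3,TRUE,FALSE,TRUE,,,,
60,Hyo- and hypoplastral processes I,4,TRUE,FALSE,TRUE,,,,
61,Hyo- and hypoplastral processes II,4,TRUE,FALSE,TRUE,,,,
62,Hyo- and hypoplastral processes III,3,TRUE,TRUE,TRUE,45;70,3,deg,
63,Hyo- and hypoplastral processes IV,2,FALSE,FALSE,TRUE,,,,
64,Hyo- and hypoplastral processes V,2,FALSE,FALSE,TRUE,,,,
65,Hyo- and hypoplastral processes VI,3,TRUE,FALSE,TRUE,,,,
66,Hyo- and hypoplastral processes VII,3,TRUE,FALSE,TRUE,,,,
67,Hyo- and hypoplastral processes VIII,2,FALSE,FALSE,TRUE,,,,
68,Xiphiplastra processes I,4,TRUE,FALSE,TRUE,,,,
69,Xiphiplastra processes II,2,FALSE,TRUE,TRUE,,,,
70,Suprascapular fontanelle observations (helper column for characters 16/17),5,FALSE,FALSE,FALSE,,,,
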