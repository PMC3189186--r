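site	omega	pvalue
1	0.735468234168366	0.779530748713296
2	0.964608289767057	0.794387442257721
3	0.168959154747427	0.763336270686705
4	0.08066909853369	0.388259811000898
5	3.09662489699581	0.00309811263578013
6	0.933844109065831	0.859683673887048
7	0.980706147383898	0.343687942053657
8	0.345047276234254	0.543771023058798
9	0.109726423863322	0.926504279160872
10	0.261581680970266	0.93057815459324
11	0.777459329925478	0.349661801650655
12	0.842206825967878	0.995443912176415
13	0.943499413086101	0.259260163933504
14	0.997442515799776	0.326473331218585
15	0.884043256752193	0.834808890847489
16	0.176322618266568	0.332947574555874
17	0.529537972062826	0.197365237120539
18	0.710665499093011	0.299677334725857
19	0.239232258405536	0.465698617487214
20	0.945957449497655	0.235090897849295
21	0.309259690111503	0.576553344260901
22	0.250343233114108	0.539652197796386
23	0.170794896781445	0.660666184255388
24	0.216121930861846	0.611238699825481
25	7.03516614403496	0.0332422660430893
26	0.368907312164083	0.548084432142787
27	0.72818453097716	0.370107598986942
28	3.85110584536984	0.0153767483890988
29	0.0595257794484496	0.224965236568823
30	0.28233534260653	0.187629353965167
31	0.772992963436991	0.515404835366644
32	0.626967018935829	0.19489125040127
33	0.59625176875852	0.534403411590029
34	0.259570250753313	0.186827348789666
35	0.758489972446114	0.726972399873193
36	0.888090127147734	0.890973453654442
37	1.28770899904173	0.0110860478132963
38	0.843174209818244	0.59988025939092
39	1.24712664845598	0.019450029626023
40	0.360592551296577	0.931953411607537
41	0.374038559850305	0.842118858313188
42	1.54185247421265	0.0108118528383784
43	0.170437621884048	0.541253932996187
44	0.144379439996555	0.404587116406765
45	0.470434712711722	0.0696350781945512
46	0.784027801360935	0.240842143434566
47	0.631722302176058	0.631915537815075
48	1.62187458771692	0.0258391830371693
49	0.422174766426906	0.0783687725081108
50	0.21850680722855	0.433828621963039
51	0.738509398186579	0.468096711568069
52	0.78408434917219	0.875201569148339
53	0.829807524336502	0.474650239921175
54	0.923306192969903	0.882102444919292
55	1.32808718178421	0.020008391502779
56	0.834828519960865	0.656299169769045
57	0.75329752638936	0.196695493743755
58	0.207196035655215	0.439784862298984
59	1.9931806595996	0.0243014367180876
60	0.549624137114733	0.330091171548702
61	0.066370690241456	0.839160377858207
62	0.717208571266383	0.0862558068824001
63	0.315030745230615	0.751390608772636
64	0.00769012700766325	0.745448567450512
65	0.340602701064199	0.965259777591564
66	0.745172110386193	0.503890974412207
67	0.652071269927546	0.885391868744046
68	0.936868612188846	0.133135066670366
69	2.30820672400296	0.00689938187133521
70	0.962457013782114	0.792012078233529
71	0.87294774921611	0.14094225022709
72	0.749157972401008	0.524855506222229
73	0.746795302722603	0.515617121395189
74	0.781514146365225	0.81809510900639
75	0.520898152608424	0.703681289067026
76	0.429980135289952	0.43620512135094
77	0.898443395271897	0.0935782387969084
78	0.503682589856908	0.764376847341191
79	0.85065748100169	0.243207763193641
80	0.524721592431888	0.949788691697177
81	0.587142495904118	0.435402549488936
82	0.122470994479954	0.448757622449193
83	0.903851429233328	0.515224572212901
84	0.111669076839462	0.341940291272476
85	0.181800954043865	0.825186014978681
86	0.829345962963998	0.796349642938003
87	1.8014811296016	0.0117152202059515
88	0.0247023142874241	0.0913965216372162
89	0.085786405717954	0.547516403684858
90	4.80881866795902	0.0224282005103305
91	0.961653471458703	0.326964108715765
92	0.0128315156325698	0.990946101269219
93	0.130017664516345	0.803705344570335
94	0.358597890473902	0.730657778086606
95	0.962345693493262	0.361593669105787
96	0.204922293545678	0.909174904134124
97	0.909588702954352	0.391274673887528
98	0.806994001846761	0.246690783009399
99	0.49877788266167	0.464787730423268
100	1.82693851273507	0.0220166309853084
101	0.480749365175143	0.657732465036679
102	0.303573942976072	0.339826910046395
103	0.281796614639461	0.0624281025724486
104	0.725432186387479	0.664994065964129
105	0.0608369745314121	0.481371069967281
106	0.661442872136831	0.196563285915181
107	0.0397269874811172	0.154945436038543
108	0.00612680683843791	0.302219127409626
109	0.826268380973488	0.160212712991051
110	3.22887940696421	0.0107963702757843
111	0.493647422175854	0.749285479006358
112	3.75403504065218	0.0402272769948468
113	0.445031703216955	0.0926373496418819
114	0.589533648220822	0.692358804028481
115	0.598670010222122	0.610410089802463
116	0.485310548450798	0.264406916929875
117	0.347467642277479	0.409290773200337
118	0.107169427210465	0.382179960235953
119	0.275653903372586	0.895144137809984
120	0.55124297272414	0.307965610572137
121	0.0680646768305451	0.292444689001422
122	0.12628478766419	0.116179805598222
123	0.109738566447049	0.40357195106335
124	1.58921134887796	0.0210288775269873
125	0.40881985402666	0.996185249602422
126	3.31741870558801	0.0193649220163934
127	5.23090490283917	0.0405425996286795
128	0.0429055807180703	0.23376671517035
129	0.351343845482916	0.250448212691117
130	0.143640074180439	0.550999920070171
131	0.0382168961223215	0.46584712783806
132	0.756139606703073	0.387238231173251
133	0.67741330107674	0.192529302381445
134	0.0312251937575638	0.829287636594381
135	4.15982778353577	0.0149097286164761
136	0.697409916203469	0.509809371724259
137	0.577399853151292	0.827185096952599
138	0.702652886044234	0.17888287093956
139	0.258751418674365	0.31078495621914
140	0.419278883608058	0.372631671547424
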