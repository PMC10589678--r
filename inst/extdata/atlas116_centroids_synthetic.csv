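node,label,x,y,z
0,Precentral_L,-39,-6,51
1,Precentral_R,39,-6,51
2,Frontal_Sup_L,-18,35,42
3,Frontal_Sup_R,18,35,42
4,Frontal_Sup_Orb_L,-17,47,-13
5,Frontal_Sup_Orb_R,17,47,-13
6,Frontal_Mid_L,-33,33,35
7,Frontal_Mid_R,33,33,35
8,Frontal_Mid_Orb_L,-31,50,-10
9,Frontal_Mid_Orb_R,31,50,-10
10,Frontal_Inf_Oper_L,-48,13,19
11,Frontal_Inf_Oper_R,48,13,19
12,Frontal_Inf_Tri_L,-46,30,14
13,Frontal_Inf_Tri_R,46,30,14
14,Frontal_Inf_Orb_L,-36,31,-12
15,Frontal_Inf_Orb_R,36,31,-12
16,Rolandic_Oper_L,-47,-8,14
17,Rolandic_Oper_R,47,-8,14
18,Supp_Motor_Area_L,-5,5,61
19,Supp_Motor_Area_R,5,5,61
20,Olfactory_L,-8,15,-11
21,Olfactory_R,8,15,-11
22,Frontal_Sup_Medial_L,-5,49,31
23,Frontal_Sup_Medial_R,5,49,31
24,Frontal_Med_Orb_L,-5,54,-7
25,Frontal_Med_Orb_R,5,54,-7
26,Rectus_L,-5,37,-18
27,Rectus_R,5,37,-18
28,Insula_L,-35,7,3
29,Insula_R,35,7,3
30,Cingulum_Ant_L,-4,35,14
31,Cingulum_Ant_R,4,35,14
32,Cingulum_Mid_L,-5,-15,42
33,Cingulum_Mid_R,5,-15,42
34,Cingulum_Post_L,-5,-43,25
35,Cingulum_Post_R,5,-43,25
36,Hippocampus_L,-25,-21,-10
37,Hippocampus_R,25,-21,-10
38,ParaHippocampal_L,-21,-16,-21
39,ParaHippocampal_R,21,-16,-21
40,Amygdala_L,-23,-1,-17
41,Amygdala_R,23,-1,-17
42,Calcarine_L,-7,-79,6
43,Calcarine_R,7,-79,6
44,Cuneus_L,-6,-80,27
45,Cuneus_R,6,-80,27
46,Lingual_L,-15,-68,-5
47,Lingual_R,15,-68,-5
48,Occipital_Sup_L,-17,-84,28
49,Occipital_Sup_R,17,-84,28
50,Occipital_Mid_L,-32,-81,16
51,Occipital_Mid_R,32,-81,16
52,Occipital_Inf_L,-36,-78,-8
53,Occipital_Inf_R,36,-78,-8
54,Fusiform_L,-31,-40,-20
55,Fusiform_R,31,-40,-20
56,Postcentral_L,-42,-23,49
57,Postcentral_R,42,-23,49
58,Parietal_Sup_L,-23,-60,59
59,Parietal_Sup_R,23,-60,59
60,Parietal_Inf_L,-43,-46,47
61,Parietal_Inf_R,43,-46,47
62,SupraMarginal_L,-56,-34,30
63,SupraMarginal_R,56,-34,30
64,Angular_L,-44,-61,36
65,Angular_R,44,-61,36
66,Precuneus_L,-7,-56,48
67,Precuneus_R,7,-56,48
68,Paracentral_Lobule_L,-8,-25,70
69,Paracentral_Lobule_R,8,-25,70
70,Caudate_L,-11,11,9
71,Caudate_R,11,11,9
72,Putamen_L,-24,4,2
73,Putamen_R,24,4,2
74,Pallidum_L,-18,0,0
75,Pallidum_R,18,0,0
76,Thalamus_L,-11,-18,8
77,Thalamus_R,11,-18,8
78,Heschl_L,-42,-19,10
79,Heschl_R,42,-19,10
80,Temporal_Sup_L,-53,-21,7
81,Temporal_Sup_R,53,-21,7
82,Temporal_Pole_Sup_L,-40,15,-20
83,Temporal_Pole_Sup_R,40,15,-20
84,Temporal_Mid_L,-56,-34,-2
85,Temporal_Mid_R,56,-34,-2
86,Temporal_Pole_Mid_L,-36,15,-34
87,Temporal_Pole_Mid_R,36,15,-34
88,Temporal_Inf_L,-50,-28,-23
89,Temporal_Inf_R,50,-28,-23
90,Cerebelum_Crus1_L,-35,-67,-29
91,Cerebelum_Crus1_R,35,-67,-29
92,Cerebelum_Crus2_L,-28,-73,-38
93,Cerebelum_Crus2_R,28,-73,-38
94,Cerebelum_3_L,-9,-37,-19
95,Cerebelum_3_R,9,-37,-19
96,Cerebelum_4_5_L,-15,-43,-17
97,Cerebelum_4_5_R,15,-43,-17
98,Cerebelum_6_L,-23,-59,-22
99,Cerebelum_6_R,23,-59,-22
100,Cerebelum_7b_L,-32,-60,-45
101,Cerebelum_7b_R,32,-60,-45
102,Cerebelum_8_L,-26,-55,-48
103,Cerebelum_8_R,26,-55,-48
104,Cerebelum_9_L,-11,-49,-46
105,Cerebelum_9_R,11,-49,-46
106,Cerebelum_10_L,-23,-34,-41
107,Cerebelum_10_R,23,-34,-41
108,Vermis_1_2,1,-39,-20
109,Vermis_3,1,-40,-11
110,Vermis_4_5,1,-52,-6
111,Vermis_6,1,-67,-15
112,Vermis_7,1,-72,-25
113,Vermis_8,1,-64,-34
114,Vermis_9,1,-55,-35
115,Vermis_10,1,-46,-32
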