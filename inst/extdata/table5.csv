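"Patient number","Chest pain","Shortness of Breath","Palpitation.","Patient at rest","SpO2 Value","High Blood Pressure (Bp) Value (mHg)","Low Blood Pressure (Bp) Value (mHg)"
1,"N","N","N","N",97,12,23
2,"Y","N","N","N",97,12,23
3,"N","Y","N","N",97,12,23
4,"Y","Y","N","N",97,12,23
5,"N","N","Y","N",97,12,23
6,"Y","N","Y","N",97,12,23
7,"N","Y","Y","N",97,12,23
8,"Y","Y","Y","N",97,12,23
9,"N","N","N","Y",97,12,23
10,"Y","N","N","Y",97,12,23
11,"N","Y","N","Y",97,12,23
12,"Y","Y","N","Y",97,12,23
13,"N","N","Y","Y",97,12,23
14,"Y","N","Y","Y",97,12,23
15,"N","Y","Y","Y",97,12,23
16,"Y","Y","Y","Y",97,12,23
17,"N","N","N","N",92,12,23
18,"Y","N","N","N",92,12,23
19,"N","Y","N","N",92,12,23
20,"Y","Y","N","N",92,12,23
21,"N","N","Y","N",92,12,23
22,"Y","N","Y","N",92,12,23
23,"N","Y","Y","N",92,12,23
24,"Y","Y","Y","N",92,12,23
25,"N","N","N","Y",92,12,23
26,"Y","N","N","Y",92,12,23
27,"N","Y","N","Y",92,12,23
28,"Y","Y","N","Y",92,12,23
29,"N","N","Y","Y",92,12,23
30,"Y","N","Y","Y",92,12,23
31,"N","Y","Y","Y",92,12,23
32,"Y","Y","Y","Y",92,12,23
33,"N","N","N","N",97,10,15
34,"Y","N","N","N",97,10,15
35,"N","Y","N","N",97,10,15
36,"Y","Y","N","N",97,10,15
37,"N","N","Y","N",97,10,15
38,"Y","N","Y","N",97,10,15
39,"N","Y","Y","N",97,10,15
40,"Y","Y","Y","N",97,10,15
41,"N","N","N","Y",97,10,15
42,"Y","N","N","Y",97,10,15
43,"N","Y","N","Y",97,10,15
44,"Y","Y","N","Y",97,10,15
45,"N","N","Y","Y",97,10,15
46,"Y","N","Y","Y",97,10,15
47,"N","Y","Y","Y",97,10,15
48,"Y","Y","Y","Y",97,10,15
49,"N","N","N","N",92,10,15
50,"Y","N","N","N",92,10,15
51,"N","Y","N","N",92,10,15
52,"Y","Y","N","N",92,10,15
53,"N","N","Y","N",92,10,15
54,"Y","N","Y","N",92,10,15
55,"N","Y","Y","N",92,10,15
56,"Y","Y","Y","N",92,10,15
57,"N","N","N","Y",92,10,15
58,"Y","N","N","Y",92,10,15
59,"N","Y","N","Y",92,10,15
60,"Y","Y","N","Y",92,10,15
61,"N","N","Y","Y",92,10,15
62,"Y","N","Y","Y",92,10,15
63,"N","Y","Y","Y",92,10,15
64,"Y","Y","Y","Y",92,10,15
65,"N","N","N","N",97,8,12
66,"Y","N","N","N",97,8,12
67,"N","Y","N","N",97,8,12
68,"Y","Y","N","N",97,8,12
69,"N","N","Y","N",97,8,12
70,"Y","N","Y","N",97,8,12
71,"N","Y","Y","N",97,8,12
72,"Y","Y","Y","N",97,8,12
73,"N","N","N","Y",97,8,12
74,"Y","N","N","Y",97,8,12
75,"N","Y","N","Y",97,8,12
76,"Y","Y","N","Y",97,8,12
77,"N","N","Y","Y",97,8,12
78,"Y","N","Y","Y",97,8,12
79,"N","Y","Y","Y",97,8,12
80,"Y","Y","Y","Y",97,8,12
81,"N","N","N","N",92,8,12
82,"Y","N","N","N",92,8,12
83,"N","Y","N","N",92,8,12
84,"Y","Y","N","N",92,8,12
85,"N","N","Y","N",92,8,12
86,"Y","N","Y","N",92,8,12
87,"N","Y","Y","N",92,8,12
88,"Y","Y","Y","N",92,8,12
89,"N","N","N","Y",92,8,12
90,"Y","N","N","Y",92,8,12
91,"N","Y","N","Y",92,8,12
92,"Y","Y","N","Y",92,8,12
93,"N","N","Y","Y",92,8,12
94,"Y","N","Y","Y",92,8,12
95,"N","Y","Y","Y",92,8,12
96,"Y","Y","Y","Y",92,8,12
97,"N","N","N","N",80,8,12
98,"Y","N","N","N",80,8,12
99,"N","Y","N","N",80,8,12
100,"Y","Y","N","N",80,8,12
101,"N","N","Y","N",80,8,12
102,"Y","N","Y","N",80,8,12
103,"N","Y","Y","N",80,8,12
104,"Y","Y","Y","N",80,8,12
105,"N","N","N","Y",80,8,12
106,"Y","N","N","Y",80,8,12
107,"N","Y","N","Y",80,8,12
108,"Y","Y","N","Y",80,8,12
109,"N","N","Y","Y",80,8,12
110,"Y","N","Y","Y",80,8,12
111,"N","Y","Y","Y",80,8,12
112,"Y","Y","Y","Y",80,8,12
113,"N","N","N","N",80,10,15
114,"Y","N","N","N",80,10,15
115,"N","Y","N","N",80,10,15
116,"Y","Y","N","N",80,10,15
117,"N","N","Y","N",80,10,15
118,"Y","N","Y","N",80,10,15
119,"N","Y","Y","N",80,10,15
120,"Y","Y","Y","N",80,10,15
121,"N","N","N","Y",80,10,15
122,"Y","N","N","Y",80,10,15
123,"N","Y","N","Y",80,10,15
124,"Y","Y","N","Y",80,10,15
125,"N","N","Y","Y",80,10,15
126,"Y","N","Y","Y",80,10,15
127,"N","Y","Y","Y",80,10,15
128,"Y","Y","Y","Y",80,10,15
129,"N","N","N","N",80,12,23
130,"Y","N","N","N",80,12,23
131,"N","Y","N","N",80,12,23
132,"Y","Y","N","N",80,12,23
133,"N","N","Y","N",80,12,23
134,"Y","N","Y","N",80,12,23
135,"N","Y","Y","N",80,12,23
136,"Y","Y","Y","N",80,12,23
137,"N","N","N","Y",80,12,23
138,"Y","N","N","Y",80,12,23
139,"N","Y","N","Y",80,12,23
140,"Y","Y","N","Y",80,12,23
141,"N","N","Y","Y",80,12,23
142,"Y","N","Y","Y",80,12,23
143,"N","Y","Y","Y",80,12,23
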