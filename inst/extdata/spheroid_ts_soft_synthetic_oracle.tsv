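f_hz	ts_db
38000	-44.093764
39000	-44.057006
40000	-44.021666
41000	-43.987778
42000	-43.955360
43000	-43.924411
44000	-43.894916
45000	-43.866845
46000	-43.840154
47000	-43.814791
48000	-43.790693
49000	-43.767790
50000	-43.746005
51000	-43.725256
52000	-43.705459
53000	-43.686528
54000	-43.668375
55000	-43.650914
56000	-43.634058
57000	-43.617724
58000	-43.601832
59000	-43.586306
60000	-43.571074
61000	-43.556067
62000	-43.541225
63000	-43.526492
64000	-43.511816
65000	-43.497153
66000	-43.482466
67000	-43.467721
68000	-43.452892
69000	-43.437958
70000	-43.422902
71000	-43.407715
72000	-43.392390
73000	-43.376925
74000	-43.361322
75000	-43.345586
76000	-43.329724
77000	-43.313745
78000	-43.297662
79000	-43.281487
80000	-43.265233
81000	-43.248913
82000	-43.232542
83000	-43.216131
84000	-43.199694
85000	-43.183241
86000	-43.166783
87000	-43.150328
88000	-43.133884
89000	-43.117456
90000	-43.101049
91000	-43.084665
92000	-43.068307
93000	-43.051974
94000	-43.035667
95000	-43.019382
96000	-43.003119
97000	-42.986874
98000	-42.970644
99000	-42.954425
100000	-42.938214
101000	-42.922008
102000	-42.905804
103000	-42.889600
104000	-42.873394
105000	-42.857185
106000	-42.840973
107000	-42.824760
108000	-42.808547
109000	-42.792336
110000	-42.776134
111000	-42.759944
112000	-42.743772
113000	-42.727626
114000	-42.711513
115000	-42.695443
116000	-42.679425
117000	-42.663469
118000	-42.647586
119000	-42.631785
120000	-42.616080
121000	-42.600480
122000	-42.584997
123000	-42.569642
124000	-42.554426
125000	-42.539360
126000	-42.524453
127000	-42.509714
128000	-42.495154
129000	-42.480779
130000	-42.466598
131000	-42.452616
132000	-42.438840
133000	-42.425275
134000	-42.411924
135000	-42.398792
136000	-42.385881
137000	-42.373194
138000	-42.360730
139000	-42.348492
140000	-42.336479
141000	-42.324691
142000	-42.313127
143000	-42.301786
144000	-42.290667
145000	-42.279768
146000	-42.269087
147000	-42.258622
148000	-42.248372
149000	-42.238334
150000	-42.228507
151000	-42.218889
152000	-42.209478
153000	-42.200272
154000	-42.191271
155000	-42.182473
156000	-42.173876
157000	-42.165481
158000	-42.157286
159000	-42.149290
160000	-42.141494
161000	-42.133896
162000	-42.126497
163000	-42.119295
164000	-42.112291
165000	-42.105485
166000	-42.098874
167000	-42.092460
168000	-42.086242
169000	-42.080217
170000	-42.074386
171000	-42.068746
172000	-42.063297
173000	-42.058036
174000	-42.052961
175000	-42.048069
176000	-42.043359
177000	-42.038826
178000	-42.034468
179000	-42.030282
180000	-42.026262
181000	-42.022406
182000	-42.018709
183000	-42.015167
184000	-42.011776
185000	-42.008530
186000	-42.005425
187000	-42.002456
188000	-41.999619
189000	-41.996909
190000	-41.994322
191000	-41.991852
192000	-41.989495
193000	-41.987247
194000	-41.985104
195000	-41.983062
196000	-41.981116
197000	-41.979264
198000	-41.977502
199000	-41.975826
200000	-41.974234
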