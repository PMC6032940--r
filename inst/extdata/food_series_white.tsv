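# food_series colour=white rho=0.215262
step	rods
1	8
2	8
3	2
4	2
5	8
6	8
7	2
8	8
9	2
10	2
11	2
12	8
13	2
14	2
15	2
16	8
17	8
18	8
19	8
20	2
21	2
22	2
23	8
24	8
25	2
26	2
27	2
28	2
29	8
30	8
31	8
32	2
33	8
34	8
35	8
36	8
37	8
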